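# Shared fixtures: small, fast objects built in code.

smallConnectome <- function(n = 8, seed = 1) synthConnectome(
  nRegions = n, nPseudoSubjects = 40, seed = seed)

smallOmega <- function(n = 8, seed = 1) defaultIntrinsicFrequencies(n, seed)

quickConfig <- function(seed = 1, duration = 120, dt = 0.05)
  simulationConfig(dt = dt, duration = duration, burnIn = 20,
                   sampleInterval = 2, seed = seed)

# Random symmetric FC-like matrix in the requested space.
randomFc <- function(n, seed, space = "fisher_z", sd = 0.1,
                     subjectId = NA_character_) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- rnorm(n * (n - 1) / 2, 0, sd)
  m <- m + t(m)
  if (space == "raw") {
    m <- tanh(m)
    diag(m) <- 1
  }
  new("FCMatrix", values = m, space = space,
      provenance = list(type = "empirical", subjectId = subjectId))
}

# A hand-assembled bank over an arbitrary grid: FCs are random but fixed
# by seed; metrics are supplied or defaulted.
makeBank <- function(grid, n = 8, seedBase = 100, metast = NULL) {
  np <- nrow(gridPoints(grid))
  fcs <- lapply(seq_len(np), function(i) {
    fc <- randomFc(n, seedBase + i)
    fc@provenance <- list(type = "simulated", params = NULL)
    fc
  })
  ut <- vapply(fcs, function(f) f@values[upper.tri(f@values)],
               numeric(n * (n - 1) / 2))
  if (is.null(metast)) metast <- seq_len(np) / np
  new("GridSimBank", grid = grid, fcs = fcs,
      upperTri = matrix(ut, ncol = np),
      metrics = data.frame(synchrony = seq(0.3, 0.7, length.out = np),
                           metastability = metast))
}

# Trajectory with prescribed constant phases (unit amplitudes).
phaseTrajectory <- function(phases, nT = 5) {
  z <- matrix(complex(modulus = 1, argument = phases), length(phases), nT)
  new("StateTrajectory", z = z,
      omega = matrix(0.1, length(phases), nT),
      times = seq(2, by = 2, length.out = nT), sampleInterval = 2,
      params = modelParameters(0, 0, 1, 0))
}

depParams1 <- function() modelParameters(-0.090, 0.010, 0.7, 0.49)
depParams2 <- function() modelParameters(0.020, 0.035, 0.4, 0.46)
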