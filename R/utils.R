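#' Construct model parameters
#'
#' @param A global bifurcation parameter (any sign; the local Hopf
#'   bifurcation sits at A = 0).
#' @param G global coupling strength (>= 0).
#' @param F global feedback coefficient of the angular-frequency equation
#'   (1/s, >= 0).
#' @param M global modulation index (rad/s per unit phase, >= 0).
#' @param beta noise standard deviation (default 0.02).
#' @return a [ModelParameters-class] object.
#' @examples
#' modelParameters(A = -0.09, G = 0.010, F = 0.7, M = 0.49)
#' @export
modelParameters <- function(A, G, F, M, beta = 0.02) {
  new("ModelParameters", A = as.numeric(A), G = as.numeric(G),
      F = as.numeric(F), M = as.numeric(M), beta = as.numeric(beta))
}

#' Construct a simulation configuration
#'
#' @param dt Euler-Maruyama step (s).
#' @param duration total integration time (s); default 420 s (7 min).
#' @param burnIn transient discarded before sampling (s).
#' @param sampleInterval state recording interval, the fMRI TR (s).
#' @param seed integer RNG seed for noise and initial conditions.
#' @return a [SimulationConfig-class] object.
#' @export
simulationConfig <- function(dt = 0.05, duration = 420, burnIn = 60,
                             sampleInterval = 2, seed = 1L) {
  new("SimulationConfig", dt = dt, duration = duration, burnIn = burnIn,
      sampleInterval = sampleInterval, seed = as.integer(seed))
}

#' Construct intrinsic frequencies
#'
#' @param omega0 numeric vector of angular frequencies (rad/s, > 0).
#' @return an [IntrinsicFrequencies-class] object.
#' @export
intrinsicFrequencies <- function(omega0) {
  new("IntrinsicFrequencies", omega0 = as.numeric(omega0))
}

#' Default intrinsic frequencies
#'
#' Draws region-specific intrinsic angular frequencies uniformly within
#' the empirically observed resting-state range 0.098-0.221 rad/s.
#'
#' @param n number of regions.
#' @param seed integer seed.
#' @param range two-element numeric range (rad/s).
#' @return an [IntrinsicFrequencies-class] object.
#' @export
defaultIntrinsicFrequencies <- function(n, seed = 1L,
                                        range = c(0.098, 0.221)) {
  stopifnot(n >= 1, range[1] > 0, range[2] > range[1])
  withr_seed(seed, {
    intrinsicFrequencies(stats::runif(n, range[1], range[2]))
  })
}

# Evaluate expr under a local RNG state restored afterwards.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-unit seed derived from a master seed and an index,
# kept within the positive 32-bit integer range.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 69621) %%
               2147483629) + 1L
}

# Deterministic 31-adic string hash within the positive 32-bit range.
stringHash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Canonical per-parameter-point simulation seed. Keyed by the parameter
# values (not a grid index) so any two grids -- or a grid bank and a
# synthetic cohort -- sharing a master seed evaluate the model with the
# same noise realization at the same point.
seedForPoint <- function(master, A, G, F, M) {
  deriveSeed(master, stringHash(sprintf("%.10g_%.10g_%.10g_%.10g",
                                        A, G, F, M)))
}

# Content hash of an arbitrary R object (md5 of its serialization).
contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Strict upper-triangle values of a square matrix, column-major order.
upperTriValues <- function(m) m[upper.tri(m, diag = FALSE)]
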