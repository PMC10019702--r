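#' @import methods
NULL

#' Structural connectome
#'
#' A nonnegative region-by-region coupling matrix \eqn{C_{ij}} with zero
#' diagonal. After row normalization every row sums to 1, so the coupling
#' term of each oscillator is a convex combination of its neighbours'
#' states. Region labels follow the row/column order of the matrix.
#'
#' @slot weights numeric matrix, N x N, nonnegative, zero diagonal.
#' @slot regionLabels character vector of length N.
#' @slot normalized logical; TRUE once rows have been scaled to unit sum.
#'
#' @seealso [synthConnectome()], [normalizeRows()], [readConnectome()]
#' @export
setClass("StructuralConnectome",
  representation(
    weights = "matrix",
    regionLabels = "character",
    normalized = "logical"
  ),
  prototype(normalized = FALSE)
)

setValidity("StructuralConnectome", function(object) {
  w <- object@weights
  msg <- character()
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "weights must be a square numeric matrix")
  else {
    if (any(!is.finite(w)))
      msg <- c(msg, "weights must be finite")
    if (any(w < 0))
      msg <- c(msg, "weights must be nonnegative")
    if (any(diag(w) != 0))
      msg <- c(msg, "diagonal entries must be exactly 0")
    if (length(object@regionLabels) != nrow(w))
      msg <- c(msg, "regionLabels length must match matrix dimension")
    if (isTRUE(object@normalized)) {
      rs <- rowSums(w)
      if (any(abs(rs - 1) > 1e-9))
        msg <- c(msg, "normalized connectome rows must sum to 1 within 1e-9")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Model parameters of the coupled oscillator network
#'
#' The four scalar control parameters of the whole-brain model plus the
#' noise standard deviation: `A` the global bifurcation parameter (the
#' local dynamics cross a supercritical Hopf bifurcation at A = 0), `G`
#' the global coupling strength, `F` the global feedback coefficient of
#' the angular-frequency equation (1/s), `M` the global modulation index
#' coupling each region's frequency to its neighbours' phases, and `beta`
#' the SD of the additive complex Wiener noise (default 0.02).
#'
#' @slot A,G,F,M,beta numeric scalars. G, F, M, beta must be >= 0.
#' @export
setClass("ModelParameters",
  representation(A = "numeric", G = "numeric", F = "numeric",
                 M = "numeric", beta = "numeric"),
  prototype(beta = 0.02)
)

setValidity("ModelParameters", function(object) {
  v <- c(A = object@A, G = object@G, F = object@F, M = object@M,
         beta = object@beta)
  msg <- character()
  if (length(v) != 5L || any(!is.finite(v)))
    return("A, G, F, M, beta must be finite scalars")
  if (object@G < 0) msg <- c(msg, "G must be >= 0")
  if (object@F < 0) msg <- c(msg, "F must be >= 0")
  if (object@M < 0) msg <- c(msg, "M must be >= 0")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Intrinsic angular frequencies
#'
#' Region-specific intrinsic angular frequencies \eqn{\omega^0_j} in rad/s,
#' the fixed points toward which each region's adaptive frequency relaxes
#' (scaled by 1/F) in the absence of phase modulation. Empirically these
#' are the dominant resting-state BOLD frequencies, in the range
#' 0.098-0.221 rad/s (about 0.016-0.035 Hz).
#'
#' @slot omega0 numeric vector, all entries > 0.
#' @seealso [defaultIntrinsicFrequencies()], [estimateIntrinsicFrequencies()]
#' @export
setClass("IntrinsicFrequencies", representation(omega0 = "numeric"))

setValidity("IntrinsicFrequencies", function(object) {
  if (length(object@omega0) < 1L) return("omega0 must be nonempty")
  if (any(!is.finite(object@omega0)) || any(object@omega0 <= 0))
    return("all intrinsic frequencies must be finite and > 0")
  TRUE
})

#' Simulation configuration
#'
#' Integration and sampling settings: Euler-Maruyama step `dt` (s), total
#' `duration` (s), initial `burnIn` discarded before sampling (s), and the
#' `sampleInterval` at which states are recorded (the fMRI TR, default 2 s).
#'
#' @slot dt,duration,burnIn,sampleInterval numeric scalars (seconds).
#' @slot seed integer seed for the noise and initial conditions.
#' @export
setClass("SimulationConfig",
  representation(dt = "numeric", duration = "numeric", burnIn = "numeric",
                 sampleInterval = "numeric", seed = "integer"),
  prototype(dt = 0.05, duration = 420, burnIn = 60, sampleInterval = 2,
            seed = 1L)
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@dt <= 0 || object@duration <= 0 || object@burnIn < 0 ||
      object@sampleInterval <= 0)
    msg <- c(msg, "dt, duration, sampleInterval must be positive; burnIn >= 0")
  if (object@dt >= object@sampleInterval)
    msg <- c(msg, "dt must be smaller than sampleInterval")
  if (object@burnIn >= object@duration)
    msg <- c(msg, "burnIn must be smaller than duration")
  if (length(msg)) msg else TRUE
})

#' Simulated state trajectory
#'
#' Sampled states of the oscillator network: the complex amplitude
#' \eqn{z_j(t)} (its real part is the simulated BOLD signal, the imaginary
#' part the hidden state) and the instantaneous angular frequency
#' \eqn{\omega_j(t)}, both N x T, sampled every `sampleInterval` seconds
#' after the burn-in.
#'
#' @slot z complex matrix N x T.
#' @slot omega numeric matrix N x T (rad/s).
#' @slot times numeric vector of T sample times (s).
#' @slot sampleInterval numeric scalar (s).
#' @slot params the [ModelParameters-class] used.
#' @export
setClass("StateTrajectory",
  representation(z = "matrix", omega = "matrix", times = "numeric",
                 sampleInterval = "numeric", params = "ModelParameters")
)

setValidity("StateTrajectory", function(object) {
  msg <- character()
  if (!is.complex(object@z)) msg <- c(msg, "z must be a complex matrix")
  if (any(!is.finite(object@z)) || any(!is.finite(object@omega)))
    msg <- c(msg, "all state entries must be finite")
  if (!all(dim(object@z) == dim(object@omega)))
    msg <- c(msg, "z and omega must have identical dimensions")
  if (ncol(object@z) != length(object@times))
    msg <- c(msg, "times length must equal the number of samples")
  dtms <- diff(object@times)
  if (length(dtms) && (any(dtms <= 0) || diff(range(dtms)) > 1e-9))
    msg <- c(msg, "times must be strictly increasing with constant spacing")
  if (length(msg)) msg else TRUE
})

#' Regional time series
#'
#' An N x T matrix of real-valued regional signals (empirical or simulated
#' BOLD) with its sampling interval in seconds.
#'
#' @slot values numeric matrix N x T.
#' @slot sampleInterval numeric scalar (s).
#' @slot subjectId character, possibly empty.
#' @export
setClass("RegionalTimeSeries",
  representation(values = "matrix", sampleInterval = "numeric",
                 subjectId = "character"),
  prototype(subjectId = NA_character_)
)

setValidity("RegionalTimeSeries", function(object) {
  msg <- character()
  if (ncol(object@values) < 8L)
    msg <- c(msg, "time series must have at least 8 time points")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "all values must be finite")
  if (object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be positive")
  if (length(msg)) msg else TRUE
})

#' Functional connectivity matrix
#'
#' Symmetric region-by-region functional connectivity, either raw Pearson
#' correlations (`space = "raw"`, diagonal 1) or Fisher z-transformed
#' values (`space = "fisher_z"`, diagonal 0). `provenance` records whether
#' the matrix came from an empirical subject or from a simulated parameter
#' set.
#'
#' @slot values numeric matrix N x N, symmetric.
#' @slot space character, `"raw"` or `"fisher_z"`.
#' @slot provenance list with element `type` (`"empirical"` or
#'   `"simulated"`) plus `subjectId` or `params`.
#' @export
setClass("FCMatrix",
  representation(values = "matrix", space = "character", provenance = "list"),
  prototype(space = "raw", provenance = list(type = "unknown"))
)

setValidity("FCMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "FC matrix must be square")
  else {
    if (max(abs(v - t(v))) > 1e-9)
      msg <- c(msg, "FC matrix must be symmetric within 1e-9")
    if (object@space == "raw") {
      if (any(v < -1 - 1e-12 | v > 1 + 1e-12))
        msg <- c(msg, "raw correlations must lie in [-1, 1]")
      if (any(abs(diag(v) - 1) > 1e-12))
        msg <- c(msg, "raw-correlation diagonal must be 1")
    }
  }
  if (!object@space %in% c("raw", "fisher_z"))
    msg <- c(msg, "space must be 'raw' or 'fisher_z'")
  if (length(msg)) msg else TRUE
})

#' Parameter search grid
#'
#' Cartesian grid over (A, G, F, M), built from per-axis (start, stop,
#' step) triples with inclusive endpoints and a half-step tolerance at the
#' top end. `points` enumerates the grid in lexicographic (A, G, F, M)
#' order; `steps` holds the per-axis step sizes used for mode detection.
#'
#' @slot points data.frame with columns A, G, F, M.
#' @slot steps named numeric vector of axis steps.
#' @export
setClass("ParameterGrid",
  representation(points = "data.frame", steps = "numeric"))

setValidity("ParameterGrid", function(object) {
  if (!all(c("A", "G", "F", "M") %in% names(object@points)))
    return("points must have columns A, G, F, M")
  if (nrow(object@points) < 1L) return("grid must contain at least one point")
  if (!all(c("A", "G", "F", "M") %in% names(object@steps)))
    return("steps must be named A, G, F, M")
  TRUE
})

#' Bank of grid-point simulations
#'
#' One simulated Fisher-z FC matrix and one pair of dynamics metrics
#' (synchrony, metastability) per grid point, plus the flattened strict
#' upper triangles stacked as a matrix for fast similarity search.
#'
#' @slot grid the [ParameterGrid-class] simulated.
#' @slot fcs list of [FCMatrix-class] (fisher_z), one per grid point.
#' @slot upperTri numeric matrix, N(N-1)/2 x nPoints; column i is the
#'   strict upper triangle of `fcs[[i]]`.
#' @slot metrics data.frame with columns synchrony, metastability.
#' @export
setClass("GridSimBank",
  representation(grid = "ParameterGrid", fcs = "list", upperTri = "matrix",
                 metrics = "data.frame"))

setValidity("GridSimBank", function(object) {
  n <- nrow(object@grid@points)
  msg <- character()
  if (length(object@fcs) != n)
    msg <- c(msg, "one FC per grid point required")
  if (ncol(object@upperTri) != n)
    msg <- c(msg, "upperTri must have one column per grid point")
  if (nrow(object@metrics) != n)
    msg <- c(msg, "metrics must have one row per grid point")
  if (length(msg)) msg else TRUE
})

#' Two-subtype stratification solution
#'
#' The two modal parameter sets found in the pooled Monte-Carlo
#' distribution, their simulated FC maps, per-mode iteration counts and
#' dynamics metrics. DEP1 is, by convention, the mode with the larger
#' simulated metastability.
#'
#' @slot paramsDep1,paramsDep2 [ModelParameters-class] of the two modes.
#' @slot fcDep1,fcDep2 the modes' simulated [FCMatrix-class] (fisher_z).
#' @slot modeCounts integer vector of length 2 (Monte-Carlo iterations per
#'   mode).
#' @slot metrics data.frame (2 rows): synchrony, metastability per mode.
#' @slot labelRule character description of the DEP1/DEP2 labeling rule.
#' @export
setClass("SubtypeSolution",
  representation(paramsDep1 = "ModelParameters", paramsDep2 = "ModelParameters",
                 fcDep1 = "FCMatrix", fcDep2 = "FCMatrix",
                 modeCounts = "integer", metrics = "data.frame",
                 labelRule = "character"))

setValidity("SubtypeSolution", function(object) {
  p1 <- paramVector(object@paramsDep1)
  p2 <- paramVector(object@paramsDep2)
  if (all(p1[1:4] == p2[1:4]))
    return("the two subtype parameter sets must differ")
  TRUE
})

#' Synthetic cohort
#'
#' A self-contained synthetic study: connectome, per-subject Fisher-z FC
#' matrices with ground-truth subtype labels, a behavioral cohort table,
#' and a generation log recording every seed and effect size injected.
#'
#' @slot connectome [StructuralConnectome-class].
#' @slot fcs list of [FCMatrix-class] (fisher_z), one per subject; may be
#'   empty when the spec disabled FC simulation.
#' @slot cohort data.frame behavioral table (see [generateCohort()]).
#' @slot truth data.frame of ground-truth labels and parameters.
#' @slot log list of generation settings and seeds.
#' @export
setClass("SyntheticCohort",
  representation(connectome = "StructuralConnectome", fcs = "list",
                 cohort = "data.frame", truth = "data.frame", log = "list"))
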