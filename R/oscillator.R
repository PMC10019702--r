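#' @useDynLib BrainHopf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulate the coupled oscillator network
#'
#' Integrates the stochastic whole-brain model by Euler-Maruyama. Each
#' region j carries a complex amplitude \eqn{z_j} and an adaptive angular
#' frequency \eqn{\omega_j}:
#' \deqn{\dot z_j = (A + i\omega_j - |z_j|^2) z_j +
#'       G \sum_i C_{ij}(z_i - z_j) + \beta \eta_j}
#' \deqn{\dot \omega_j = \omega^0_j - F \omega_j + M \sum_i C_{ij}
#'       \arg(z_i)}
#' where \eqn{\eta_j} is complex white noise with independent real and
#' imaginary increments of SD \eqn{\beta\sqrt{dt}} per step, and
#' \eqn{\arg} is the principal phase in \eqn{(-\pi, \pi]}. The frequency
#' equation is deterministic. Initial amplitudes are drawn uniformly in a
#' disk of radius 0.1 and \eqn{\omega_j(0) = \omega^0_j}; both the initial
#' conditions and the noise path are determined by `config@seed`.
#'
#' For uncoupled noise-free dynamics (G = 0, beta = 0) the amplitude
#' follows the Stuart-Landau normal form: for A > 0 a stable limit cycle
#' of radius \eqn{\sqrt A}, for A < 0 a stable focus at the origin.
#'
#' @param params [ModelParameters-class].
#' @param connectome row-normalized [StructuralConnectome-class].
#' @param omega0 [IntrinsicFrequencies-class], same dimension as the
#'   connectome.
#' @param config [SimulationConfig-class].
#' @return a [StateTrajectory-class] sampled every `sampleInterval`
#'   seconds after the burn-in.
#' @examples
#' sc <- synthConnectome(nRegions = 8, seed = 1)
#' om <- defaultIntrinsicFrequencies(8, seed = 1)
#' tr <- simulateNetwork(modelParameters(-0.09, 0.01, 0.7, 0.49), sc, om,
#'                       simulationConfig(duration = 120, seed = 7))
#' @export
simulateNetwork <- function(params, connectome, omega0, config) {
  stopifnot(is(params, "ModelParameters"),
            is(connectome, "StructuralConnectome"),
            is(omega0, "IntrinsicFrequencies"),
            is(config, "SimulationConfig"))
  validObject(params); validObject(config)
  N <- nRegions(connectome)
  if (length(omega0@omega0) != N)
    stop("omega0 has length ", length(omega0@omega0),
         " but the connectome has ", N, " regions")
  if (!connectome@normalized)
    stop("connectome must be row-normalized before simulation")
  if (params@F == 0)
    warning("F = 0: the angular-frequency equation has no restoring term; ",
            "omega may drift over the run")
  dt <- config@dt
  nSteps <- round(config@duration / dt)
  sampleEvery <- round(config@sampleInterval / dt)
  if (abs(sampleEvery * dt - config@sampleInterval) > 1e-9)
    stop("sampleInterval must be an integer multiple of dt")
  firstSample <- max(round(config@burnIn / dt), sampleEvery)

  withr_seed(config@seed, {
    r <- 0.1 * sqrt(stats::runif(N))
    phi <- stats::runif(N, -pi, pi)
    z0 <- complex(modulus = r, argument = phi)
    res <- simulate_hopf_cpp(weightMatrix(connectome), z0, omega0@omega0,
                             params@A, params@G, params@F, params@M,
                             params@beta, dt, nSteps, sampleEvery,
                             firstSample)
  })
  times <- dt * seq(firstSample, nSteps, by = sampleEvery)
  new("StateTrajectory", z = res$z, omega = res$omega, times = times,
      sampleInterval = config@sampleInterval, params = params)
}

#' Extract the simulated BOLD signal
#'
#' The real part of the complex amplitude state is the model's proxy for
#' the regional BOLD signal; the imaginary part is the unobservable hidden
#' state and is discarded.
#'
#' @param traj a [StateTrajectory-class].
#' @param subjectId optional subject identifier to attach.
#' @return a [RegionalTimeSeries-class] of Re(z), N x T.
#' @export
extractBold <- function(traj, subjectId = NA_character_) {
  stopifnot(is(traj, "StateTrajectory"))
  new("RegionalTimeSeries", values = Re(traj@z),
      sampleInterval = traj@sampleInterval, subjectId = subjectId)
}

#' Export a trajectory as tab-separated tables
#'
#' Writes `<prefix>_re.tsv`, `<prefix>_im.tsv` and `<prefix>_omega.tsv`
#' (region x time) plus a JSON sidecar `<prefix>_config.json` echoing the
#' sampling settings and parameters.
#'
#' @param traj a [StateTrajectory-class].
#' @param prefix output path prefix.
#' @return the sidecar path, invisibly.
#' @export
writeTrajectory <- function(traj, prefix) {
  stopifnot(is(traj, "StateTrajectory"))
  wr <- function(m, suffix) {
    utils::write.table(format(m, digits = 10, trim = TRUE),
                       paste0(prefix, "_", suffix, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  wr(Re(traj@z), "re"); wr(Im(traj@z), "im"); wr(traj@omega, "omega")
  side <- paste0(prefix, "_config.json")
  jsonlite::write_json(list(
    sampleInterval = traj@sampleInterval,
    times = range(traj@times),
    nRegions = nrow(traj@z), nSamples = ncol(traj@z),
    params = as.list(paramVector(traj@params))
  ), side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
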