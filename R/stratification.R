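#' Kuramoto order parameter time series
#'
#' \eqn{R(t) = |N^{-1} \sum_j e^{i\theta_j(t)}|}, the modulus of the mean
#' unit phasor across regions, bounded in `[0, 1]`. For a simulated
#' [StateTrajectory-class] the phase is \eqn{\arg z_j(t)}; for an
#' empirical [RegionalTimeSeries-class] (typically band-passed BOLD) the
#' phase is extracted from the analytic signal (frequency-domain Hilbert
#' transform), and the returned vector carries the attribute
#' `phaseSource = "analytic_signal"` to flag the different provenance.
#'
#' @param x a [StateTrajectory-class] or [RegionalTimeSeries-class] with
#'   at least two regions.
#' @return numeric vector R(t), length T.
#' @export
setGeneric("kuramotoOrderSeries",
           function(x) standardGeneric("kuramotoOrderSeries"))

#' @rdname kuramotoOrderSeries
#' @export
setMethod("kuramotoOrderSeries", "StateTrajectory", function(x) {
  if (nrow(x@z) < 2L) stop("at least two regions required")
  theta <- Arg(x@z)
  out <- Mod(colMeans(exp(1i * theta)))
  attr(out, "phaseSource") <- "model_state"
  out
})

#' @rdname kuramotoOrderSeries
#' @export
setMethod("kuramotoOrderSeries", "RegionalTimeSeries", function(x) {
  if (nrow(x@values) < 2L) stop("at least two regions required")
  theta <- t(apply(x@values, 1, analyticPhase))
  out <- Mod(colMeans(exp(1i * theta)))
  attr(out, "phaseSource") <- "analytic_signal"
  out
})

#' Synchrony and metastability of an order-parameter series
#'
#' Synchrony is the time mean of the Kuramoto order parameter R(t);
#' metastability is its temporal population standard deviation (the
#' trajectory is treated as the full object of interest, not a sample).
#'
#' @param R numeric vector from [kuramotoOrderSeries()].
#' @return a scalar.
#' @export
synchrony <- function(R) {
  if (length(R) == 0L) stop("empty order-parameter series")
  mean(R)
}

#' @rdname synchrony
#' @export
metastability <- function(R) {
  if (length(R) == 0L) stop("empty order-parameter series")
  sqrt(mean((R - mean(R))^2))
}

#' Assign subjects to the two dynamical subtypes
#'
#' Each subject's Fisher-z FC is compared (upper-triangle correlation)
#' with the simulated FC of both subtype models; the subject is assigned
#' to the more similar one. Exact ties go to DEP1 with a warning.
#'
#' @param subjectFcs list of [FCMatrix-class] (fisher_z); names or
#'   provenance supply subject ids.
#' @param solution a [SubtypeSolution-class].
#' @return data.frame with columns `subjectId`, `subtype`, `simDep1`,
#'   `simDep2`, `margin`.
#' @export
assignSubjects <- function(subjectFcs, solution) {
  stopifnot(is(solution, "SubtypeSolution"), length(subjectFcs) > 0)
  ids <- names(subjectFcs)
  if (is.null(ids))
    ids <- vapply(seq_along(subjectFcs), function(i) {
      sid <- subjectFcs[[i]]@provenance$subjectId
      if (is.null(sid) || is.na(sid)) sprintf("subject_%03d", i) else sid
    }, character(1))
  s1 <- vapply(subjectFcs, fcSimilarity, numeric(1), b = solution@fcDep1)
  s2 <- vapply(subjectFcs, fcSimilarity, numeric(1), b = solution@fcDep2)
  if (any(s1 == s2))
    warning("similarity tie for subject(s) ",
            paste(ids[s1 == s2], collapse = ", "), "; assigned to DEP1")
  data.frame(subjectId = ids,
             subtype = ifelse(s1 >= s2, "DEP1", "DEP2"),
             simDep1 = unname(s1), simDep2 = unname(s2),
             margin = abs(unname(s1) - unname(s2)))
}

#' z-score a value against a reference distribution
#'
#' `(value - mean(reference)) / sd_pop(reference)` with the population
#' standard deviation. Used to express a subtype's synchrony or
#' metastability relative to the distribution of the same metric over all
#' Monte-Carlo-selected grid points.
#'
#' @param value numeric scalar.
#' @param reference numeric vector with positive spread.
#' @return the z-score.
#' @export
zscoreAgainstDistribution <- function(value, reference) {
  if (length(reference) < 2L) stop("reference must have length >= 2")
  s <- sqrt(mean((reference - mean(reference))^2))
  if (s == 0) stop("reference distribution has zero standard deviation")
  (value - mean(reference)) / s
}

#' Subtype dynamics metrics referenced to the Monte-Carlo distribution
#'
#' Computes, for both subtype representatives in a solution, the z-score
#' of synchrony and metastability against the distribution of those
#' metrics over all Monte-Carlo-selected grid points (one entry per
#' record).
#'
#' @param solution a [SubtypeSolution-class].
#' @param records Monte-Carlo records from [monteCarloFit()].
#' @param bank the [GridSimBank-class].
#' @return data.frame: subtype, synchrony, metastability, zSynchrony,
#'   zMetastability.
#' @export
subtypeDynamics <- function(solution, records, bank) {
  refSync <- bank@metrics$synchrony[records$bankIndex]
  refMeta <- bank@metrics$metastability[records$bankIndex]
  m <- solution@metrics
  data.frame(
    subtype = m$subtype,
    synchrony = m$synchrony,
    metastability = m$metastability,
    zSynchrony = vapply(m$synchrony, zscoreAgainstDistribution, numeric(1),
                        reference = refSync),
    zMetastability = vapply(m$metastability, zscoreAgainstDistribution,
                            numeric(1), reference = refMeta))
}
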