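#' Construct a regional time series
#'
#' @param values N x T numeric matrix (regions x time).
#' @param sampleInterval sampling interval in seconds.
#' @param subjectId optional subject identifier.
#' @return a [RegionalTimeSeries-class].
#' @export
regionalTimeSeries <- function(values, sampleInterval,
                               subjectId = NA_character_) {
  new("RegionalTimeSeries", values = as.matrix(values),
      sampleInterval = sampleInterval, subjectId = subjectId)
}

# Orthonormal DCT-II basis matrix, rows = coefficients, columns = time.
dctBasis <- function(T) {
  k <- 0:(T - 1)
  n <- 0:(T - 1)
  D <- sqrt(2 / T) * cos(pi * outer(k, n + 0.5) / T)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Band-pass filter via discrete cosine transform windowing
#'
#' Per region: forward DCT-II over the full series length, zeroing of all
#' coefficients whose equivalent frequency `k / (2 * T * sampleInterval)`
#' falls outside `[fLow, fHigh]`, inverse transform. The zero-frequency
#' coefficient lies below any positive `fLow`, so the mean is removed.
#' Defaults match the conventional resting-state fMRI band 0.008-0.1 Hz.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param fLow,fHigh band edges in Hz; `fHigh` must be below the Nyquist
#'   frequency `1 / (2 * sampleInterval)`.
#' @return a filtered [RegionalTimeSeries-class].
#' @export
bandpassDct <- function(ts, fLow = 0.008, fHigh = 0.1) {
  stopifnot(is(ts, "RegionalTimeSeries"), fLow > 0, fLow < fHigh)
  nyq <- 1 / (2 * ts@sampleInterval)
  if (fHigh >= nyq)
    stop(sprintf("fHigh (%.4f Hz) must be below Nyquist (%.4f Hz)",
                 fHigh, nyq))
  T <- ncol(ts@values)
  D <- dctBasis(T)
  freqs <- (0:(T - 1)) / (2 * T * ts@sampleInterval)
  keep <- freqs >= fLow & freqs <= fHigh
  coef <- D %*% t(ts@values)
  coef[!keep, ] <- 0
  filtered <- t(crossprod(D, coef))
  new("RegionalTimeSeries", values = filtered,
      sampleInterval = ts@sampleInterval, subjectId = ts@subjectId)
}

#' Compute a functional connectivity matrix
#'
#' Pairwise Pearson correlation of the regional time series.
#'
#' @param ts a [RegionalTimeSeries-class]; every region must have nonzero
#'   variance.
#' @param provenance provenance list to attach; defaults to an empirical
#'   tag built from the series' subject id.
#' @return an [FCMatrix-class] in raw-correlation space.
#' @export
computeFc <- function(ts, provenance = NULL) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  v <- apply(ts@values, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s): ", paste(which(v == 0), collapse = ", "))
  fc <- stats::cor(t(ts@values))
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  if (is.null(provenance))
    provenance <- list(type = "empirical", subjectId = ts@subjectId)
  new("FCMatrix", values = fc, space = "raw", provenance = provenance)
}

#' Fisher z-transform of a correlation matrix
#'
#' Entrywise `atanh` with inputs clipped to +/- 0.999999 (degenerate
#' simulated pairs can reach |r| = 1); the diagonal is set to 0 and the
#' result is marked as `fisher_z` so it cannot be transformed twice.
#'
#' @param fc an [FCMatrix-class] in raw-correlation space.
#' @return an [FCMatrix-class] in fisher_z space.
#' @export
fisherZ <- function(fc) {
  stopifnot(is(fc, "FCMatrix"))
  if (fc@space != "raw")
    stop("fisherZ requires a raw-correlation FC (got space '", fc@space, "')")
  v <- atanh(pmin(pmax(fc@values, -0.999999), 0.999999))
  diag(v) <- 0
  new("FCMatrix", values = v, space = "fisher_z", provenance = fc@provenance)
}

#' Similarity between two FC matrices
#'
#' Pearson correlation of the strict upper triangles (N(N-1)/2 values);
#' the constant diagonal is excluded. Both matrices must share dimensions
#' and value space.
#'
#' @param a,b [FCMatrix-class] objects.
#' @return a correlation in `[-1, 1]`.
#' @export
fcSimilarity <- function(a, b) {
  stopifnot(is(a, "FCMatrix"), is(b, "FCMatrix"))
  if (!all(dim(a@values) == dim(b@values)))
    stop("FC dimension mismatch")
  if (a@space != b@space)
    stop("FC space mismatch: '", a@space, "' vs '", b@space, "'")
  stats::cor(upperTriValues(a@values), upperTriValues(b@values))
}

#' Average a set of Fisher-z FC matrices
#'
#' Entrywise mean of Fisher-z transformed FC matrices, the group map used
#' as the fitting target in each Monte-Carlo iteration.
#'
#' @param fcs nonempty list of [FCMatrix-class] in fisher_z space.
#' @return an [FCMatrix-class] (fisher_z) with provenance
#'   `type = "group_average"`.
#' @export
groupAverageFc <- function(fcs) {
  if (length(fcs) == 0L) stop("empty FC list")
  stopifnot(all(vapply(fcs, is, logical(1), "FCMatrix")))
  if (!all(vapply(fcs, function(f) f@space, character(1)) == "fisher_z"))
    stop("all FCs must be in fisher_z space")
  d <- dim(fcs[[1]]@values)
  if (!all(vapply(fcs, function(f) all(dim(f@values) == d), logical(1))))
    stop("FC dimension mismatch")
  m <- Reduce(`+`, lapply(fcs, fcValues)) / length(fcs)
  new("FCMatrix", values = m, space = "fisher_z",
      provenance = list(type = "group_average", n = length(fcs)))
}

# Welch-style averaged periodogram of one series: Hann-tapered segments
# of length segLength with 50% overlap, demeaned per segment.
welchPsd <- function(x, sampleInterval, segLength = 64) {
  T <- length(x)
  L <- min(T, segLength)
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, T - L + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  nf <- floor(L / 2) + 1L
  psd <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2
    psd <- psd + p[seq_len(nf)]
  }
  list(freq = (seq_len(nf) - 1L) / (L * sampleInterval),
       power = psd / length(starts))
}

#' Estimate intrinsic angular frequencies from a cohort
#'
#' Per subject and region, the power spectral density is estimated with a
#' Welch-style averaged periodogram (segment length `min(T, segLength)`,
#' 50% overlap, cosine taper) and its peak within `[fLow, fHigh]` Hz is
#' taken as the region's dominant frequency, converted to rad/s as
#' \eqn{\omega^0 = 2\pi f^*}. The per-region median across subjects is the
#' group-representative intrinsic frequency.
#'
#' @param cohortTs nonempty list of [RegionalTimeSeries-class], all with
#'   the same region count and sampling interval.
#' @param fLow,fHigh peak search band in Hz.
#' @param segLength Welch segment length (time points).
#' @return an [IntrinsicFrequencies-class].
#' @export
estimateIntrinsicFrequencies <- function(cohortTs, fLow = 0.008,
                                         fHigh = 0.1, segLength = 64) {
  if (length(cohortTs) == 0L) stop("empty cohort")
  stopifnot(all(vapply(cohortTs, is, logical(1), "RegionalTimeSeries")))
  N <- nrow(cohortTs[[1]]@values)
  dtv <- cohortTs[[1]]@sampleInterval
  ok <- vapply(cohortTs, function(t)
    nrow(t@values) == N && t@sampleInterval == dtv, logical(1))
  if (!all(ok)) stop("all subjects must share region count and TR")
  peaks <- vapply(cohortTs, function(ts) {
    vapply(seq_len(N), function(j) {
      w <- welchPsd(ts@values[j, ], dtv, segLength)
      inband <- which(w$freq >= fLow & w$freq <= fHigh)
      if (length(inband) == 0L)
        stop("no spectral bins inside the band; series too short")
      w$freq[inband[which.max(w$power[inband])]]
    }, numeric(1))
  }, numeric(N))
  peaks <- matrix(peaks, nrow = N)
  intrinsicFrequencies(2 * pi * apply(peaks, 1, stats::median))
}

# Instantaneous phase of a real series via the analytic signal
# (frequency-domain Hilbert transform).
analyticPhase <- function(x) {
  T <- length(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[c(1, T / 2 + 1)] <- 1
    h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((T + 1) / 2)] <- 2
  }
  Arg(stats::fft(stats::fft(x) * h, inverse = TRUE) / T)
}

#' Read / write regional time series and FC matrices as TSV
#'
#' Time series are stored as region x time TSV with region labels in the
#' first column; FC matrices as square labeled TSV. Each writer emits a
#' JSON sidecar (`<path>.json`) recording the sampling interval or the FC
#' space and provenance.
#'
#' @param x object to write.
#' @param path file path.
#' @param sampleInterval sampling interval used by `readTimeSeries` when
#'   no sidecar is present.
#' @return readers return the object; writers return `path` invisibly.
#' @name fc_io
NULL

#' @rdname fc_io
#' @export
writeTimeSeries <- function(x, path) {
  stopifnot(is(x, "RegionalTimeSeries"))
  m <- x@values
  rownames(m) <- sprintf("region_%02d", seq_len(nrow(m)))
  utils::write.table(format(m, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  jsonlite::write_json(list(sampleInterval = x@sampleInterval,
                            subjectId = x@subjectId),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fc_io
#' @export
readTimeSeries <- function(path, sampleInterval = NULL) {
  side <- paste0(path, ".json")
  sid <- NA_character_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    sampleInterval <- as.numeric(meta$sampleInterval)
    if (!is.null(meta$subjectId)) sid <- as.character(meta$subjectId)
  }
  if (is.null(sampleInterval))
    stop("sampleInterval required (no JSON sidecar found)")
  df <- utils::read.table(path, sep = "\t", row.names = 1)
  regionalTimeSeries(unname(as.matrix(df)), sampleInterval, sid)
}

#' @rdname fc_io
#' @export
writeFc <- function(x, path) {
  stopifnot(is(x, "FCMatrix"))
  m <- x@values
  dimnames(m) <- list(sprintf("region_%02d", seq_len(nrow(m))),
                      sprintf("region_%02d", seq_len(nrow(m))))
  utils::write.table(format(m, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  prov <- x@provenance
  if (!is.null(prov$params) && is(prov$params, "ModelParameters"))
    prov$params <- as.list(paramVector(prov$params))
  jsonlite::write_json(list(space = x@space, provenance = prov),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname fc_io
#' @export
readFc <- function(path) {
  side <- paste0(path, ".json")
  space <- "raw"; prov <- list(type = "unknown")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    space <- meta$space
    prov <- meta$provenance
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  new("FCMatrix", values = unname(as.matrix(df)), space = space,
      provenance = prov)
}
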