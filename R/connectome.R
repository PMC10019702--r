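#' Rank-based Gaussian resampling of edge weights
#'
#' Maps a vector of positive edge weights onto a Gaussian profile by a
#' rank-based inverse-normal transform: the weight with rank r among n
#' (average ranks on ties) becomes `mu + sigma * qnorm((r - 0.5)/n)`.
#' This reproduces the construction in which group-consensus streamline
#' densities are resampled to follow a Gaussian with mean 0.5 and SD 0.15
#' before row normalization. Values are clipped below at 1e-6 so the
#' coupling matrix stays nonnegative (at mu = 0.5, sigma = 0.15 roughly
#' 0.04% of the Gaussian mass falls below zero).
#'
#' @param weights numeric vector of edge weights (nonempty).
#' @param mu,sigma target Gaussian mean and SD.
#' @return numeric vector of resampled weights, same length and order.
#' @examples
#' gaussianResampleWeights(c(1, 2, 3))
#' @export
gaussianResampleWeights <- function(weights, mu = 0.5, sigma = 0.15) {
  if (length(weights) == 0L) stop("weights must be nonempty")
  stopifnot(sigma > 0)
  r <- rank(weights, ties.method = "average")
  out <- mu + sigma * stats::qnorm((r - 0.5) / length(weights))
  pmax(out, 1e-6)
}

#' Row-normalize a coupling matrix
#'
#' Divides every row by its sum so that the structural connectivity
#' weights of each region sum to 1; the zero pattern is preserved.
#'
#' @param weights nonnegative square matrix.
#' @return matrix with unit row sums.
#' @export
normalizeRows <- function(weights) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (any(weights < 0)) stop("weights must be nonnegative")
  rs <- rowSums(weights)
  bad <- which(rs <= 0)
  if (length(bad))
    stop("row(s) with zero total connectivity: region ",
         paste(bad, collapse = ", "))
  weights / rs
}

# Group-consensus edge weights: an edge survives only when present in
# strictly more than `threshold` of the pseudo-subjects ("above" the
# consistency threshold); surviving weights are averaged over the
# pseudo-subjects that carry them. Rows = edges, columns = pseudo-subjects.
consensusEdges <- function(presence, weightsByEdge, threshold) {
  keep <- rowMeans(presence) > threshold
  avg <- numeric(nrow(presence))
  cnt <- rowSums(presence)
  avg[keep] <- rowSums(weightsByEdge)[keep] / cnt[keep]
  avg
}

#' Generate a synthetic group-consensus connectome
#'
#' Emulates the construction of a group-level structural connectome from a
#' sample of individual tractograms when the raw diffusion data are not
#' available: each of `nPseudoSubjects` pseudo-subjects contributes a
#' symmetric random edge-presence pattern (each undirected edge present
#' independently with probability `edgePresenceProb`) with positive
#' log-normal weights; only edges present in strictly more than
#' `consistencyThreshold` of pseudo-subjects are kept; surviving edge
#' weights are averaged over the pseudo-subjects carrying them, resampled
#' to a Gaussian profile (mean 0.5, SD 0.15) by
#' [gaussianResampleWeights()], and the matrix is row-normalized.
#'
#' @param nRegions number of regions (default 68, a Desikan-Killiany-like
#'   cortical parcellation).
#' @param nPseudoSubjects number of simulated tractograms.
#' @param edgePresenceProb per-edge presence probability in (0, 1].
#' @param consistencyThreshold fraction in (0, 1); edges must be present
#'   in strictly more than this fraction of pseudo-subjects.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a row-normalized [StructuralConnectome-class].
#' @examples
#' sc <- synthConnectome(nRegions = 12, seed = 1)
#' range(rowSums(weightMatrix(sc)))
#' @export
synthConnectome <- function(nRegions = 68, nPseudoSubjects = 100,
                            edgePresenceProb = 0.7,
                            consistencyThreshold = 0.6, seed = 1L) {
  stopifnot(nRegions >= 2, nPseudoSubjects >= 1,
            edgePresenceProb > 0, edgePresenceProb <= 1,
            consistencyThreshold > 0, consistencyThreshold < 1)
  nEdges <- nRegions * (nRegions - 1) / 2
  withr_seed(seed, {
    presence <- matrix(stats::runif(nEdges * nPseudoSubjects) <
                         edgePresenceProb, nEdges, nPseudoSubjects)
    w <- matrix(stats::rlnorm(nEdges * nPseudoSubjects, 0, 0.5),
                nEdges, nPseudoSubjects) * presence
    avg <- consensusEdges(presence, w, consistencyThreshold)
    mat <- matrix(0, nRegions, nRegions)
    mat[upper.tri(mat)] <- avg
    mat <- mat + t(mat)
    rs <- rowSums(mat)
    if (any(rs == 0))
      stop("region(s) with zero surviving edges: ",
           paste(which(rs == 0), collapse = ", "),
           "; increase edgePresenceProb or nPseudoSubjects")
    idx <- which(upper.tri(mat) & mat > 0, arr.ind = FALSE)
    vals <- mat[idx]
    mat[idx] <- gaussianResampleWeights(vals)
    mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
    labels <- sprintf("region_%02d", seq_len(nRegions))
    new("StructuralConnectome", weights = normalizeRows(mat),
        regionLabels = labels, normalized = TRUE)
  })
}

#' Read / write a connectome as tab-separated text
#'
#' The on-disk format is a TSV matrix with region labels as the header row
#' and first column. The reader validates squareness and nonnegativity.
#'
#' @param path file path.
#' @param x a [StructuralConnectome-class].
#' @return `readConnectome` returns a [StructuralConnectome-class];
#'   `writeConnectome` returns `path` invisibly.
#' @export
readConnectome <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("connectome file must be a square matrix")
  if (any(m < 0)) stop("connectome weights must be nonnegative")
  rs <- rowSums(m)
  new("StructuralConnectome", weights = unname(m),
      regionLabels = rownames(m),
      normalized = all(abs(rs - 1) <= 1e-9))
}

#' @rdname readConnectome
#' @export
writeConnectome <- function(x, path) {
  stopifnot(is(x, "StructuralConnectome"))
  m <- x@weights
  dimnames(m) <- list(x@regionLabels, x@regionLabels)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
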