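# Inclusive arithmetic sequence with a half-step tolerance at the top end.
seqInclusive <- function(start, stop, step) {
  if (step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be >= start")
  n <- floor((stop - start) / step + 0.5)
  start + step * (0:n)
}

#' Build the (A, G, F, M) search grid
#'
#' Each axis is an inclusive arithmetic sequence `start, start+step, ...`
#' extending up to `stop + step/2`; the Cartesian product is enumerated in
#' lexicographic (A, G, F, M) order. The default ranges are the search
#' intervals used for the depression cohort (A: -0.2..0.2 step 0.01,
#' G: 0.005..0.05 step 0.005, F: 0..1 step 0.1, M: 0.10..0.50 step 0.03),
#' which produce 41 x 10 x 11 x 14 = 63,140 combinations.
#'
#' @param aRange,gRange,fRange,mRange numeric triples (start, stop, step).
#' @return a [ParameterGrid-class].
#' @examples
#' nrow(gridPoints(buildParameterGrid()))  # 63140
#' @export
buildParameterGrid <- function(aRange = c(-0.2, 0.2, 0.01),
                               gRange = c(0.005, 0.05, 0.005),
                               fRange = c(0, 1, 0.1),
                               mRange = c(0.10, 0.50, 0.03)) {
  av <- seqInclusive(aRange[1], aRange[2], aRange[3])
  gv <- seqInclusive(gRange[1], gRange[2], gRange[3])
  fv <- seqInclusive(fRange[1], fRange[2], fRange[3])
  mv <- seqInclusive(mRange[1], mRange[2], mRange[3])
  pts <- expand.grid(M = mv, F = fv, G = gv, A = av,
                     KEEP.OUT.ATTRS = FALSE)[, c("A", "G", "F", "M")]
  rownames(pts) <- NULL
  new("ParameterGrid", points = pts,
      steps = c(A = aRange[3], G = gRange[3], F = fRange[3], M = mRange[3]))
}

#' Simulate every grid point
#'
#' For each grid point the full forward pipeline is run: network
#' simulation, BOLD extraction, band-pass filtering, Pearson FC, Fisher-z
#' transform; the trajectory's Kuramoto synchrony and metastability are
#' recorded alongside. Per-point noise seeds are derived deterministically
#' from the master seed in `config@seed` and the parameter values of the
#' point, so results do not depend on worker count, execution order, or
#' which other points the grid contains; two analyses sharing a master
#' seed evaluate the model identically at shared points. When `cacheDir` is
#' given, each point's result is cached on disk keyed by a content hash of
#' (grid point, connectome, intrinsic frequencies, config), and re-runs
#' reuse the cache.
#'
#' @param grid a [ParameterGrid-class].
#' @param connectome row-normalized [StructuralConnectome-class].
#' @param omega0 [IntrinsicFrequencies-class].
#' @param config [SimulationConfig-class]; its `seed` acts as master seed.
#' @param nWorkers parallel workers (forked; 1 = serial).
#' @param cacheDir optional directory for the on-disk bank cache.
#' @param beta noise SD applied at every grid point (default 0.02).
#' @param fLow,fHigh band-pass edges in Hz.
#' @return a [GridSimBank-class].
#' @export
simulateGrid <- function(grid, connectome, omega0, config, nWorkers = 1L,
                         cacheDir = NULL, beta = 0.02, fLow = 0.008,
                         fHigh = 0.1) {
  stopifnot(is(grid, "ParameterGrid"))
  pts <- gridPoints(grid)
  if (!is.null(cacheDir) && !dir.exists(cacheDir))
    dir.create(cacheDir, recursive = TRUE)
  simOne <- function(i) {
    p <- modelParameters(pts$A[i], pts$G[i], pts$F[i], pts$M[i], beta)
    key <- NULL
    if (!is.null(cacheDir)) {
      key <- contentHash(list(paramVector(p), weightMatrix(connectome),
                              omega0@omega0, config@dt, config@duration,
                              config@burnIn, config@sampleInterval,
                              config@seed, fLow, fHigh))
      f <- file.path(cacheDir, paste0(key, ".rds"))
      if (file.exists(f)) return(readRDS(f))
    }
    cfg <- config
    cfg@seed <- seedForPoint(config@seed, pts$A[i], pts$G[i], pts$F[i],
                             pts$M[i])
    traj <- withCallingHandlers(
      simulateNetwork(p, connectome, omega0, cfg),
      warning = function(w) invokeRestart("muffleWarning"))
    R <- kuramotoOrderSeries(traj)
    fc <- fisherZ(computeFc(bandpassDct(extractBold(traj), fLow, fHigh),
                            provenance = list(type = "simulated",
                                              params = p)))
    out <- list(fc = fc, synchrony = synchrony(R),
                metastability = metastability(R))
    if (!is.null(key))
      saveRDS(out, file.path(cacheDir, paste0(key, ".rds")))
    out
  }
  applyFun <- if (nWorkers > 1L)
    function(x, f) parallel::mclapply(x, f, mc.cores = nWorkers)
  else lapply
  res <- applyFun(seq_len(nrow(pts)), simOne)
  fcs <- lapply(res, `[[`, "fc")
  nUT <- length(upperTriValues(fcValues(fcs[[1]])))
  ut <- vapply(fcs, function(f) upperTriValues(fcValues(f)), numeric(nUT))
  new("GridSimBank", grid = grid, fcs = fcs,
      upperTri = matrix(ut, ncol = nrow(pts)),
      metrics = data.frame(
        synchrony = vapply(res, `[[`, numeric(1), "synchrony"),
        metastability = vapply(res, `[[`, numeric(1), "metastability")))
}

# Round-half-up used for Monte-Carlo subject counts.
roundHalfUp <- function(x) floor(x + 0.5)

#' Monte-Carlo nonparametric fit of the grid bank to a cohort
#'
#' In each iteration a fraction (`threshold`) of the subjects is drawn
#' without replacement, their Fisher-z FC maps are averaged, and the grid
#' point whose simulated FC has the highest upper-triangle correlation
#' with the average is recorded. 500 iterations are run per threshold
#' (30%, 50%, 70% by default) and the three distributions are pooled into
#' one multi-threshold distribution of 1500 selected parameter sets.
#' Subjects are put in a stable id-sorted order before drawing, so the
#' result is invariant to the input ordering of `subjectFcs`.
#'
#' @param bank a [GridSimBank-class].
#' @param subjectFcs list of subject [FCMatrix-class] in fisher_z space;
#'   names (or provenance subject ids) identify subjects.
#' @param thresholds fractions of the cohort drawn per iteration.
#' @param itersPerThreshold iterations per threshold.
#' @param seed integer seed for the subject draws.
#' @return a data.frame with one row per iteration: `iteration`,
#'   `threshold`, `bankIndex`, `A`, `G`, `F`, `M`, `similarity`.
#' @export
monteCarloFit <- function(bank, subjectFcs, thresholds = c(0.3, 0.5, 0.7),
                          itersPerThreshold = 500L, seed = 1L) {
  stopifnot(is(bank, "GridSimBank"), length(subjectFcs) > 0)
  if (!all(vapply(subjectFcs, function(f) f@space, character(1)) ==
           "fisher_z"))
    stop("subject FCs must be in fisher_z space")
  n <- length(subjectFcs)
  ids <- names(subjectFcs)
  if (is.null(ids))
    ids <- vapply(seq_along(subjectFcs), function(i) {
      sid <- subjectFcs[[i]]@provenance$subjectId
      if (is.null(sid) || is.na(sid)) sprintf("subject_%03d", i) else sid
    }, character(1))
  ord <- order(ids)
  subjectFcs <- subjectFcs[ord]
  subjUT <- vapply(subjectFcs, function(f) upperTriValues(fcValues(f)),
                   numeric(nrow(bank@upperTri)))
  pts <- gridPoints(bank@grid)
  bankUT <- bank@upperTri
  recs <- vector("list", length(thresholds))
  withr_seed(seed, {
    iterGlobal <- 0L
    for (ti in seq_along(thresholds)) {
      k <- roundHalfUp(thresholds[ti] * n)
      if (k < 2) stop("threshold ", thresholds[ti],
                      " selects fewer than 2 subjects")
      rows <- vector("list", itersPerThreshold)
      for (it in seq_len(itersPerThreshold)) {
        iterGlobal <- iterGlobal + 1L
        sel <- sample.int(n, k)
        g <- rowMeans(subjUT[, sel, drop = FALSE])
        sims <- as.vector(stats::cor(g, bankUT))
        best <- which.max(sims)
        if (sum(sims == sims[best]) > 1L)
          warning("similarity tie at iteration ", iterGlobal,
                  "; lexicographically smallest grid point kept")
        rows[[it]] <- data.frame(
          iteration = iterGlobal, threshold = thresholds[ti],
          bankIndex = best, A = pts$A[best], G = pts$G[best],
          F = pts$F[best], M = pts$M[best], similarity = sims[best])
      }
      recs[[ti]] <- do.call(rbind, rows)
    }
  })
  do.call(rbind, recs)
}

#' Detect the two modes of the pooled Monte-Carlo distribution
#'
#' The selected parameter sets (one per Monte-Carlo iteration) are scaled
#' by their axis step sizes and partitioned into two clusters by 2-means
#' with deterministic farthest-point initialization (the two most distant
#' distinct selected points seed the centers). Each cluster's
#' representative is its most frequently selected grid point (ties broken
#' toward the lexicographically smallest). DEP1 is the representative
#' whose simulation has the larger metastability, matching the observed
#' direction in which the first subtype exhibits higher metastability and
#' synchrony.
#'
#' @param records Monte-Carlo record data.frame from [monteCarloFit()].
#' @param bank the [GridSimBank-class] the records refer to.
#' @return a [SubtypeSolution-class].
#' @export
detectModes <- function(records, bank) {
  stopifnot(is.data.frame(records), is(bank, "GridSimBank"))
  idx <- records$bankIndex
  uniq <- sort(unique(idx))
  if (length(uniq) < 2L)
    stop("unimodal solution; no stratification possible")
  steps <- gridSteps(bank@grid)
  pts <- gridPoints(bank@grid)
  scaled <- as.matrix(pts[idx, c("A", "G", "F", "M")])
  scaled <- sweep(scaled, 2, steps[c("A", "G", "F", "M")], "/")
  uScaled <- as.matrix(pts[uniq, c("A", "G", "F", "M")])
  uScaled <- sweep(uScaled, 2, steps[c("A", "G", "F", "M")], "/")
  d <- as.matrix(stats::dist(uScaled))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  centers <- uScaled[c(far[1], far[2]), , drop = FALSE]
  km <- stats::kmeans(scaled, centers = centers, iter.max = 100L)
  rep_of <- function(cl) {
    members <- idx[km$cluster == cl]
    tab <- table(members)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)  # grid order is lexicographic, so min index = smallest point
  }
  r1 <- rep_of(1L); r2 <- rep_of(2L)
  if (r1 == r2)
    stop("mode detection collapsed onto a single grid point")
  met <- bank@metrics$metastability
  if (met[r2] > met[r1]) { tmp <- r1; r1 <- r2; r2 <- tmp }
  mk <- function(i) modelParameters(pts$A[i], pts$G[i], pts$F[i], pts$M[i])
  cl1 <- km$cluster[match(r1, idx)]
  cl2 <- km$cluster[match(r2, idx)]
  counts <- c(sum(km$cluster == cl1), sum(km$cluster == cl2))
  new("SubtypeSolution",
      paramsDep1 = mk(r1), paramsDep2 = mk(r2),
      fcDep1 = bank@fcs[[r1]], fcDep2 = bank@fcs[[r2]],
      modeCounts = as.integer(counts),
      metrics = data.frame(subtype = c("DEP1", "DEP2"),
                           synchrony = bank@metrics$synchrony[c(r1, r2)],
                           metastability = met[c(r1, r2)]),
      labelRule = "DEP1 = mode with larger simulated metastability")
}
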