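test_that("the default search grid enumerates 63,140 combinations", {
  g <- buildParameterGrid()
  pts <- gridPoints(g)
  expect_identical(nrow(pts), 63140L)
  expect_identical(length(unique(pts$A)), 41L)
  expect_identical(length(unique(pts$G)), 10L)
  expect_identical(length(unique(pts$F)), 11L)
  expect_identical(length(unique(pts$M)), 14L)
  # inclusive top with half-step tolerance: M stops at 0.49, not 0.50
  expect_equal(max(pts$M), 0.49)
  expect_equal(range(pts$A), c(-0.2, 0.2))
  # lexicographic (A, G, F, M) enumeration
  expect_false(is.unsorted(pts$A))
  first <- pts[pts$A == pts$A[1] & pts$G == pts$G[1] & pts$F == pts$F[1], ]
  expect_equal(first$M, sort(first$M))
})

test_that("degenerate and invalid grid ranges behave", {
  g <- buildParameterGrid(c(0.1, 0.1, 0.01), c(0.01, 0.01, 0.01),
                          c(0.5, 0.5, 0.1), c(0.2, 0.2, 0.03))
  expect_identical(nrow(gridPoints(g)), 1L)
  expect_error(buildParameterGrid(aRange = c(0, 1, 0)), "step")
  expect_error(buildParameterGrid(aRange = c(1, 0, 0.1)), "stop")
})

test_that("grid simulation: caching, determinism and regime contrast", {
  sc <- smallConnectome(8)
  om <- smallOmega(8)
  g <- buildParameterGrid(c(-0.1, 0.1, 0.2), c(0.01, 0.01, 0.01),
                          c(0.7, 0.7, 0.1), c(0.3, 0.3, 0.03))
  expect_identical(nrow(gridPoints(g)), 2L)
  d <- withr::local_tempdir()
  b1 <- simulateGrid(g, sc, om, quickConfig(seed = 6), cacheDir = d)
  b2 <- simulateGrid(g, sc, om, quickConfig(seed = 6), cacheDir = d)
  expect_identical(b1@upperTri, b2@upperTri)
  expect_identical(b1@metrics, b2@metrics)
  expect_length(list.files(d), 2L)
  # the two regimes (stable focus vs limit cycle) give different FCs
  expect_gt(max(abs(b1@upperTri[, 1] - b1@upperTri[, 2])), 0.05)
  # single-point grid gives a bank of size one
  g1 <- buildParameterGrid(c(0, 0, 0.01), c(0.01, 0.01, 0.01),
                           c(0.5, 0.5, 0.1), c(0.2, 0.2, 0.03))
  expect_length(simulateGrid(g1, sc, om, quickConfig())@fcs, 1L)
})

test_that("per-point seeds depend on the parameter point, not the grid", {
  sc <- smallConnectome(6)
  om <- smallOmega(6)
  wide <- buildParameterGrid(c(-0.1, 0.1, 0.2), c(0.01, 0.01, 0.01),
                             c(0.7, 0.7, 0.1), c(0.3, 0.3, 0.03))
  solo <- buildParameterGrid(c(0.1, 0.1, 0.2), c(0.01, 0.01, 0.01),
                             c(0.7, 0.7, 0.1), c(0.3, 0.3, 0.03))
  bw <- simulateGrid(wide, sc, om, quickConfig(seed = 3))
  bs <- simulateGrid(solo, sc, om, quickConfig(seed = 3))
  expect_identical(bw@upperTri[, 2], bs@upperTri[, 1])
})

test_that("Monte-Carlo fit selects exact matches with similarity 1", {
  g <- buildParameterGrid(c(-0.1, 0, 0.1), c(0.01, 0.01, 0.01),
                          c(0.5, 0.5, 0.1), c(0.2, 0.2, 0.03))
  bank <- makeBank(g, n = 10)
  # cohort of identical FCs equal to the second bank entry
  target <- bank@fcs[[2]]
  target@provenance <- list(type = "empirical", subjectId = NA_character_)
  fcs <- stats::setNames(rep(list(target), 8), sprintf("s%02d", 1:8))
  rec <- monteCarloFit(bank, fcs, itersPerThreshold = 20L, seed = 2)
  expect_identical(nrow(rec), 60L)
  expect_true(all(rec$bankIndex == 2L))
  expect_true(all(abs(rec$similarity - 1) < 1e-12))
  expect_identical(unique(rec$A), gridPoints(g)$A[2])
  # single-point bank: that point is always selected
  b1 <- makeBank(buildParameterGrid(c(0, 0, 1), c(0.01, 0.01, 1),
                                    c(0.5, 0.5, 1), c(0.2, 0.2, 1)), n = 10)
  r1 <- monteCarloFit(b1, fcs, itersPerThreshold = 5L, seed = 1)
  expect_true(all(r1$bankIndex == 1L))
  expect_true(all(r1$similarity >= -1 & r1$similarity <= 1))
})

test_that("Monte-Carlo fit is invariant to subject ordering", {
  g <- buildParameterGrid(c(-0.1, 0.1, 0.1), c(0.01, 0.01, 0.01),
                          c(0.5, 0.5, 0.1), c(0.2, 0.2, 0.03))
  bank <- makeBank(g, n = 8)
  fcs <- stats::setNames(lapply(1:9, function(i) randomFc(8, 40 + i)),
                         sprintf("s%02d", 1:9))
  r1 <- monteCarloFit(bank, fcs, itersPerThreshold = 25L, seed = 7)
  r2 <- monteCarloFit(bank, fcs[sample(9)], itersPerThreshold = 25L,
                      seed = 7)
  expect_identical(r1, r2)
})

test_that("subject draw sizes follow round-half-up of threshold x n", {
  g <- buildParameterGrid(c(0, 0, 1), c(0.01, 0.01, 1), c(0.5, 0.5, 1),
                          c(0.2, 0.2, 1))
  bank <- makeBank(g, n = 6)
  fcs <- stats::setNames(lapply(1:5, function(i) randomFc(6, 50 + i)),
                         sprintf("s%d", 1:5))
  # 0.3 * 5 = 1.5 rounds up to 2, the smallest legal draw
  rec <- monteCarloFit(bank, fcs, thresholds = 0.3,
                       itersPerThreshold = 3L, seed = 1)
  expect_identical(nrow(rec), 3L)
  expect_error(monteCarloFit(bank, fcs[1:3], thresholds = 0.3,
                             itersPerThreshold = 2L, seed = 1),
               "fewer than 2")
})

test_that("mode detection recovers two well-separated modes exactly", {
  g <- buildParameterGrid(c(-0.1, 0.1, 0.01), c(0.005, 0.05, 0.005),
                          c(0.5, 0.5, 0.1), c(0.2, 0.2, 0.03))
  np <- nrow(gridPoints(g))
  bank <- makeBank(g, n = 8, metast = seq(0.2, 0.01, length.out = np))
  iA <- 3L; iB <- np - 5L
  rec <- data.frame(iteration = 1:1500,
                    threshold = rep(c(0.3, 0.5, 0.7), each = 500),
                    bankIndex = rep(c(iA, iB), 750),
                    similarity = 0.5)
  pts <- gridPoints(g)
  rec$A <- pts$A[rec$bankIndex]; rec$G <- pts$G[rec$bankIndex]
  rec$F <- pts$F[rec$bankIndex]; rec$M <- pts$M[rec$bankIndex]
  sol <- detectModes(rec, bank)
  got <- rbind(paramVector(sol@paramsDep1)[1:4],
               paramVector(sol@paramsDep2)[1:4])
  want <- as.matrix(pts[c(iA, iB), c("A", "G", "F", "M")])
  # DEP1 is the higher-metastability representative (index iA here)
  expect_equal(unname(got[1, ]), unname(want[1, ]))
  expect_equal(unname(got[2, ]), unname(want[2, ]))
  expect_identical(sort(sol@modeCounts), c(750L, 750L))
  # record order must not matter
  sol2 <- detectModes(rec[sample(nrow(rec)), ], bank)
  expect_identical(paramVector(sol2@paramsDep1),
                   paramVector(sol@paramsDep1))
  # unimodal records refuse to stratify
  recU <- rec; recU$bankIndex <- iA
  expect_error(detectModes(recU, bank), "unimodal")
})
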