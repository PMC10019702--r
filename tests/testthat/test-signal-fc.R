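mkTs <- function(values, tr = 2) regionalTimeSeries(values, tr)

test_that("DCT band-pass keeps in-band and rejects out-of-band cosines", {
  # sample at the DCT's natural half-sample offsets so pure tones align
  # with single basis functions (the frequency-domain oracle)
  t <- ((0:209) + 0.5) * 2
  inBand <- mkTs(rbind(cos(2 * pi * 0.05 * t), sin(2 * pi * 0.02 * t)))
  out <- bandpassDct(inBand)
  # in-band passthrough: amplitude preserved up to edge leakage
  expect_gt(sd(out@values[1, ]) / sd(inBand@values[1, ]), 0.95)
  expect_gt(sd(out@values[2, ]) / sd(inBand@values[2, ]), 0.95)
  # 0.2 Hz is below Nyquist (0.25) but above the band: rejected; a slow
  # drift at 3/840 Hz (below 0.008) is rejected too
  hi <- mkTs(rbind(cos(2 * pi * 0.2 * t), cos(2 * pi * (3 / 840) * t)))
  outHi <- bandpassDct(hi)
  expect_lt(sd(outHi@values[1, ]) / sd(hi@values[1, ]), 0.05)
  expect_lt(sd(outHi@values[2, ]) / sd(hi@values[2, ]), 0.05)
  # constant series: mean removed entirely
  cst <- mkTs(matrix(3, 2, 64))
  expect_lt(max(abs(bandpassDct(cst)@values)), 1e-12)
  expect_error(bandpassDct(inBand, fHigh = 0.3), "Nyquist")
})

test_that("DCT band-pass is linear", {
  set.seed(1)
  x <- matrix(rnorm(2 * 100), 2)
  y <- matrix(rnorm(2 * 100), 2)
  fx <- bandpassDct(mkTs(x))@values
  fy <- bandpassDct(mkTs(y))@values
  fxy <- bandpassDct(mkTs(2 * x - 3 * y))@values
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9)
})

test_that("FC computation matches Pearson correlation limits", {
  a <- sin((1:50) / 3)
  fc <- computeFc(mkTs(rbind(a, a, -a)))
  v <- fcValues(fc)
  expect_equal(v[1, 2], 1)
  expect_equal(v[1, 3], -1)
  expect_equal(unname(diag(v)), rep(1, 3))
  expect_identical(fcSpace(fc), "raw")
  set.seed(2)
  big <- computeFc(mkTs(matrix(rnorm(2 * 10000), 2)))
  expect_lt(abs(fcValues(big)[1, 2]), 0.1)
  expect_error(computeFc(mkTs(rbind(a, rep(1, 50)))), "region.*2")
})

test_that("FC is invariant to positive affine rescaling of regions", {
  set.seed(3)
  x <- matrix(rnorm(4 * 60), 4)
  f1 <- fcValues(computeFc(mkTs(x)))
  f2 <- fcValues(computeFc(mkTs(x * c(2, 0.5, 10, 1) + c(-1, 3, 0, 7))))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("Fisher z transform matches arctanh and guards its space", {
  a <- sin((1:40) / 2)
  set.seed(4)
  fc <- computeFc(mkTs(rbind(a + rnorm(40, 0, 1), a + rnorm(40, 0, 1))))
  z <- fisherZ(fc)
  expect_identical(fcSpace(z), "fisher_z")
  expect_equal(fcValues(z)[1, 2], atanh(fcValues(fc)[1, 2]))
  expect_equal(diag(fcValues(z)), rep(0, 2))
  expect_error(fisherZ(z), "space")
  # worked value and odd symmetry
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  m <- new("FCMatrix", values = r, space = "raw")
  expect_equal(fcValues(fisherZ(m))[1, 2], 0.5493, tolerance = 1e-4)
  mneg <- new("FCMatrix", values = matrix(c(1, -0.5, -0.5, 1), 2),
              space = "raw")
  expect_equal(fcValues(fisherZ(mneg))[1, 2], -fcValues(fisherZ(m))[1, 2])
  # perfect correlations are clipped, not infinite
  mone <- new("FCMatrix", values = matrix(c(1, 1, 1, 1), 2), space = "raw")
  expect_true(all(is.finite(fcValues(fisherZ(mone)))))
})

test_that("FC similarity equals the upper-triangle correlation oracle", {
  a <- randomFc(4, 11)
  b <- randomFc(4, 12)
  expect_equal(fcSimilarity(a, a), 1)
  neg <- new("FCMatrix", values = -fcValues(a), space = "fisher_z")
  expect_equal(fcSimilarity(a, neg), -1)
  # brute-force oracle on the six free values of a 4x4 matrix
  ua <- fcValues(a)[upper.tri(fcValues(a))]
  ub <- fcValues(b)[upper.tri(fcValues(b))]
  expect_equal(fcSimilarity(a, b), cor(ua, ub))
  expect_error(fcSimilarity(a, randomFc(5, 13)), "dimension")
  expect_error(fcSimilarity(a, randomFc(4, 13, space = "raw")), "space")
  # self-similarity after the Fisher transform is exactly 1
  raw <- randomFc(6, 14, space = "raw")
  expect_equal(fcSimilarity(fisherZ(raw), fisherZ(raw)), 1)
})

test_that("group averaging is the entrywise mean with guards", {
  a <- randomFc(5, 21)
  b <- randomFc(5, 22)
  expect_equal(fcValues(groupAverageFc(list(a))), fcValues(a))
  neg <- new("FCMatrix", values = -fcValues(a), space = "fisher_z")
  expect_equal(max(abs(fcValues(groupAverageFc(list(a, neg))))), 0)
  expect_equal(fcValues(groupAverageFc(list(a, a, a))), fcValues(a))
  expect_equal(fcValues(groupAverageFc(list(a, b))),
               (fcValues(a) + fcValues(b)) / 2)
  expect_error(groupAverageFc(list()), "empty")
  expect_error(groupAverageFc(list(a, randomFc(5, 23, space = "raw"))),
               "fisher_z")
})

test_that("intrinsic frequency estimation finds spectral peaks", {
  t <- (0:299) * 2
  set.seed(5)
  x <- rbind(sin(2 * pi * 0.03 * t) + rnorm(300, 0, 0.1),
             sin(2 * pi * 0.02 * t) + rnorm(300, 0, 0.1))
  om <- estimateIntrinsicFrequencies(list(mkTs(x)))
  binWidth <- 2 * pi / (64 * 2)   # one Welch frequency bin, rad/s
  expect_lt(abs(om@omega0[1] - 2 * pi * 0.03), binWidth)
  expect_lt(abs(om@omega0[2] - 2 * pi * 0.02), binWidth)
  # identical subjects: the median equals the single-subject estimate
  om3 <- estimateIntrinsicFrequencies(list(mkTs(x), mkTs(x), mkTs(x)))
  expect_equal(om3@omega0, om@omega0)
  # white noise peaks stay inside the searched band by construction
  wn <- mkTs(matrix(rnorm(2 * 256), 2))
  omw <- estimateIntrinsicFrequencies(list(wn))
  expect_true(all(omw@omega0 >= 2 * pi * 0.008 - 1e-12 &
                    omw@omega0 <= 2 * pi * 0.1 + 1e-12))
})

test_that("time series and FC round-trip through TSV with sidecars", {
  d <- withr::local_tempdir()
  ts <- mkTs(matrix(rnorm(3 * 20), 3))
  ts@subjectId <- "sub-001"
  f <- file.path(d, "ts.tsv")
  writeTimeSeries(ts, f)
  back <- readTimeSeries(f)
  expect_equal(back@values, ts@values, tolerance = 1e-12)
  expect_identical(back@sampleInterval, 2)
  expect_identical(back@subjectId, "sub-001")
  fc <- randomFc(6, 31)
  g <- file.path(d, "fc.tsv")
  writeFc(fc, g)
  fcBack <- readFc(g)
  expect_equal(fcValues(fcBack), fcValues(fc), tolerance = 1e-12)
  expect_identical(fcSpace(fcBack), "fisher_z")
})
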