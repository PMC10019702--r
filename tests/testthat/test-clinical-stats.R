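test_that("2x2 chi-squared reproduces the worked allocation example", {
  res <- chi2Test2x2(matrix(c(10, 10, 10, 12), 2, byrow = TRUE))
  expect_equal(round(res$statistic, 2), 0.09)
  expect_identical(res$df, 1L)
  expect_gt(res$p, 0.75)
  # identical row proportions give exactly zero
  expect_equal(chi2Test2x2(matrix(c(5, 10, 10, 20), 2))$statistic, 0)
  expect_equal(chi2Test2x2(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  expect_error(chi2Test2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("chi-squared agrees with stats::chisq.test on random tables", {
  set.seed(10)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    got <- chi2Test2x2(tab)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

# Six-subject worked fixture with hand-computable sham medians.
sixSubjectCohort <- function() {
  df <- data.frame(
    id = sprintf("s%d", 1:6),
    treatment = rep(c("sham", "active"), each = 3),
    subtype = rep(c("DEP1", "DEP2"), 3),
    age = c(25, 30, 35, 40, 45, 50),
    sex = rep(c("M", "F"), 3))
  df$MADRS1_baseline <- c(4, 3, 5, 4, 2, 6)
  df$MADRS1_followup <- c(4, 1, 4, 2, 2, 3)
  df
}

test_that("change scores and improvement-vs-sham match hand computation", {
  out <- changeScores(sixSubjectCohort())
  # change = followup - baseline
  expect_equal(out$change$MADRS1, c(0, -2, -1, -2, 0, -3))
  # sham improvements: 0, 2, 1 -> median 1
  expect_equal(unname(out$shamMedian["MADRS1"]), 1)
  expect_equal(out$improvementVsSham$MADRS1, c(-1, 1, 0, 1, -1, 2))
  # an all-sham cohort is centered on its own median
  allSham <- sixSubjectCohort()
  allSham$treatment <- "sham"
  outS <- changeScores(allSham)
  expect_equal(median(outS$improvementVsSham$MADRS1), 0)
})

test_that("missing cells are dropped per item and counted", {
  df <- sixSubjectCohort()
  df$MADRS1_followup[2] <- NA
  expect_message(out <- changeScores(df), "1 subject-item")
  expect_identical(unname(out$droppedCounts["MADRS1"]), 1L)
  expect_true(is.na(out$change$MADRS1[2]))
})

fourCellCohort <- function(sizes = c(10, 10, 10, 12)) {
  data.frame(
    id = sprintf("p%02d", seq_len(sum(sizes))),
    treatment = rep(c("sham", "sham", "active", "active"), sizes),
    subtype = rep(c("DEP1", "DEP2", "DEP1", "DEP2"), sizes),
    age = 30, sex = "F")
}

test_that("balanced bootstrap equalizes subtype cells within arms", {
  co <- fourCellCohort()
  bal <- balancedBootstrap(co, seed = 4)
  tab <- table(bal$treatment, bal$subtype)
  expect_equal(unname(tab["active", ]), c(12, 12))
  expect_equal(unname(tab["sham", ]), c(10, 10))
  # resampled rows are copies of subjects from the same cell only
  extra <- bal[!(bal$id %in% co$id), ]
  base <- sub("_rep.*", "", extra$id)
  expect_true(all(base %in% co$id[co$treatment == "active" &
                                    co$subtype == "DEP1"]))
  # an already balanced cohort is returned with unchanged cell sizes
  even <- fourCellCohort(c(8, 8, 9, 9))
  expect_identical(nrow(balancedBootstrap(even, 1)), nrow(even))
  # determinism
  expect_identical(balancedBootstrap(co, seed = 4), bal)
  co0 <- co[co$subtype != "DEP2" | co$treatment != "active", ]
  expect_error(balancedBootstrap(co0, 1), "empty treatment x subtype")
})

test_that("logistic bootstrap recovers a known log-odds and flags
           separation", {
  set.seed(20)
  n <- 500
  # consistency oracle: mean ML estimate over independent datasets
  coefs <- vapply(1:10, function(r) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.2 + 1.0 * x))
    fit <- fitLogisticBootstrap(cbind(sym = x), y, nBoot = 50,
                                seed = r)
    log(fit$estimate)
  }, numeric(1))
  expect_lt(abs(mean(coefs) - 1.0), 0.2)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 1.0 * x))
  fit <- fitLogisticBootstrap(cbind(sym = x), y, nBoot = 200, seed = 1)
  expect_true(fit$ciLow < fit$estimate & fit$estimate < fit$ciHigh)
  # a perfectly separating predictor destabilizes every replicate
  ysep <- rep(0:1, each = 20)
  expect_error(fitLogisticBootstrap(cbind(v = as.numeric(ysep)), ysep,
                                    nBoot = 50, seed = 1),
               "unstable")
  expect_error(fitLogisticBootstrap(cbind(v = rnorm(4)), c(0, 0, 0, 1),
                                    nBoot = 10, seed = 1),
               "2 subjects per class")
})

test_that("null predictors give near-nominal odds-ratio coverage", {
  set.seed(30)
  hits <- 0L
  for (r in 1:25) {
    x <- rnorm(200)
    y <- rbinom(200, 1, 0.5)
    fit <- fitLogisticBootstrap(cbind(v = x), y, nBoot = 200,
                                seed = 100 + r)
    if (fit$ciLow <= 1 && 1 <= fit$ciHigh) hits <- hits + 1L
  }
  expect_gte(hits, 22L)  # >= 90% of repeats cover the null odds ratio
})

test_that("linear bootstrap detects an injected interaction at n = 42", {
  # the 10/10/10/12 design with residual SD 1 has asymptotic power 0.84
  # at effect 2.0 (noncentral-t oracle); the percentile bootstrap sits a
  # little below it (~0.78 over many repeats), so assert at 70%
  hits <- 0L
  ratios <- numeric(40)
  for (r in 1:40) {
    syn <- generateCohort(syntheticCohortSpec(simulateFc = FALSE,
                                              seed = 100 + r))
    co <- syn@cohort
    set.seed(r)
    inter <- as.numeric(co$treatment == "active" & co$subtype == "DEP2")
    change <- 2.0 * inter + rnorm(nrow(co), 0, 1)
    base <- rowSums(co[, paste0(sprintf("MADRS%d", 1:9), "_baseline")])
    fit <- fitLinearBootstrap(change, co$treatment, co$subtype,
                              baseline = base, co$age,
                              co$sex, nBoot = 400, seed = r)
    ci <- c(fit$interaction$ciLow, fit$interaction$ciHigh)
    if (ci[1] > 0 || ci[2] < 0) hits <- hits + 1L
    # independent oracle: asymptotic OLS interval from lm()
    lmf <- lm(change ~ tr * st + base + age + sex, data.frame(
      change, tr = factor(co$treatment, c("sham", "active")),
      st = factor(co$subtype, c("DEP1", "DEP2")), base, age = co$age,
      sex = co$sex))
    sm <- summary(lmf)$coefficients["tractive:stDEP2", ]
    asympW <- 2 * qt(0.975, lmf$df.residual) * sm["Std. Error"]
    ratios[r] <- (ci[2] - ci[1]) / asympW
  }
  expect_gte(hits, 28L)  # 70% floor under the measured ~0.78 power
  # bootstrap intervals agree with the asymptotic oracle in width
  expect_gt(median(ratios), 0.7)
  expect_lt(median(ratios), 1.3)
})

test_that("linear bootstrap degenerate cases", {
  co <- fourCellCohort()
  set.seed(8)
  co$age <- rnorm(nrow(co), 30, 5)
  co$sex <- rep(c("M", "F"), length.out = nrow(co))
  fit <- fitLinearBootstrap(rep(3, nrow(co)), co$treatment, co$subtype,
                            baseline = rnorm(nrow(co)), co$age, co$sex,
                            nBoot = 50, seed = 1)
  expect_equal(fit$interaction$estimate, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["age"]), 0, tolerance = 1e-10)
  # collinear design errors out before bootstrapping
  expect_error(fitLinearBootstrap(rnorm(42), co$treatment, co$subtype,
                                  baseline = co$age, co$age, co$sex,
                                  nBoot = 10, seed = 1),
               "rank-deficient")
})

test_that("nested ANOVA isolates subtype-within-treatment signal", {
  set.seed(40)
  n <- 400
  treatment <- rep(c("sham", "active"), each = n / 2)
  subtype <- rep(c("DEP1", "DEP2"), n / 2)
  age <- rnorm(n, 30, 5)
  sex <- sample(c("M", "F"), n, TRUE)
  # subtype difference inside the active arm only, essentially no noise
  change <- ifelse(treatment == "active" & subtype == "DEP2", 5, 0) +
    rnorm(n, 0, 0.1)
  res <- nestedAnova(change, treatment, subtype, age, sex)
  expect_identical(res$df1, 2L)
  expect_gt(res$F, 100)
  expect_lt(res$p, 1e-10)
  expect_identical(res$df2, as.integer(n - 6))
  co <- fourCellCohort()
  co$sex <- rep(c("M", "F"), length.out = nrow(co))
  co$subtype[co$treatment == "active"] <- "DEP1"
  expect_error(nestedAnova(rnorm(42), co$treatment, co$subtype, co$age,
                           co$sex),
               "both subtypes")
})
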