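#' Symptom item catalog
#'
#' The behavioral battery of the trial: the self-rated depression scale
#' MADRS-S (9 items, each 0-6), the affective subscale of the Brief
#' Psychiatric Rating Scale BPRS-AFF (5 items, 0-7), the negative-symptom
#' interview CAINS (13 items, 0-4), and the Trail Making Test parts A and
#' B analyzed on a log-seconds scale. Higher scores mean more severe
#' symptoms on every scale, so improvement is minus the change score.
#'
#' @return data.frame with columns `item`, `scale`, `min`, `max`
#'   (`min`/`max` are `NA` for the continuous TMT measures).
#' @export
itemCatalog <- function() {
  rbind(
    data.frame(item = sprintf("MADRS%d", 1:9), scale = "MADRS-S",
               min = 0, max = 6),
    data.frame(item = sprintf("BPRSAFF%d", 1:5), scale = "BPRS-AFF",
               min = 0, max = 7),
    data.frame(item = sprintf("CAINS%d", 1:13), scale = "CAINS",
               min = 0, max = 4),
    data.frame(item = c("TMTA", "TMTB"), scale = "TMT",
               min = NA_real_, max = NA_real_)
  )
}

#' Validate a cohort table
#'
#' Checks the behavioral table schema: unique subject ids, treatment in
#' `active`/`sham`, subtype in `DEP1`/`DEP2`, sex in `M`/`F`, and every
#' ordinal item (columns `<item>_baseline`, `<item>_followup`) within its
#' scale range. Missing values are allowed.
#'
#' @param cohort data.frame.
#' @return the cohort, invisibly, or an error.
#' @export
validateCohortTable <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("id", "treatment", "subtype", "age", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("duplicate subject ids")
  if (!all(cohort$treatment %in% c("active", "sham")))
    stop("treatment must be 'active' or 'sham'")
  if (!all(cohort$subtype %in% c("DEP1", "DEP2", NA)))
    stop("subtype must be 'DEP1' or 'DEP2'")
  if (!all(cohort$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  cat_ <- itemCatalog()
  for (i in seq_len(nrow(cat_))) {
    if (is.na(cat_$min[i])) next
    for (ses in c("baseline", "followup")) {
      col <- paste0(cat_$item[i], "_", ses)
      if (!col %in% names(cohort)) next
      v <- cohort[[col]]
      bad <- !is.na(v) & (v < cat_$min[i] | v > cat_$max[i])
      if (any(bad))
        stop("values out of range in ", col, ": rows ",
             paste(which(bad), collapse = ", "))
    }
  }
  invisible(cohort)
}

#' Pearson chi-squared test for a 2x2 contingency table
#'
#' Plain Pearson statistic \eqn{\sum (O-E)^2/E} with expectations from
#' the marginal products, no continuity correction, df = 1. On the
#' trial's treatment-by-subtype allocation (10/10 sham, 10/12 active)
#' this gives the printed chi-squared of 0.09.
#'
#' @param tab 2x2 nonnegative integer matrix.
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chi2Test2x2(matrix(c(10, 10, 10, 12), 2, byrow = TRUE))
#' @export
chi2Test2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all marginals must be positive")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Item columns present in a cohort for both sessions.
presentItems <- function(cohort) {
  it <- itemCatalog()$item
  it[paste0(it, "_baseline") %in% names(cohort) &
       paste0(it, "_followup") %in% names(cohort)]
}

#' Per-item change scores and improvement against the sham median
#'
#' For every item, `change = followup - baseline`. Because higher scores
#' mean more severe symptoms, per-subject improvement is `-change`; the
#' improvement-vs-sham score subtracts, per item, the median improvement
#' of the sham group (computed over all sham subjects with data on that
#' item). Subjects missing either session for an item are dropped for
#' that item and the dropped counts are reported.
#'
#' @param cohort validated cohort data.frame.
#' @return list with data.frames `change` and `improvementVsSham` (columns
#'   `id`, `treatment`, `subtype`, one column per item), the per-item sham
#'   medians `shamMedian`, and `droppedCounts`.
#' @export
changeScores <- function(cohort) {
  validateCohortTable(cohort)
  items <- presentItems(cohort)
  if (length(items) == 0L) stop("no item columns with both sessions found")
  base <- cohort[, c("id", "treatment", "subtype")]
  change <- base; improv <- base
  shamMedian <- stats::setNames(numeric(length(items)), items)
  dropped <- stats::setNames(integer(length(items)), items)
  for (it in items) {
    ch <- cohort[[paste0(it, "_followup")]] -
      cohort[[paste0(it, "_baseline")]]
    dropped[it] <- sum(is.na(ch))
    imp <- -ch
    med <- stats::median(imp[cohort$treatment == "sham"], na.rm = TRUE)
    shamMedian[it] <- med
    change[[it]] <- ch
    improv[[it]] <- imp - med
  }
  if (sum(dropped) > 0)
    message(sum(dropped), " subject-item cells dropped for missing data")
  list(change = change, improvementVsSham = improv,
       shamMedian = shamMedian, droppedCounts = dropped)
}

#' Balance subtype cells within treatment arms by resampling
#'
#' Within each treatment arm, the smaller subtype cell is topped up by
#' resampling its own subjects with replacement until both cells have the
#' size of the larger cell (e.g. 10/10/10/12 becomes 10/10/12/12).
#' Resampled rows duplicate original subjects; their ids are suffixed to
#' keep the table's ids unique. Deterministic given `seed`.
#'
#' @param cohort validated cohort data.frame.
#' @param seed integer seed.
#' @return a resampled cohort data.frame.
#' @export
balancedBootstrap <- function(cohort, seed = 1L) {
  validateCohortTable(cohort)
  cells <- split(seq_len(nrow(cohort)),
                 list(cohort$treatment, cohort$subtype), drop = FALSE)
  if (any(lengths(cells) == 0L))
    stop("empty treatment x subtype cell: ",
         paste(names(cells)[lengths(cells) == 0], collapse = ", "))
  extra <- integer(0)
  withr_seed(seed, {
    for (arm in c("active", "sham")) {
      armCells <- cells[paste(arm, c("DEP1", "DEP2"), sep = ".")]
      target <- max(lengths(armCells))
      for (cell in armCells) {
        k <- target - length(cell)
        if (k > 0)
          extra <- c(extra, sample(cell, k, replace = TRUE))
      }
    }
  })
  out <- rbind(cohort, cohort[extra, , drop = FALSE])
  out$id <- make.unique(as.character(out$id), sep = "_rep")
  rownames(out) <- NULL
  out
}

# Fit a logistic model, flagging non-convergence and separation.
fitLogisticOnce <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(maxit = 100,
                                                epsilon = 1e-8)))
  mu <- fit$fitted.values
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8)
  list(coef = fit$coefficients, converged = fit$converged,
       separated = separated)
}

#' Logistic model of subtype on symptom items with bootstrap CIs
#'
#' Maximum-likelihood logistic regression (IRLS, at most 100 iterations,
#' tolerance 1e-8) of a binary subtype outcome on a matrix of per-subject
#' item scores, with nonparametric bootstrap of the subjects: each
#' replicate resamples subjects with replacement, refits, and records the
#' odds ratios `exp(coef)`. Replicates that fail to converge or show
#' complete separation are dropped and counted. 95% CIs are percentile.
#'
#' @param items numeric matrix (subjects x items), column names label the
#'   items.
#' @param subtype binary vector (0/1 or a two-level factor).
#' @param nBoot number of bootstrap replicates.
#' @param seed integer seed.
#' @return data.frame, one row per item: `term`, `estimate` (odds ratio),
#'   `ciLow`, `ciHigh`, `nBoot`, `dropped`.
#' @export
fitLogisticBootstrap <- function(items, subtype, nBoot = 1000L, seed = 1L) {
  X <- as.matrix(items)
  if (is.null(colnames(X))) colnames(X) <- sprintf("item%d", seq_len(ncol(X)))
  y <- if (is.factor(subtype)) as.integer(subtype) - 1L
       else as.integer(subtype)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (min(table(y)) < 2L) stop("need at least 2 subjects per class")
  orig <- fitLogisticOnce(X, y)
  n <- nrow(X)
  p <- ncol(X)
  boots <- matrix(NA_real_, nBoot, p)
  droppedN <- 0L
  withr_seed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) { droppedN <- droppedN + 1L; next }
      fit <- tryCatch(fitLogisticOnce(X[idx, , drop = FALSE], y[idx]),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged || fit$separated ||
          any(is.na(fit$coef))) {
        droppedN <- droppedN + 1L
        next
      }
      boots[b, ] <- exp(fit$coef[-1])
    }
  })
  if (droppedN > nBoot / 2)
    stop("unstable model: ", droppedN, " of ", nBoot,
         " bootstrap replicates dropped")
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  data.frame(term = colnames(X), estimate = exp(orig$coef[-1]),
             ciLow = ci[1, ], ciHigh = ci[2, ], nBoot = nBoot,
             dropped = droppedN, row.names = NULL)
}

#' Linear model of a change score with bootstrap CI for the
#' treatment-by-subtype interaction
#'
#' Ordinary least squares of
#' `change ~ treatment + subtype + treatment:subtype + baseline + age +
#' sex`, with nonparametric bootstrap of the subjects and percentile 95%
#' CIs of the coefficients. Rank-deficient replicates are dropped and
#' counted. The interaction coefficient is the quantity of interest: a CI
#' excluding 0 indicates a subtype-dependent treatment effect.
#'
#' @param change numeric outcome (follow-up minus baseline).
#' @param treatment factor/character, `active` or `sham`.
#' @param subtype factor/character, `DEP1` or `DEP2`.
#' @param baseline numeric baseline score covariate.
#' @param age numeric. @param sex character `M`/`F`.
#' @param nBoot bootstrap replicates. @param seed integer seed.
#' @return list with `interaction` (data.frame: term, estimate, ciLow,
#'   ciHigh, bootMedian, nBoot, dropped) and `coefficients` (the original
#'   OLS fit's coefficients).
#' @export
fitLinearBootstrap <- function(change, treatment, subtype, baseline, age,
                               sex, nBoot = 1000L, seed = 1L) {
  df <- data.frame(change = change,
                   treatment = factor(treatment, c("sham", "active")),
                   subtype = factor(subtype, c("DEP1", "DEP2")),
                   baseline = baseline, age = age,
                   sex = factor(sex, c("F", "M")))
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  X <- stats::model.matrix(
    ~ treatment + subtype + treatment:subtype + baseline + age + sex, df)
  y <- df$change
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design on the original sample")
  beta <- qr.coef(qr(X), y)
  interName <- "treatmentactive:subtypeDEP2"
  n <- nrow(X)
  boots <- rep(NA_real_, nBoot)
  droppedN <- 0L
  withr_seed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      qb <- qr(Xb)
      if (qb$rank < p) { droppedN <- droppedN + 1L; next }
      boots[b] <- qr.coef(qb, y[idx])[interName]
    }
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  list(
    interaction = data.frame(
      term = "treatment:subtype", estimate = unname(beta[interName]),
      ciLow = unname(ci[1]), ciHigh = unname(ci[2]),
      bootMedian = stats::median(boots, na.rm = TRUE),
      nBoot = nBoot, dropped = droppedN),
    coefficients = beta)
}

#' Nested ANOVA: subtype nested within treatment
#'
#' Linear model of a change score with a treatment main effect and the
#' depression subtype nested within treatment (two nested parameters),
#' controlling for age and sex. Returns the F-test of the nested term
#' (df1 = 2; df2 = residual degrees of freedom of the full model).
#'
#' @inheritParams fitLinearBootstrap
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
nestedAnova <- function(change, treatment, subtype, age, sex) {
  df <- data.frame(change = change,
                   treatment = factor(treatment, c("sham", "active")),
                   subtype = factor(subtype, c("DEP1", "DEP2")),
                   age = age, sex = factor(sex, c("F", "M")))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  tab <- table(df$treatment, df$subtype)
  if (any(tab == 0)) stop("each treatment arm must contain both subtypes")
  full <- stats::lm(change ~ age + sex + treatment + treatment:subtype,
                    data = df)
  reduced <- stats::lm(change ~ age + sex + treatment, data = df)
  an <- stats::anova(reduced, full)
  list(F = an$F[2], df1 = as.integer(an$Df[2]),
       df2 = as.integer(full$df.residual), p = an$`Pr(>F)`[2])
}
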