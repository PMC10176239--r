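#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation with a two-sided p-value from the
#' t-distribution on n - 2 degrees of freedom. Incomplete pairs are dropped
#' and the n actually used is reported.
#'
#' @param x,y numeric vectors of equal length.
#' @return A `correlation_result`: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) fail("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) fail("need >= 3 complete pairs, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) fail("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, P = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' ANCOVA group comparison with covariate adjustment
#'
#' Ordinary least-squares fit of `dep ~ group + covariates` with partial
#' (Type-III) F tests for every term, obtained by comparing the residual sum
#' of squares of the full model against the model with that term removed.
#' With a two-level group and continuous covariates and no interactions,
#' this matches the SPSS Type-III ANCOVA table. Adjusted group means are
#' the model predictions for each group at the covariate grand means
#' (identical to `emmeans` estimates for this design).
#'
#' @param dep numeric response.
#' @param group factor or character with exactly two levels.
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (e.g. age).
#' @return An `ancova_result`: `f_group`, `p_group`, per-covariate `f`/`p`,
#'   `df` (numerator, denominator), `adjusted_means`, `raw_means`,
#'   `raw_sds`, `n`.
#' @export
ancova_group <- function(dep, group, covariates) {
  covariates <- as.data.frame(covariates)
  if (is.null(names(covariates)) || any(names(covariates) == ""))
    names(covariates) <- paste0("cov", seq_along(covariates))
  if (length(dep) != length(group) || nrow(covariates) != length(dep))
    fail("dep, group and covariates must have matching length")
  dat <- data.frame(dep = dep, group = factor(group), covariates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (nlevels(droplevels(dat$group)) != 2L) fail("group must have exactly two levels")
  dat$group <- droplevels(dat$group)
  n <- nrow(dat)
  p_par <- 2L + ncol(covariates)
  if (n <= p_par + 1L) fail("too few complete cases (%d) for the model", n)
  full <- lm(dep ~ ., data = dat)
  if (any(is.na(coef(full))))
    fail("singular design: %s",
         paste(names(coef(full))[is.na(coef(full))], collapse = ", "))
  dfres <- df.residual(full)
  rss_full <- sum(resid(full)^2)
  part <- function(term) {
    keep <- setdiff(c("group", names(covariates)), term)
    red <- if (length(keep) == 0L) lm(dep ~ 1, data = dat)
    else lm(stats::reformulate(keep, response = "dep"), data = dat)
    rss_red <- sum(resid(red)^2)
    if (rss_red <= .Machine$double.eps * sum((dat$dep - mean(dat$dep))^2))
      return(list(f = 0, p = 1))      # nothing left for the term to explain
    if (rss_full <= .Machine$double.eps * rss_red)
      return(list(f = Inf, p = 0))    # exact separation of residuals
    f <- max(0, (rss_red - rss_full) / 1 / (rss_full / dfres))
    list(f = f, p = pf(f, 1, dfres, lower.tail = FALSE))
  }
  pg <- part("group")
  cov_tests <- lapply(names(covariates), part)
  names(cov_tests) <- names(covariates)
  nd <- data.frame(group = factor(levels(dat$group), levels(dat$group)))
  for (cv in names(covariates)) nd[[cv]] <- mean(dat[[cv]])
  adj <- setNames(predict(full, newdata = nd), levels(dat$group))
  raw_m <- tapply(dat$dep, dat$group, mean)
  raw_s <- tapply(dat$dep, dat$group, sd)
  structure(list(
    f_group = pg$f, p_group = pg$p,
    covariate_tests = cov_tests,
    f_age = if ("age" %in% names(cov_tests)) cov_tests$age$f else NULL,
    p_age = if ("age" %in% names(cov_tests)) cov_tests$age$p else NULL,
    df = c(1L, dfres),
    adjusted_means = adj, raw_means = raw_m, raw_sds = raw_s, n = n
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: F(%d,%d) group = %.3f, P = %.4g (n = %d)\n",
              x$df[1], x$df[2], x$f_group, x$p_group, x$n))
  for (nm in names(x$covariate_tests))
    cat(sprintf("  %s: F = %.3f, P = %.4g\n", nm,
                x$covariate_tests[[nm]]$f, x$covariate_tests[[nm]]$p))
  cat("  adjusted means:", paste(sprintf("%s = %.4f", names(x$adjusted_means),
                                         x$adjusted_means), collapse = ", "), "\n")
  invisible(x)
}

#' Multiple linear regression with standardized coefficients
#'
#' OLS on the raw scale with listwise deletion; standardized coefficients
#' (SPSS "Beta") from the identity `b_std = b_raw * SD(x)/SD(y)`;
#' per-predictor two-sided t-tests; and partial-regression (added-variable)
#' residual pairs for each predictor, for partial-regression plots.
#'
#' @param dep numeric response.
#' @param predictors data.frame or named matrix of numeric predictors.
#' @param kappa_max condition-number threshold above which the design is
#'   declared collinear.
#' @return A `regression_result`: `r_squared`, `f_overall`, `p_overall`,
#'   `coefficients` (data.frame: predictor, b_raw, b_std, se, t, p),
#'   `n`, `partial_residuals` (named list of data.frames `x`, `y`).
#' @export
multiple_regression <- function(dep, predictors, kappa_max = 1e8) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    fail("predictors must be named")
  if (nrow(predictors) != length(dep)) fail("dep and predictors lengths differ")
  dat <- data.frame(dep = dep, predictors)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  k <- ncol(predictors)
  if (n <= k + 2L) fail("too few complete cases (%d) for %d predictors", n, k)
  X <- as.matrix(dat[, names(predictors), drop = FALSE])
  Xs <- scale(X)
  if (any(attr(Xs, "scaled:scale") == 0))
    fail("constant predictor(s): %s",
         paste(names(predictors)[attr(Xs, "scaled:scale") == 0], collapse = ", "))
  kp <- kappa(cbind(1, Xs), exact = TRUE)
  if (kp > kappa_max) {
    cm <- abs(cor(X))
    diag(cm) <- 0
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    fail("collinear predictors (condition number %.3g): %s",
         kp, paste(names(predictors)[worst], collapse = ", "))
  }
  fit <- lm(dep ~ ., data = dat)
  sm <- summary(fit)
  b_raw <- coef(fit)[-1L]
  b_std <- b_raw * apply(X, 2L, sd) / sd(dat$dep)
  coefs <- data.frame(
    predictor = names(predictors),
    b_raw = unname(b_raw),
    b_std = unname(b_std),
    se = sm$coefficients[-1L, "Std. Error"],
    t = sm$coefficients[-1L, "t value"],
    p = sm$coefficients[-1L, "Pr(>|t|)"],
    row.names = NULL
  )
  fstat <- sm$fstatistic
  partials <- lapply(names(predictors), function(v) {
    others <- setdiff(names(predictors), v)
    if (length(others) == 0L) {
      data.frame(x = dat[[v]] - mean(dat[[v]]), y = dat$dep - mean(dat$dep))
    } else {
      fy <- lm(stats::reformulate(others, response = "dep"), data = dat)
      fx <- lm(stats::reformulate(others, response = v), data = dat)
      data.frame(x = resid(fx), y = resid(fy))
    }
  })
  names(partials) <- names(predictors)
  structure(list(
    r_squared = sm$r.squared,
    f_overall = unname(fstat[1L]),
    p_overall = pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE),
    coefficients = coefs, n = n, partial_residuals = partials,
    fit = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Multiple regression: R^2 = %.3f, F = %.3f, P = %.4g, n = %d\n",
              x$r_squared, x$f_overall, x$p_overall, x$n))
  for (i in seq_len(nrow(x$coefficients)))
    cat(sprintf("  %s: b = %.3f (std %.3f), P = %.4g\n",
                x$coefficients$predictor[i], x$coefficients$b_raw[i],
                x$coefficients$b_std[i], x$coefficients$p[i]))
  invisible(x)
}

#' Full cohort statistical report
#'
#' Runs the standard battery for a two-group glymphatic cohort table:
#' demographic t-test (age) and chi-square (sex); age-adjusted ANCOVA group
#' comparisons of the ALPS index, PVS measures (volume, count, score),
#' white-matter integrity (ROI-mean FA/MD if present) and NfL; Pearson
#' correlations among injury features, imaging metrics and NfL; and the
#' multiple regression of NfL on ALPS index, PVS volume and age within the
#' TBI group.
#'
#' @param table a cohort data.frame with at least columns `group`, `age`,
#'   `sex`, `alps_mean`, `pvs_volume`, `pvs_count`, `pvs_score`; optional
#'   `nfl`, `gcs`, `days_since_injury`, `fa_proj`, `md_proj`.
#' @return A `cohort_report` list.
#' @export
group_compare <- function(table) {
  req <- c("group", "age", "sex", "alps_mean", "pvs_volume", "pvs_count",
           "pvs_score")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0L)
    fail("cohort table lacks required columns: %s",
         paste(missing_cols, collapse = ", "))
  g <- factor(table$group)
  if (nlevels(g) != 2L) fail("group must have exactly two levels")
  demo <- list()
  demo$age_ttest <- t.test(age ~ group, data = table)
  sex_tab <- table(table$group, table$sex)
  demo$sex_chisq <- if (ncol(sex_tab) < 2L) {
    list(statistic = c(`X-squared` = 0), p.value = 1)
  } else suppressWarnings(chisq.test(sex_tab, correct = FALSE))
  anc_vars <- intersect(c("alps_mean", "pvs_volume", "pvs_count", "pvs_score",
                          "fa_proj", "fa_assoc", "md_proj", "md_assoc", "nfl"),
                        names(table))
  ancova <- lapply(anc_vars, function(v) {
    tryCatch(ancova_group(table[[v]], table$group, data.frame(age = table$age)),
             error = function(e) e$message)
  })
  names(ancova) <- anc_vars
  ## correlations of injury features with imaging and NfL (TBI only where
  ## the feature is TBI-specific)
  tbi_level <- if ("tbi" %in% levels(g)) "tbi" else levels(g)[1]
  tbi <- table[table$group == tbi_level, , drop = FALSE]
  cor_pairs <- list()
  feats <- intersect(c("gcs", "days_since_injury"), names(tbi))
  outs <- intersect(c("alps_mean", "pvs_volume", "pvs_count", "pvs_score", "nfl"),
                    names(tbi))
  for (f in feats) for (o in outs) {
    res <- tryCatch(pearson(tbi[[f]], tbi[[o]]), error = function(e) NULL)
    if (!is.null(res)) cor_pairs[[paste(f, o, sep = "_vs_")]] <- res
  }
  for (o in setdiff(outs, "alps_mean")) {
    res <- tryCatch(pearson(table$alps_mean, table[[o]]), error = function(e) NULL)
    if (!is.null(res)) cor_pairs[[paste("alps_mean", o, sep = "_vs_")]] <- res
  }
  if ("pvs_count" %in% names(table)) {
    res <- tryCatch(pearson(table$pvs_volume, table$pvs_count),
                    error = function(e) NULL)
    if (!is.null(res)) cor_pairs[["pvs_volume_vs_pvs_count"]] <- res
  }
  nfl_regression <- NULL
  if ("nfl" %in% names(tbi)) {
    nfl_regression <- tryCatch(
      multiple_regression(tbi$nfl,
                          data.frame(alps = tbi$alps_mean,
                                     pvs_volume = tbi$pvs_volume,
                                     age = tbi$age)),
      error = function(e) e$message)
  }
  structure(list(demographics = demo, ancova = ancova,
                 correlations = cor_pairs, nfl_regression = nfl_regression,
                 n = c(table(g))),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report (n =", paste(sprintf("%s: %d", names(x$n), x$n),
                                  collapse = ", "), ")\n")
  cat(sprintf("  age t-test P = %.3g; sex chi-square = %.3f, P = %.3g\n",
              x$demographics$age_ttest$p.value,
              unname(x$demographics$sex_chisq$statistic),
              x$demographics$sex_chisq$p.value))
  cat("  age-adjusted group comparisons:\n")
  for (v in names(x$ancova)) {
    a <- x$ancova[[v]]
    if (is.character(a)) cat(sprintf("    %s: (%s)\n", v, a))
    else cat(sprintf("    %s: F(%d,%d) = %.3f, P = %.4g\n",
                     v, a$df[1], a$df[2], a$f_group, a$p_group))
  }
  if (inherits(x$nfl_regression, "regression_result")) {
    cat("  NfL regression (TBI group):\n")
    r <- x$nfl_regression
    cat(sprintf("    R^2 = %.3f, F = %.3f, P = %.4g, n = %d\n",
                r$r_squared, r$f_overall, r$p_overall, r$n))
    for (i in seq_len(nrow(r$coefficients)))
      cat(sprintf("    %s: beta = %.3f, P = %.4g\n",
                  r$coefficients$predictor[i], r$coefficients$b_std[i],
                  r$coefficients$p[i]))
  }
  invisible(x)
}
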