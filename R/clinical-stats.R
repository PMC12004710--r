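# Cross-cohort comparison and survival plumbing. The two-cohort gene
# frequency comparison uses the two-sided Fisher exact test (sum of
# hypergeometric table probabilities <= the observed table's) with BH
# adjustment across genes and the adjusted-p < 0.1 significance cutoff.
# Cox, Kaplan-Meier/log-rank and logistic models are delegated to the
# survival package and stats::glm; multivariable Cox models are gated on all
# variables having VIF < 5.

#' Two-cohort Fisher/BH comparison table
#'
#' Per gene, a two-sided Fisher exact test of mutant/total counts between two
#' cohorts, BH adjustment across genes, and a significance flag at adjusted
#' p < `alpha`.
#'
#' @param tab data.frame with columns `gene`, `mut_a`, `total_a`, `mut_b`,
#'   `total_b`.
#' @param alpha adjusted-p significance cutoff (default 0.1).
#' @return data.frame gene, counts, p, p_adj, significant.
#' @export
fisherCohortTable <- function(tab, alpha = 0.1) {
  requireColumns(tab, c("gene", "mut_a", "total_a", "mut_b", "total_b"),
                 "cohort comparison table")
  if (any(tab$mut_a > tab$total_a | tab$mut_b > tab$total_b))
    stop("mutant count exceeds cohort total", call. = FALSE)
  p <- vapply(seq_len(nrow(tab)), function(i) {
    m <- matrix(c(tab$mut_a[i], tab$total_a[i] - tab$mut_a[i],
                  tab$mut_b[i], tab$total_b[i] - tab$mut_b[i]),
                2L, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
  out <- tab
  out$p <- p
  out$p_adj <- bhAdjust(p)
  out$significant <- out$p_adj < alpha
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with enforced monotonicity; invariant to input order and
#' idempotent (adjusting an already-adjusted monotone vector never lowers
#' any value). Inputs outside \[0, 1\] are an error.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Variance inflation factors
#'
#' VIF of each column of a model matrix: `1 / (1 - R^2)` of the regression
#' of that column on the others. Perfectly collinear columns give infinite
#' VIF.
#'
#' @param X numeric model matrix (no intercept column).
#' @return named numeric vector.
#' @export
varianceInflation <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      max(sum((X[, j] - mean(X[, j]))^2), 1e-300)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Survival and recurrence models
#'
#' Univariate Cox per covariate, a multivariable Cox model gated on all
#' variables having VIF < `vif_cutoff` (rejected with the offending
#' variables named otherwise), Kaplan-Meier + log-rank per grouping
#' covariate, and logistic regression for recurrence within
#' `logistic_horizon` months.
#'
#' @param clin clinical data.frame with `rfs_months` and `event`.
#' @param covariates data.frame of covariates (rows match `clin`).
#' @param vif_cutoff VIF gate (default 5).
#' @param logistic_horizon recurrence horizon in months (default 24).
#' @return list with `univariate` (data.frame term, hr, lower, upper, p),
#'   `multivariable` (same, or NULL when rejected), `vif`,
#'   `vif_rejected`, `logrank` (per categorical covariate), `logistic`.
#' @export
survivalModels <- function(clin, covariates, vif_cutoff = 5,
                           logistic_horizon = 24) {
  stopifnot(nrow(clin) == nrow(covariates))
  if (!any(clin$event == 1)) stop("no events observed", call. = FALSE)
  surv <- survival::Surv(clin$rfs_months, clin$event)
  uni <- do.call(rbind, lapply(names(covariates), function(v) {
    fit <- survival::coxph(surv ~ x, data = data.frame(x = covariates[[v]]))
    s <- summary(fit)
    data.frame(term = paste0(v, rownames(s$conf.int)),
               hr = s$conf.int[, 1], lower = s$conf.int[, 3],
               upper = s$conf.int[, 4],
               p = s$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  }))
  rownames(uni) <- NULL
  X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  vif <- varianceInflation(X)
  offending <- names(vif)[vif >= vif_cutoff]
  multi <- NULL
  if (!length(offending)) {
    fit <- survival::coxph(surv ~ ., data = covariates)
    s <- summary(fit)
    multi <- data.frame(term = rownames(s$conf.int),
                        hr = s$conf.int[, 1], lower = s$conf.int[, 3],
                        upper = s$conf.int[, 4],
                        p = s$coefficients[, "Pr(>|z|)"],
                        stringsAsFactors = FALSE)
    rownames(multi) <- NULL
  } else {
    warning("multivariable Cox rejected: VIF >= ", vif_cutoff, " for ",
            paste(offending, collapse = ", "), call. = FALSE)
  }
  logrank <- list()
  for (v in names(covariates)) {
    g <- covariates[[v]]
    if (is.numeric(g) && length(unique(g)) > 4) next
    g <- factor(g)
    if (nlevels(g) < 2) {
      logrank[[v]] <- NA_real_
      next
    }
    sd0 <- survival::survdiff(surv ~ g)
    logrank[[v]] <- stats::pchisq(sd0$chisq, df = nlevels(g) - 1,
                                  lower.tail = FALSE)
  }
  rec2y <- as.integer(clin$event == 1 & clin$rfs_months <= logistic_horizon)
  logistic <- NULL
  if (length(unique(rec2y)) == 2) {
    lfit <- suppressWarnings(
      stats::glm(rec2y ~ ., data = covariates, family = stats::binomial()))
    sl <- summary(lfit)$coefficients
    separated <- any(abs(stats::coef(lfit)[-1]) > 10)
    logistic <- data.frame(term = rownames(sl)[-1],
                           or = exp(sl[-1, 1]), p = sl[-1, 4],
                           separation_flag = separated,
                           stringsAsFactors = FALSE)
    rownames(logistic) <- NULL
  }
  list(univariate = uni, multivariable = multi, vif = vif,
       vif_rejected = offending, logrank = logrank, logistic = logistic)
}

#' Kaplan-Meier log-rank p for a grouping
#'
#' @param clin clinical data.frame with `rfs_months`, `event`.
#' @param groups per-sample grouping (>= 2 levels required).
#' @return log-rank p-value.
#' @export
logrankTest <- function(clin, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2)
    stop("log-rank requires >= 2 groups", call. = FALSE)
  sd0 <- survival::survdiff(
    survival::Surv(clin$rfs_months, clin$event) ~ g)
  stats::pchisq(sd0$chisq, df = nlevels(g) - 1, lower.tail = FALSE)
}

#' Path to the bundled two-cohort comparison count fixture
#'
#' Per-gene mutant counts of the combined European (n = 127) and Chinese
#' (n = 58) Ta-stage NMIBC cohorts for the ten recurrently compared genes.
#'
#' @return file path inside the installed package.
#' @export
cohortCountsPath <- function() {
  system.file("extdata", "cohort_comparison_counts.tsv",
              package = "nmibcGenomics", mustWork = TRUE)
}
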