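#' Survival machinery: Kaplan-Meier, log-rank, stepwise Cox, cutoff search
#'
#' Thin, validated wrappers over the `survival` package plus the cutoff-search
#' and quadrant-stratification procedures used throughout the pipeline. Cox
#' fits use Efron tie handling (the `coxph` default).
#'
#' @name survival-analysis
NULL

surv_obj <- function(survival) {
  stopifnot(inherits(survival, "SurvivalTable"))
  survival::Surv(survival$time_months, survival$event)
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param survival a `SurvivalTable`.
#' @param groups group label per sample (character or factor, aligned with
#'   `survival`); every group must be non-empty.
#' @return a `StratificationResult`: list with `groups`, per-group KM `curves`
#'   (data.frame of time, n_risk, n_event, survival), `chisq`, `df`, `p`, and
#'   for two groups the hazard ratio `hr` with 95% CI from a univariate Cox
#'   fit on the group indicator.
#' @export
km_logrank <- function(survival, groups) {
  stopifnot(length(groups) == nrow(survival))
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group in stratification")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  y <- surv_obj(survival)
  fit <- survival::survfit(y ~ groups)
  strata_names <- if (is.null(fit$strata)) levels(groups) else
    sub("^groups=", "", names(fit$strata))
  idx <- if (is.null(fit$strata)) rep(1L, length(fit$time)) else
    rep(seq_along(fit$strata), fit$strata)
  curves <- lapply(seq_along(strata_names), function(i) {
    sel <- idx == i
    data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
               n_event = fit$n.event[sel], survival = fit$surv[sel])
  })
  names(curves) <- strata_names

  if (sum(survival$event) == 0) {
    warning("no events observed; log-rank p set to 1")
    chisq <- 0; p <- 1; df <- nlevels(groups) - 1
  } else {
    lr <- survival::survdiff(y ~ groups)
    chisq <- lr$chisq
    df <- length(lr$n) - 1
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }

  hr <- NULL
  if (nlevels(groups) == 2 && sum(survival$event) > 0) {
    cx <- survival::coxph(y ~ groups)
    s <- summary(cx)
    hr <- c(hr = unname(s$conf.int[1, "exp(coef)"]),
            lower = unname(s$conf.int[1, "lower .95"]),
            upper = unname(s$conf.int[1, "upper .95"]))
  }
  structure(list(groups = groups, curves = curves, chisq = chisq, df = df,
                 p = p, hr = hr),
            class = "StratificationResult")
}

#' @export
print.StratificationResult <- function(x, ...) {
  cat(sprintf("StratificationResult: %d groups, log-rank chisq = %.3f (df %d), p = %.3g\n",
              nlevels(x$groups), x$chisq, x$df, x$p))
  if (!is.null(x$hr))
    cat(sprintf("  HR = %.3f [%.3f, %.3f]\n", x$hr["hr"], x$hr["lower"], x$hr["upper"]))
  invisible(x)
}

#' Multivariate Cox risk model with backward-stepwise selection
#'
#' Fits a multivariate Cox proportional-hazards model on the listed genes'
#' expression, then repeatedly drops the single least significant covariate
#' (largest Wald p) while any retained covariate has p above `drop_threshold`,
#' refitting after each drop. The risk score of a sample is the linear
#' predictor sum(coef_g * expr_g).
#'
#' @param expr an `ExpressionMatrix` whose columns cover the survival samples.
#' @param survival a `SurvivalTable`.
#' @param genes genes to start from (all must be rows of `expr`).
#' @param drop_threshold stay criterion on the Wald p-value, default 0.05.
#' @return a `RiskModel`: list with named `coefficients`, the `drop_sequence`
#'   (gene and p at each removal), per-sample `score`, and the final fit.
#' @export
backward_stepwise_cox <- function(expr, survival, genes, drop_threshold = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  miss <- setdiff(genes, rownames(expr$values))
  if (length(miss)) stop("genes absent from matrix: ", paste(miss, collapse = ", "))
  common <- intersect(colnames(expr$values), survival$sample_id)
  surv <- survival[match(common, survival$sample_id), ]
  if (sum(surv$event) < 5 * length(genes))
    warning("fewer than 5 events per starting covariate; estimates may be unstable")
  x <- t(expr$values[genes, common, drop = FALSE])
  y <- survival::Surv(surv$time_months, surv$event)
  drops <- data.frame(gene = character(0), p = numeric(0))
  current <- genes
  repeat {
    if (length(current) == 0) stop("all covariates dropped; empty model")
    df <- data.frame(x[, current, drop = FALSE], check.names = FALSE)
    fit <- tryCatch(survival::coxph(y ~ ., data = df),
                    warning = function(w) w, error = function(e) e)
    if (inherits(fit, "condition")) {
      # non-convergence: drop the last covariate and continue
      bad <- current[length(current)]
      warning("Cox fit unstable; removing covariate ", bad)
      drops <- rbind(drops, data.frame(gene = bad, p = NA_real_))
      current <- setdiff(current, bad)
      next
    }
    pv <- summary(fit)$coefficients[, "Pr(>|z|)"]
    names(pv) <- current
    if (all(pv <= drop_threshold, na.rm = TRUE) && !anyNA(pv)) break
    worst <- names(pv)[which.max(ifelse(is.na(pv), Inf, pv))]
    drops <- rbind(drops, data.frame(gene = worst, p = unname(pv[worst])))
    current <- setdiff(current, worst)
  }
  coefs <- stats::coef(fit)
  names(coefs) <- current
  score <- as.numeric(x[, current, drop = FALSE] %*% coefs)
  names(score) <- common
  structure(list(coefficients = coefs, drop_sequence = drops,
                 score = score, fit = fit, drop_threshold = drop_threshold),
            class = "RiskModel")
}

#' @export
print.RiskModel <- function(x, ...) {
  cat("RiskModel:", length(x$coefficients), "gene(s) retained\n")
  print(round(x$coefficients, 4))
  if (nrow(x$drop_sequence))
    cat("dropped:", paste(x$drop_sequence$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Search the score cutoff that best separates survival
#'
#' Scans every observed score value whose split lies inside `quantile_range`
#' and keeps both groups at or above `min_group_fraction` of the samples, and
#' returns the cutoff minimizing the two-group log-rank p. The reported p is
#' selection-biased (minimum over many candidate splits) and is labeled as
#' optimized in the result; treat it as descriptive.
#'
#' @param score numeric score per sample (named by sample id or aligned with
#'   `survival`).
#' @param survival a `SurvivalTable`.
#' @param quantile_range candidate cutoffs restricted to these score
#'   quantiles, default (0.10, 0.90).
#' @param min_group_fraction smallest allowed group size as a fraction of n.
#' @return list with `cutoff`, `result` (a `StratificationResult` for groups
#'   `low`/`high` split at the cutoff, high = score >= cutoff), and
#'   `optimized = TRUE`.
#' @export
optimal_cutoff <- function(score, survival, quantile_range = c(0.10, 0.90),
                           min_group_fraction = 0.10) {
  stopifnot(length(score) == nrow(survival), all(is.finite(score)))
  stopifnot(quantile_range[1] > 0, quantile_range[2] < 1,
            quantile_range[1] < quantile_range[2])
  n <- length(score)
  qs <- stats::quantile(score, quantile_range, names = FALSE, type = 1)
  cand <- sort(unique(score))
  cand <- cand[cand > qs[1] & cand <= qs[2]]
  keep <- vapply(cand, function(ct) {
    nh <- sum(score >= ct)
    min(nh, n - nh) >= min_group_fraction * n
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0)
    stop("no candidate cutoff respects min_group_fraction")
  y <- surv_obj(survival)
  pvals <- vapply(cand, function(ct) {
    g <- factor(score >= ct, levels = c(FALSE, TRUE), labels = c("low", "high"))
    lr <- survival::survdiff(y ~ g)
    stats::pchisq(lr$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  best <- cand[which.min(pvals)]
  g <- factor(score >= best, levels = c(FALSE, TRUE), labels = c("low", "high"))
  res <- km_logrank(survival, g)
  list(cutoff = best, result = res, optimized = TRUE)
}

#' Four-quadrant stratification by gene expression and a cell score
#'
#' Samples are split at the medians of both inputs (ties go to "high") into
#' high/low x high/low quadrants, tested with a 4-group log-rank.
#'
#' @param gene_expr numeric expression per sample.
#' @param cell_score numeric cell-type score per sample, same order.
#' @param survival a `SurvivalTable` aligned with both.
#' @return a `StratificationResult` with labels like `"gene_high.score_low"`.
#' @export
quadrant_stratification <- function(gene_expr, cell_score, survival) {
  stopifnot(length(gene_expr) == nrow(survival),
            length(cell_score) == nrow(survival))
  gh <- ifelse(gene_expr >= stats::median(gene_expr), "gene_high", "gene_low")
  sh <- ifelse(cell_score >= stats::median(cell_score), "score_high", "score_low")
  lab <- paste(gh, sh, sep = ".")
  expected <- c("gene_high.score_high", "gene_high.score_low",
                "gene_low.score_high", "gene_low.score_low")
  empty <- setdiff(expected, unique(lab))
  if (length(empty))
    stop("empty quadrant(s): ", paste(empty, collapse = ", "))
  km_logrank(survival, factor(lab, levels = expected))
}
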