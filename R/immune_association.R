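#' Immune cell-score contrasts and gene-score association tests
#'
#' @name immune-association
NULL

#' Contrast cell-type scores between two sample groups
#'
#' Per cell type, a two-sample t-test between the groups plus the log2 ratio
#' of raw group means. The ratio is flagged undefined when either mean is
#' non-positive.
#'
#' @param scores a `CellScoreMatrix`.
#' @param group_a,group_b disjoint, non-empty sample id sets.
#' @param alpha significance level for the pass flag.
#' @return data.frame with columns `cell_type`, `mean_a`, `mean_b`,
#'   `log2_ratio`, `t`, `p`, `pass`, `ratio_defined`.
#' @export
cellscore_contrast <- function(scores, group_a, group_b, alpha = 0.05) {
  stopifnot(inherits(scores, "CellScoreMatrix"))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  sa <- scores$scores[, intersect(group_a, colnames(scores$scores)), drop = FALSE]
  sb <- scores$scores[, intersect(group_b, colnames(scores$scores)), drop = FALSE]
  rows <- lapply(rownames(scores$scores), function(ct) {
    a <- sa[ct, ]; b <- sb[ct, ]
    ma <- mean(a, na.rm = TRUE); mb <- mean(b, na.rm = TRUE)
    defined <- is.finite(ma) && is.finite(mb) && ma > 0 && mb > 0
    l2 <- if (defined) log2(ma / mb) else NA_real_
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    p <- if (is.null(tt)) 1 else tt$p.value
    data.frame(cell_type = ct, mean_a = ma, mean_b = mb, log2_ratio = l2,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = p, pass = p < alpha, ratio_defined = defined)
  })
  do.call(rbind, rows)
}

#' Chi-squared association between gene expression and a cell score
#'
#' Both vectors are dichotomized at their medians (high = value >= median) and
#' tested with a Pearson chi-squared test on the 2x2 table, without continuity
#' correction. The table is returned for audit.
#'
#' @param gene_expr numeric expression per sample.
#' @param cell_score numeric score per sample, same order.
#' @return list with `chisq`, `p`, `table`.
#' @export
gene_cellscore_chi2 <- function(gene_expr, cell_score) {
  stopifnot(length(gene_expr) == length(cell_score))
  if (length(gene_expr) < 20)
    warning("fewer than 20 samples; chi-squared approximation may be poor")
  g <- factor(gene_expr >= stats::median(gene_expr),
              levels = c(FALSE, TRUE), labels = c("low", "high"))
  s <- factor(cell_score >= stats::median(cell_score),
              levels = c(FALSE, TRUE), labels = c("low", "high"))
  tab <- table(gene = g, score = s)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin in 2x2 table (constant dichotomy)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p = ct$p.value, table = tab)
}
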