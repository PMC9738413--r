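#' Intermediate-gene filter criteria
#'
#' Three standalone screens plus their conjunction, applied to candidate
#' intermediate genes before indirect network construction:
#' (1) differential expression between tumors and NATs (two-sample t-tests,
#' p < 0.05); (2) a proliferation effect (dependency score < -0.5) in at least
#' half the cell lines of either the CRISPR or the RNAi screen; (3) prognostic
#' stratification of patient survival in every configured cohort. No
#' multiplicity correction is applied anywhere in these screens; raw p-values
#' at alpha are the contract (a known limitation, kept deliberately).
#'
#' @name gene-filters
NULL

#' Per-gene two-sample t-tests between two expression matrices
#'
#' Welch (unequal-variance) t-tests by default; set `pooled = TRUE` for the
#' classic equal-variance test. Genes present on only one side are excluded
#' and listed in the `excluded` attribute.
#'
#' @param expr_a,expr_b `ExpressionMatrix` objects sharing gene ids (e.g.
#'   tumor vs NAT).
#' @param alpha significance level for the pass flag, default 0.05.
#' @param pooled use the pooled-variance t statistic instead of Welch.
#' @return data.frame with columns `gene`, `t`, `p`, `mean_a`, `mean_b`,
#'   `direction` ("higher_in_a"/"higher_in_b"), `pass`.
#' @export
differential_expression <- function(expr_a, expr_b, alpha = 0.05, pooled = FALSE) {
  stopifnot(inherits(expr_a, "ExpressionMatrix"),
            inherits(expr_b, "ExpressionMatrix"))
  shared <- intersect(rownames(expr_a$values), rownames(expr_b$values))
  excluded <- setdiff(union(rownames(expr_a$values), rownames(expr_b$values)),
                      shared)
  rows <- lapply(shared, function(g) {
    a <- expr_a$values[g, ]; b <- expr_b$values[g, ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(gene = g, t = NA_real_, p = NA_real_,
                        mean_a = mean(a), mean_b = mean(b),
                        direction = NA_character_, pass = FALSE))
    tt <- tryCatch(stats::t.test(a, b, var.equal = pooled),
                   error = function(e) NULL)
    if (is.null(tt)) {  # zero variance both sides
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(data.frame(gene = g, t = if (eq) 0 else NA_real_, p = 1,
                        mean_a = mean(a), mean_b = mean(b),
                        direction = NA_character_, pass = FALSE))
    }
    data.frame(gene = g, t = unname(tt$statistic), p = tt$p.value,
               mean_a = mean(a), mean_b = mean(b),
               direction = if (mean(a) >= mean(b)) "higher_in_a" else "higher_in_b",
               pass = tt$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}

#' Proliferation screen on dependency scores
#'
#' A gene passes when, in CRISPR or RNAi (mode `"or"`, the screen default) or
#' in both assays (mode `"and"`, used by the signature-construction exclusion
#' rule), the fraction of cell lines with dependency score strictly below
#' `threshold` is at least `line_fraction`. Boundary scores equal to the
#' threshold do not count.
#'
#' @param dep_crispr,dep_rnai `DependencyMatrix` objects (either may be NULL).
#' @param genes genes to screen; genes absent from both assays are excluded
#'   and listed in the `excluded` attribute.
#' @param threshold dependency cutoff, default -0.5.
#' @param line_fraction required fraction of lines below threshold, default 0.5.
#' @param mode `"or"` or `"and"` over the two assays.
#' @return data.frame with per-assay fractions, per-assay pass flags and the
#'   combined `pass`.
#' @export
proliferation_screen <- function(dep_crispr, dep_rnai, genes,
                                 threshold = -0.5, line_fraction = 0.5,
                                 mode = c("or", "and")) {
  mode <- match.arg(mode)
  stopifnot(threshold < 0)
  frac_below <- function(dep, g) {
    if (is.null(dep) || !g %in% rownames(dep$scores)) return(NA_real_)
    s <- dep$scores[g, ]
    mean(s < threshold, na.rm = TRUE)
  }
  rows <- lapply(genes, function(g) {
    fc <- frac_below(dep_crispr, g)
    fr <- frac_below(dep_rnai, g)
    pc <- !is.na(fc) && fc >= line_fraction
    pr <- !is.na(fr) && fr >= line_fraction
    pass <- if (mode == "or") pc || pr else pc && pr
    data.frame(gene = g, frac_crispr = fc, frac_rnai = fr,
               pass_crispr = pc, pass_rnai = pr, pass = pass)
  })
  out <- do.call(rbind, rows)
  excluded <- out$gene[is.na(out$frac_crispr) & is.na(out$frac_rnai)]
  out <- out[!out$gene %in% excluded, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Prognostic screen across cohorts
#'
#' Per cohort, each gene's expression is dichotomized at the cutoff returned
#' by [optimal_cutoff()] and tested by log-rank; a gene passes only if
#' p < alpha in every usable cohort. Cohorts with fewer than 10 events are
#' skipped with a warning and the conjunction is taken over the remainder.
#'
#' @param cohorts list of `list(expr = ExpressionMatrix, survival =
#'   SurvivalTable)` entries.
#' @param genes genes to screen.
#' @param alpha significance level, default 0.05.
#' @param ... passed to [optimal_cutoff()].
#' @return data.frame with one row per gene: per-cohort p-values
#'   (`p_cohort1`, ...) and the overall `pass`.
#' @export
prognostic_screen <- function(cohorts, genes, alpha = 0.05, ...) {
  stopifnot(length(cohorts) >= 1)
  usable <- vapply(cohorts, function(co) {
    ok <- sum(co$survival$event) >= 10
    if (!ok) warning("cohort skipped: fewer than 10 events")
    ok
  }, logical(1))
  cohorts <- cohorts[usable]
  if (length(cohorts) == 0) stop("no usable cohort (all have < 10 events)")
  pmat <- sapply(cohorts, function(co) {
    common <- intersect(colnames(co$expr$values), co$survival$sample_id)
    surv <- co$survival[match(common, co$survival$sample_id), ]
    vapply(genes, function(g) {
      if (!g %in% rownames(co$expr$values)) return(NA_real_)
      sc <- co$expr$values[g, common]
      if (any(is.na(sc))) { surv2 <- surv[!is.na(sc), ]; sc <- sc[!is.na(sc)] }
      else surv2 <- surv
      res <- tryCatch(optimal_cutoff(sc, surv2, ...), error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$result$p
    }, numeric(1))
  })
  pmat <- matrix(pmat, nrow = length(genes),
                 dimnames = list(genes, paste0("p_cohort", seq_along(cohorts))))
  pass <- apply(pmat, 1, function(p) all(!is.na(p)) && all(p < alpha))
  data.frame(gene = genes, pmat, pass = pass, row.names = NULL)
}

#' Conjunction of the three intermediate-gene criteria
#'
#' @param candidates candidate gene ids.
#' @param de result of [differential_expression()].
#' @param prolif result of [proliferation_screen()].
#' @param prognostic result of [prognostic_screen()].
#' @return a `FilterReport` data.frame: per-gene flags `de_pass`,
#'   `dependency_pass`, `prognostic_pass` and `all_pass` (their conjunction);
#'   only `all_pass` genes should feed indirect network construction.
#' @export
intermediate_gene_filter <- function(candidates, de, prolif, prognostic) {
  flag <- function(tab, col, g) {
    i <- match(g, tab$gene)
    !is.na(i) & tab[[col]][i]
  }
  out <- data.frame(
    gene = candidates,
    de_pass = flag(de, "pass", candidates),
    dependency_pass = flag(prolif, "pass", candidates),
    prognostic_pass = flag(prognostic, "pass", candidates))
  out$all_pass <- out$de_pass & out$dependency_pass & out$prognostic_pass
  structure(out, class = c("FilterReport", "data.frame"))
}
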