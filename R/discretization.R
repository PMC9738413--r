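#' Ternary discretization of expression matrices
#'
#' Expression values are mapped to under-expressed (-1), normal (0) and
#' over-expressed (+1) states using a per-gene normal range center +/- k * sd.
#' The multiplier k is not chosen per gene: it is calibrated once per dataset
#' on a designated housekeeping set so that the pooled fraction of non-normal
#' (i.e. -1 or +1) housekeeping gene-sample cells hits a target (30% by
#' default), and the same k is then applied to every other gene.
#'
#' @name discretization
NULL

per_gene_stats <- function(values) {
  list(center = rowMeans(values, na.rm = TRUE),
       sd = apply(values, 1, stats::sd, na.rm = TRUE))
}

nonzero_fraction <- function(values, center, sd, k) {
  lo <- center - k * sd
  hi <- center + k * sd
  hit <- (values > hi) | (values < lo)
  mean(hit, na.rm = TRUE)
}

#' Calibrate the normal-range multiplier k on housekeeping genes
#'
#' For each candidate k in `grid`, housekeeping genes are discretized by their
#' own center +/- k * sd and the pooled fraction of non-zero states across all
#' housekeeping gene-sample cells is computed; the k whose achieved fraction is
#' closest to `target_fraction` wins (ties go to the smaller k). With
#' `tail_mode = "per_tail"` the target is interpreted per tail instead of
#' combined (kept for sensitivity analysis).
#'
#' @param expr an `ExpressionMatrix`.
#' @param housekeeping character vector of housekeeping gene ids; at least two
#'   must be present in `expr`. Zero-variance housekeeping genes are excluded
#'   with a warning.
#' @param target_fraction target fraction of non-normal states, default 0.30.
#' @param grid ascending candidate k values; default 0.50..1.50 step 0.01,
#'   spanning the multipliers typically selected on real tumor/NAT data.
#' @param tail_mode `"combined"` (default; target is the under+over fraction
#'   jointly) or `"per_tail"`.
#' @return A `DiscretizationRecord`: list with `k`, `target_fraction`,
#'   `achieved_fraction`, `housekeeping_ids`, per-gene `center` and `sd` for
#'   every gene of `expr`, `tail_mode`, `layer`, `compartment`.
#' @export
calibrate_k <- function(expr, housekeeping = housekeeping_genes(),
                        target_fraction = 0.30,
                        grid = seq(0.50, 1.50, by = 0.01),
                        tail_mode = c("combined", "per_tail")) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  tail_mode <- match.arg(tail_mode)
  if (is.unsorted(grid)) stop("`grid` must be ascending")
  hk <- intersect(housekeeping, rownames(expr$values))
  if (length(hk) == 0) stop("no housekeeping gene present in the matrix")
  hv <- expr$values[hk, , drop = FALSE]
  sds <- apply(hv, 1, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate)) {
    warning("excluding zero-variance housekeeping genes: ",
            paste(hk[degenerate], collapse = ", "))
    hk <- hk[!degenerate]
    hv <- hv[hk, , drop = FALSE]
  }
  if (length(hk) < 2) stop("fewer than 2 usable housekeeping genes; cannot calibrate")
  st <- per_gene_stats(hv)
  target <- if (tail_mode == "per_tail") 2 * target_fraction else target_fraction
  achieved <- vapply(grid, function(k)
    nonzero_fraction(hv, st$center, st$sd, k), numeric(1))
  best <- which.min(abs(achieved - target))  # which.min takes the first => smaller k on ties
  all_st <- per_gene_stats(expr$values)
  structure(list(k = grid[best],
                 target_fraction = target_fraction,
                 tail_mode = tail_mode,
                 achieved_fraction = achieved[best],
                 housekeeping_ids = hk,
                 center = all_st$center,
                 sd = all_st$sd,
                 layer = expr$layer,
                 compartment = expr$compartment),
            class = "DiscretizationRecord")
}

#' @export
print.DiscretizationRecord <- function(x, ...) {
  cat(sprintf(
    "DiscretizationRecord [%s/%s]: k = %.2f, achieved non-normal fraction %.3f (target %.2f, %s), %d housekeeping genes\n",
    x$layer, x$compartment, x$k, x$achieved_fraction, x$target_fraction,
    x$tail_mode, length(x$housekeeping_ids)))
  invisible(x)
}

#' Discretize an expression matrix to ternary states
#'
#' State is +1 where value > center + k * sd, -1 where value < center - k * sd,
#' 0 otherwise. Per-gene centers and sds come from the calibration record when
#' the gene was present at calibration time, and are computed from `expr`
#' itself otherwise (e.g. when a record calibrated on one compartment is
#' applied to new genes of the same dataset). Missing values get state 0 and
#' are flagged so rule counting can drop them pairwise. Genes with sd = 0 get
#' all-zero states with a warning.
#'
#' @param expr an `ExpressionMatrix` in units compatible with the record.
#' @param record a `DiscretizationRecord` from [calibrate_k()].
#' @return A `TernaryMatrix`: list with integer matrix `states` (values in
#'   {-1,0,1}), logical matrix `missing`, and the `record`.
#' @export
discretize <- function(expr, record) {
  stopifnot(inherits(expr, "ExpressionMatrix"),
            inherits(record, "DiscretizationRecord"))
  v <- expr$values
  genes <- rownames(v)
  center <- record$center[genes]
  sdv <- record$sd[genes]
  new_g <- is.na(center)
  if (any(new_g)) {
    st <- per_gene_stats(v[new_g, , drop = FALSE])
    center[new_g] <- st$center
    sdv[new_g] <- st$sd
  }
  flat <- !is.finite(sdv) | sdv == 0
  if (any(flat)) {
    warning("genes with zero variance set to all-normal states: ",
            paste(genes[flat], collapse = ", "))
    sdv[flat] <- Inf  # thresholds at +/-Inf => state 0 everywhere
  }
  lo <- center - record$k * sdv
  hi <- center + record$k * sdv
  states <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  states[v > hi] <- 1L
  states[v < lo] <- -1L
  miss <- is.na(v)
  states[miss] <- 0L
  structure(list(states = states, missing = miss, record = record),
            class = "TernaryMatrix")
}

#' @export
print.TernaryMatrix <- function(x, ...) {
  tab <- table(factor(x$states, levels = c(-1, 0, 1)))
  cat(sprintf("TernaryMatrix: %d genes x %d samples | -1: %d, 0: %d, +1: %d (k = %.2f)\n",
              nrow(x$states), ncol(x$states), tab[1], tab[2], tab[3], x$record$k))
  invisible(x)
}
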