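#' Drug-response gene calling and pan classification
#'
#' Cell lines are categorized per drug from a response measure (lower IC50 /
#' EC50 = more sensitive), genes are called sensitive or resistant by
#' two-sample t-tests between the extreme classes, and genes whose call
#' pattern is one-sided across the whole drug panel are classified as
#' pan-sensitive or pan-resistant.
#'
#' @name drug-response
NULL

#' Categorize cell lines for one drug
#'
#' Default mode `"tertile"`: lines are ordered by (measure, cell-line id) and
#' split into three nearly equal parts — lowest third sensitive, highest third
#' resistant, middle intermediate; part sizes differ by at most one and ties
#' are resolved deterministically by the id order. Mode `"median"` is a
#' two-way split without an intermediate class.
#'
#' @param response a `DrugResponseTable`.
#' @param drug drug id (row of the table).
#' @param mode `"tertile"` or `"median"`.
#' @return named character vector (by cell line) with values in
#'   `"sensitive"`, `"intermediate"`, `"resistant"`; lines with missing
#'   measures are dropped.
#' @export
categorize_cell_lines <- function(response, drug, mode = c("tertile", "median")) {
  mode <- match.arg(mode)
  stopifnot(inherits(response, "DrugResponseTable"))
  if (!drug %in% rownames(response$measure)) stop("unknown drug: ", drug)
  m <- response$measure[drug, ]
  m <- m[!is.na(m)]
  if (length(m) == 0) stop("all measures missing for drug ", drug)
  if (length(m) < 10) warning("fewer than 10 measured lines for drug ", drug)
  ord <- order(m, names(m), method = "radix")
  n <- length(m)
  lab <- character(n)
  if (mode == "tertile") {
    b1 <- round(n / 3); b2 <- n - round(n / 3)
    lab[seq_len(b1)] <- "sensitive"
    lab[(b2 + 1):n] <- "resistant"
    if (b2 > b1) lab[(b1 + 1):b2] <- "intermediate"
  } else {
    half <- floor(n / 2)
    lab[seq_len(half)] <- "sensitive"
    lab[(half + 1):n] <- "resistant"
  }
  out <- lab
  names(out) <- names(m)[ord]
  out
}

#' Call sensitive/resistant genes per drug
#'
#' Per (gene, drug): a two-sample t-test of the gene's expression between
#' sensitive and resistant lines (intermediate lines excluded). Higher in
#' sensitive at p < alpha gives a "sensitive" call, higher in resistant a
#' "resistant" call, anything else "neither". Drugs with fewer than 3 lines
#' per class yield all-"neither" calls with a warning.
#'
#' @param expr a cell-line `ExpressionMatrix`.
#' @param labels named list: per drug, the label vector from
#'   [categorize_cell_lines()].
#' @param candidates gene ids to test.
#' @param alpha significance level, default 0.05.
#' @return a `DrugCallMatrix`: list with character matrix `calls`
#'   (genes x drugs, values "sensitive"/"resistant"/"neither") and numeric
#'   matrix `p`.
#' @export
call_drug_genes <- function(expr, labels, candidates, alpha = 0.05) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  candidates <- intersect(candidates, rownames(expr$values))
  drugs <- names(labels)
  calls <- matrix("neither", length(candidates), length(drugs),
                  dimnames = list(candidates, drugs))
  pmat <- matrix(NA_real_, length(candidates), length(drugs),
                 dimnames = list(candidates, drugs))
  for (d in drugs) {
    lab <- labels[[d]]
    sens <- intersect(names(lab)[lab == "sensitive"], colnames(expr$values))
    res <- intersect(names(lab)[lab == "resistant"], colnames(expr$values))
    if (length(sens) < 3 || length(res) < 3) {
      warning("drug ", d, ": fewer than 3 lines per class; all calls neither")
      next
    }
    for (g in candidates) {
      a <- expr$values[g, sens]; b <- expr$values[g, res]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      if (is.null(tt)) next
      pmat[g, d] <- tt$p.value
      if (tt$p.value < alpha)
        calls[g, d] <- if (mean(a) > mean(b)) "sensitive" else "resistant"
    }
  }
  structure(list(calls = calls, p = pmat), class = "DrugCallMatrix")
}

#' Pan-sensitive / pan-resistant classification
#'
#' A pan-sensitive gene is never called resistant for any listed drug and is
#' called sensitive for at least one; a pan-resistant gene is never called
#' sensitive and is called resistant at least once. The two sets are disjoint
#' by construction. Genes missing a call for any listed drug are excluded and
#' reported.
#'
#' @param calls a `DrugCallMatrix` (or a plain character matrix genes x drugs).
#' @param drugs drug panel to classify over; defaults to all columns.
#' @return list with `pan_sensitive`, `pan_resistant`, `excluded`.
#' @export
pan_classification <- function(calls, drugs = NULL) {
  m <- if (inherits(calls, "DrugCallMatrix")) calls$calls else calls
  if (is.null(drugs)) drugs <- colnames(m)
  missing_drugs <- setdiff(drugs, colnames(m))
  if (length(missing_drugs))
    stop("calls missing for drug(s): ", paste(missing_drugs, collapse = ", "))
  m <- m[, drugs, drop = FALSE]
  complete <- apply(m, 1, function(r) all(r %in% c("sensitive", "resistant", "neither")))
  excluded <- rownames(m)[!complete]
  m <- m[complete, , drop = FALSE]
  n_sens <- rowSums(m == "sensitive")
  n_res <- rowSums(m == "resistant")
  list(pan_sensitive = rownames(m)[n_res == 0 & n_sens >= 1],
       pan_resistant = rownames(m)[n_sens == 0 & n_res >= 1],
       excluded = excluded)
}

#' Correlation between drug concentration and checkpoint-gene expression
#'
#' Pearson correlation between a drug's response measure and per-line
#' expression of an immune-checkpoint gene, after removing outlier pairs whose
#' measure exceeds `outlier_cutoff` (drug concentration > 10 by convention).
#' The inhibitory-concordant flag requires R < 0 and p < 0.05.
#'
#' @param response a `DrugResponseTable`.
#' @param drug drug id.
#' @param ici_expr named numeric vector of checkpoint-gene expression per cell
#'   line.
#' @param outlier_cutoff measures above this are dropped, default 10.
#' @return list with `r`, `p`, `n_used`, `n_outliers`, `flagged`,
#'   `sufficient` (FALSE when fewer than 5 pairs remain, in which case no
#'   flag is set).
#' @export
ici_correlation <- function(response, drug, ici_expr, outlier_cutoff = 10) {
  stopifnot(inherits(response, "DrugResponseTable"))
  if (!drug %in% rownames(response$measure)) stop("unknown drug: ", drug)
  m <- response$measure[drug, ]
  common <- intersect(names(m)[!is.na(m)], names(ici_expr)[!is.na(ici_expr)])
  m <- m[common]; e <- ici_expr[common]
  out <- m > outlier_cutoff
  n_outliers <- sum(out)
  m <- m[!out]; e <- e[!out]
  if (length(m) < 5)
    return(list(r = NA_real_, p = NA_real_, n_used = length(m),
                n_outliers = n_outliers, flagged = FALSE, sufficient = FALSE))
  ct <- stats::cor.test(m, e, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, p = ct$p.value, n_used = length(m), n_outliers = n_outliers,
       flagged = r < 0 && ct$p.value < 0.05, sufficient = TRUE)
}

#' Per-drug potency summary with outlier removal
#'
#' Mean response per drug after dropping measures above `outlier_cutoff`,
#' with retained and removed counts.
#'
#' @param response a `DrugResponseTable`.
#' @param outlier_cutoff default 10.
#' @return data.frame with columns `drug`, `mean`, `n`, `n_outliers`,
#'   `measure_kind`.
#' @export
potency_summary <- function(response, outlier_cutoff = 10) {
  stopifnot(inherits(response, "DrugResponseTable"))
  if (nrow(response$measure) == 0) stop("empty response table")
  rows <- lapply(rownames(response$measure), function(d) {
    m <- response$measure[d, ]
    m <- m[!is.na(m)]
    keep <- m <= outlier_cutoff
    data.frame(drug = d,
               mean = if (any(keep)) mean(m[keep]) else NA_real_,
               n = sum(keep), n_outliers = sum(!keep),
               measure_kind = response$measure_kind)
  })
  do.call(rbind, rows)
}

#' Read the packaged pan-gene transcription tables
#'
#' The package ships machine-readable transcriptions of the published
#' pan-sensitive / pan-resistant gene lists per drug for the 21-drug NSCLC
#' panel, one table for the RNA-seq layer and one for the proteomics layer.
#' Gene symbols are normalized on read (whitespace stripped, aliases
#' resolved); proteomics entries carrying isoform accessions (e.g.
#' `TJP1_G3V1L9`) keep the gene symbol part only when `strip_isoforms`.
#'
#' @param layer `"rnaseq"` or `"protein"`.
#' @param strip_isoforms drop `_ACCESSION` suffixes from proteomics symbols.
#' @return data.frame with columns `drug`, `therapy`, and list-columns
#'   `pan_sensitive`, `pan_resistant` (character vectors per drug).
#' @export
read_pan_gene_table <- function(layer = c("rnaseq", "protein"),
                                strip_isoforms = TRUE) {
  layer <- match.arg(layer)
  fname <- paste0("pan_genes_", layer, ".tsv")
  path <- system.file("extdata", fname, package = "impnet")
  if (path == "") stop("packaged table not found: ", fname)
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, na.strings = NULL)
  split_genes <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    g <- trimws(strsplit(s, ",")[[1]])
    if (strip_isoforms) g <- sub("_.*$", "", g)
    unique(normalize_gene_ids(g))
  }
  df$pan_sensitive <- lapply(df$pan_sensitive, split_genes)
  df$pan_resistant <- lapply(df$pan_resistant, split_genes)
  df
}
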