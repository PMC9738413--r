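#' Expression matrix container
#'
#' A validated gene-by-sample matrix tagged with its molecular layer and tissue
#' compartment. Missing entries are allowed (NA); everything else must be
#' finite. Genes absent from a layer (common for proteomics coverage gaps) are
#' represented as absent rows, never as NA-filled rows.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   rownames (gene ids) and colnames (sample ids).
#' @param layer one of `"mrna"`, `"protein"`.
#' @param compartment one of `"tumor"`, `"nat"`, `"cell_line"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `layer`, `compartment`.
#' @export
expression_matrix <- function(values, layer = c("mrna", "protein"),
                              compartment = c("tumor", "nat", "cell_line")) {
  layer <- match.arg(layer)
  compartment <- match.arg(compartment)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (ncol(values) < 2)
    stop("an ExpressionMatrix needs at least 2 samples")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (any(is.infinite(values)))
    stop("non-missing values must be finite")
  structure(list(values = values, layer = layer, compartment = compartment),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s/%s]: %d genes x %d samples (%d missing cells)\n",
              x$layer, x$compartment, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Survival table container
#'
#' @param sample_ids unique sample identifiers.
#' @param time follow-up times in months, non-negative.
#' @param event event indicator, 1 = death/recurrence observed, 0 = censored.
#' @return data.frame of class `SurvivalTable` with columns
#'   `sample_id`, `time_months`, `event`.
#' @export
survival_table <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in survival table")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop("sample_ids, time and event must have equal length")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  structure(data.frame(sample_id = sample_ids, time_months = as.numeric(time),
                       event = as.integer(event), stringsAsFactors = FALSE),
            class = c("SurvivalTable", "data.frame"))
}

#' Cell-type score matrix container
#'
#' Holds per-sample enrichment scores for immune/stroma cell types (xCell-style,
#' consumed precomputed). Composite scores (microenvironment, stroma) are
#' ordinary rows.
#'
#' @param scores non-negative numeric matrix, cell types in rows, samples in
#'   columns.
#' @return object of class `CellScoreMatrix`.
#' @export
cell_score_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("`scores` must have cell-type rownames and sample colnames")
  if (anyDuplicated(rownames(scores))) stop("duplicate cell-type names")
  if (any(scores < 0, na.rm = TRUE)) stop("scores must be >= 0")
  structure(list(scores = scores), class = "CellScoreMatrix")
}

infer_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("cannot infer delimiter from extension '.", ext,
              "' (use .tsv or .csv)"))
}

#' Read a gene-by-sample matrix from TSV/CSV
#'
#' First column holds gene ids, first row sample ids; delimiter is inferred
#' from the extension (.tsv tab, .csv comma). Blank or NA cells become missing
#' values. Duplicated gene rows are rejected, not merged.
#'
#' @param path file path.
#' @param layer,compartment tags passed to [expression_matrix()].
#' @param normalize if TRUE (default) gene ids are passed through
#'   [normalize_gene_ids()].
#' @param samples_in_rows set TRUE when the file is oriented samples x genes;
#'   the matrix is transposed after reading so that genes are always rows.
#' @return an `ExpressionMatrix`.
#' @export
read_matrix <- function(path, layer = "mrna", compartment = "tumor",
                        normalize = TRUE, samples_in_rows = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- infer_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) stop("malformed header: expected id column plus samples")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
    if (all(is.na(m)) && nrow(df) > 0) stop("malformed matrix: non-numeric body")
  }
  rownames(m) <- if (normalize && !samples_in_rows) normalize_gene_ids(ids) else ids
  if (samples_in_rows) {
    m <- t(m)
    if (normalize) rownames(m) <- normalize_gene_ids(rownames(m))
  }
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup))
    stop("duplicate gene ids after normalization: ", paste(dup, collapse = ", "))
  expression_matrix(m, layer = layer, compartment = compartment)
}

#' Write an ExpressionMatrix to TSV/CSV
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output path; delimiter inferred from extension.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  sep <- infer_sep(path)
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table (columns sample_id, time_months, event)
#'
#' @param path TSV/CSV path.
#' @return a `SurvivalTable`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = infer_sep(path), header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  survival_table(df$sample_id, df$time_months, df$event)
}

state_word <- function(s) c(`-1` = "down", `1` = "up")[as.character(s)]

#' Export an implication network in SIF format
#'
#' One line per rule, `source<TAB>relation<TAB>target`, where the relation
#' encodes premise and consequent states (`up-up`, `up-down`, `down-up`,
#' `down-down`). Lines are sorted lexicographically by source, target and
#' relation so the export is byte-deterministic; suitable for Cytoscape.
#'
#' @param network an `ImplicationNetwork` (see [direct_network()]).
#' @param path output file path.
#' @return `path`, invisibly. An empty network writes an empty file and warns.
#' @export
write_network_sif <- function(network, path) {
  stopifnot(inherits(network, "ImplicationNetwork"))
  rules <- network$rules
  if (is.null(rules) || nrow(rules) == 0) {
    warning("empty network: writing empty SIF file")
    writeLines(character(0), path)
    return(invisible(path))
  }
  rel <- paste0(state_word(rules$premise_state), "-",
                state_word(rules$consequent_state))
  lines <- paste(rules$premise_gene, rel, rules$consequent_gene, sep = "\t")
  lines <- lines[order(rules$premise_gene, rules$consequent_gene, rel,
                       method = "radix")]
  writeLines(lines, path)
  invisible(path)
}
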