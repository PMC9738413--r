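#' Packaged gene sets
#'
#' Curated gene lists used throughout the pipeline: the 14 housekeeping genes
#' that anchor ternary discretization, epithelial and mesenchymal marker sets
#' gating the signature-construction rules, and the immune-checkpoint genes
#' appended to the down-regulated signature list.
#'
#' @return Character vector of gene symbols.
#' @name gene-sets
NULL

#' @rdname gene-sets
#' @export
housekeeping_genes <- function() {
  c("B2M", "ESD", "FLOT2", "GAPDH", "GRB2", "HPRT1", "HSP90AB1",
    "LDHA", "NONO", "POLR2A", "PPP1CA", "RHOA", "SDCBP", "TFRC")
}

#' @rdname gene-sets
#' @export
epithelial_genes <- function() {
  c("CDH1", "EPCAM", "ESRP1", "ESRP2", "DDR1", "CTNNB1", "CD24",
    "CLDN7", "KRT8", "KRT19", "RAB25")
}

#' @rdname gene-sets
#' @export
mesenchymal_genes <- function() {
  c("ZEB1", "VIM", "FN1")
}

#' @rdname gene-sets
#' @export
ici_genes <- function() {
  c("CD27", "PDCD1", "CD274")
}

#' Gene symbol alias table
#'
#' Maps legacy or shorthand symbols to the canonical symbol used everywhere in
#' the pipeline. Downstream rules reference both names (e.g. PD1 and PDCD1),
#' so all identifiers are resolved through this table on input.
#'
#' @return Named character vector: names are aliases, values canonical symbols.
#' @export
gene_alias_table <- function() {
  c(TMEM173 = "STING1",
    PD1     = "PDCD1",
    PDL1    = "CD274",
    CGAS    = "CGAS",     # MB21D1 in older annotations
    MB21D1  = "CGAS")
}

#' Normalize gene symbols
#'
#' Uppercases, strips all whitespace (symbols are occasionally printed with
#' internal spaces, e.g. "RNASE L"), and resolves aliases through
#' [gene_alias_table()].
#'
#' @param ids character vector of gene identifiers.
#' @param aliases named character vector overriding the packaged alias table.
#' @return character vector of canonical symbols, same length as `ids`.
#' @export
normalize_gene_ids <- function(ids, aliases = gene_alias_table()) {
  out <- toupper(gsub("[[:space:]]+", "", as.character(ids)))
  hit <- out %in% names(aliases)
  out[hit] <- unname(aliases[out[hit]])
  out
}
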