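#' Synthetic cell-line panel generator
#'
#' Emulates a dependency-screen + drug-response cell-line panel: CRISPR and
#' RNAi dependency scores are drawn around -1 for a designated common-essential
#' set and around 0 for a non-essential set, then renormalized per cell line by
#' the affine map that sends the non-essential median to exactly 0 and the
#' essential median to exactly -1 (the convention of CERES/DEMETER2-processed
#' screens). Drug response plants a sensitive/resistant split per drug with
#' designated genes shifted upward in their class.
#'
#' @name synthetic-panel
NULL

#' Cell panel configuration
#'
#' @param n_cell_lines number of cell lines.
#' @param essential_genes,nonessential_genes designated control gene sets for
#'   the dependency normalization (must be non-empty and disjoint).
#' @param other_genes additional genes carried in expression and dependency
#'   matrices with null dependency.
#' @param drug_ids drug identifiers.
#' @param planted_sensitive,planted_resistant named lists (by drug) of gene
#'   sets whose expression is shifted upward in sensitive (resp. resistant)
#'   lines; the two sets must be disjoint within each drug.
#' @param sensitive_fraction fraction of lines truly sensitive per drug.
#' @param effect_size expression shift (in sd units of the unit-variance
#'   background) between sensitivity classes.
#' @param dep_sd sd of the raw dependency draws.
#' @param seed integer seed.
#' @return a `CellPanelConfig` list.
#' @export
cell_panel_config <- function(n_cell_lines = 60,
                              essential_genes = sprintf("ESS%03d", 1:20),
                              nonessential_genes = sprintf("NES%03d", 1:40),
                              other_genes = character(0),
                              drug_ids = c("drugA", "drugB"),
                              planted_sensitive = list(),
                              planted_resistant = list(),
                              sensitive_fraction = 0.5,
                              effect_size = 2, dep_sd = 0.3, seed = 1L) {
  if (length(essential_genes) == 0) stop("essential gene set must be non-empty")
  if (length(nonessential_genes) == 0) stop("non-essential gene set must be non-empty")
  if (length(intersect(essential_genes, nonessential_genes)))
    stop("essential and non-essential sets must be disjoint")
  stopifnot(sensitive_fraction > 0, sensitive_fraction < 1, n_cell_lines >= 6)
  for (d in union(names(planted_sensitive), names(planted_resistant))) {
    if (length(intersect(planted_sensitive[[d]], planted_resistant[[d]])))
      stop("planted sensitive/resistant sets overlap for drug ", d)
  }
  structure(list(n_cell_lines = n_cell_lines,
                 essential_genes = essential_genes,
                 nonessential_genes = nonessential_genes,
                 other_genes = other_genes, drug_ids = drug_ids,
                 planted_sensitive = planted_sensitive,
                 planted_resistant = planted_resistant,
                 sensitive_fraction = sensitive_fraction,
                 effect_size = effect_size, dep_sd = dep_sd,
                 seed = as.integer(seed)),
            class = "CellPanelConfig")
}

#' Dependency matrix container
#'
#' @param scores numeric matrix, genes x cell lines.
#' @param assay `"crispr"` or `"rnai"`.
#' @return object of class `DependencyMatrix`.
#' @export
dependency_matrix <- function(scores, assay = c("crispr", "rnai")) {
  assay <- match.arg(assay)
  stopifnot(is.matrix(scores), is.numeric(scores))
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must have gene rownames and cell-line colnames")
  if (anyDuplicated(rownames(scores)) || anyDuplicated(colnames(scores)))
    stop("duplicate ids in dependency matrix")
  structure(list(scores = scores, assay = assay), class = "DependencyMatrix")
}

#' Drug response table container
#'
#' @param measure numeric matrix, drugs x cell lines (IC50/EC50 or a log
#'   thereof); missing entries allowed.
#' @param measure_kind one of `"ic50"`, `"ec50"`, `"ln_ic50"`, `"ln_ec50"`.
#' @param source free-text provenance tag.
#' @return object of class `DrugResponseTable`.
#' @export
drug_response_table <- function(measure,
                                measure_kind = c("ic50", "ec50", "ln_ic50", "ln_ec50"),
                                source = "synthetic") {
  measure_kind <- match.arg(measure_kind)
  stopifnot(is.matrix(measure), is.numeric(measure))
  if (is.null(rownames(measure)) || is.null(colnames(measure)))
    stop("measure must have drug rownames and cell-line colnames")
  if (any(is.infinite(measure))) stop("measures must be finite or missing")
  structure(list(measure = measure, measure_kind = measure_kind, source = source),
            class = "DrugResponseTable")
}

# Affine per-line map sending the non-essential median to 0 and the essential
# median to -1; exact by construction and order-preserving.
normalize_dependency <- function(raw, essential, nonessential) {
  out <- raw
  for (j in seq_len(ncol(raw))) {
    m_e <- stats::median(raw[essential, j])
    m_n <- stats::median(raw[nonessential, j])
    out[, j] <- (raw[, j] - m_n) / (m_n - m_e)
  }
  out
}

#' Generate a synthetic cell-line panel
#'
#' @param config a `CellPanelConfig`.
#' @return list with `expr` (cell-line ExpressionMatrix), `dep_crispr` and
#'   `dep_rnai` (DependencyMatrix, medians exactly -1/0 for the control sets
#'   per line), `response` (DrugResponseTable, lower = more sensitive), and
#'   `truth` (per-drug class labels and planted gene sets).
#' @export
generate_cell_panel <- function(config) {
  stopifnot(inherits(config, "CellPanelConfig"))
  with_seed(config$seed, {
    cfg <- config
    lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
    planted <- unique(c(unlist(cfg$planted_sensitive),
                        unlist(cfg$planted_resistant)))
    genes <- unique(c(cfg$essential_genes, cfg$nonessential_genes,
                      cfg$other_genes, planted))

    raw_dep <- function() {
      m <- matrix(stats::rnorm(length(genes) * cfg$n_cell_lines, sd = cfg$dep_sd),
                  length(genes), cfg$n_cell_lines,
                  dimnames = list(genes, lines))
      m[cfg$essential_genes, ] <- m[cfg$essential_genes, ] - 1
      m
    }
    dep_c <- normalize_dependency(raw_dep(), cfg$essential_genes,
                                  cfg$nonessential_genes)
    dep_r <- normalize_dependency(raw_dep(), cfg$essential_genes,
                                  cfg$nonessential_genes)

    expr <- matrix(stats::rnorm(length(genes) * cfg$n_cell_lines),
                   length(genes), cfg$n_cell_lines,
                   dimnames = list(genes, lines))

    n_sens <- max(1, round(cfg$sensitive_fraction * cfg$n_cell_lines))
    labels <- list()
    measure <- matrix(NA_real_, length(cfg$drug_ids), cfg$n_cell_lines,
                      dimnames = list(cfg$drug_ids, lines))
    for (d in cfg$drug_ids) {
      sens <- sample(lines, n_sens)
      lab <- ifelse(lines %in% sens, "sensitive", "resistant")
      names(lab) <- lines
      labels[[d]] <- lab
      measure[d, ] <- ifelse(lab == "sensitive",
                             stats::rnorm(cfg$n_cell_lines, 1, 0.4),
                             stats::rnorm(cfg$n_cell_lines, 3, 0.4))
      for (g in cfg$planted_sensitive[[d]])
        expr[g, lab == "sensitive"] <- expr[g, lab == "sensitive"] + cfg$effect_size
      for (g in cfg$planted_resistant[[d]])
        expr[g, lab == "resistant"] <- expr[g, lab == "resistant"] + cfg$effect_size
    }

    list(expr = expression_matrix(expr, "mrna", "cell_line"),
         dep_crispr = dependency_matrix(dep_c, "crispr"),
         dep_rnai = dependency_matrix(dep_r, "rnai"),
         response = drug_response_table(measure, "ic50"),
         truth = list(labels = labels,
                      planted_sensitive = cfg$planted_sensitive,
                      planted_resistant = cfg$planted_resistant,
                      essential = cfg$essential_genes,
                      nonessential = cfg$nonessential_genes))
  })
}
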