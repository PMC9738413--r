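#' End-to-end pipeline orchestration
#'
#' Runs the full synthetic-cohort workflow in dependency order:
#' simulate -> discretize -> networks -> filters -> survival -> immune ->
#' drugs -> signature, writing every artifact under an output directory and
#' returning a manifest with file hashes. All thresholds are centralized in
#' the config with the pipeline defaults (alpha 0.05, z 1.64, dependency
#' -0.5, line fraction 0.5, tail fraction 0.30, outlier cutoff 10); there are
#' no hidden constants. A single global seed is fanned out to per-stage child
#' seeds by a stable affine map so individual stages are reproducible
#' standalone.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param seed global seed.
#' @param outdir output directory (created if needed).
#' @param cohort a `CohortConfig`; by default a planted demonstration cohort.
#' @param panel a `CellPanelConfig`.
#' @param stages character vector of stages to run (dependencies are not
#'   re-resolved: disable only trailing stages).
#' @param alpha,z_threshold,dependency_threshold,line_fraction,tail_fraction,outlier_cutoff
#'   central thresholds.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("impnet_run_"),
                            cohort = NULL, panel = NULL,
                            stages = c("simulate", "discretize", "network",
                                       "filters", "survival", "immune",
                                       "drugs", "signature"),
                            alpha = 0.05, z_threshold = 1.64,
                            dependency_threshold = -0.5, line_fraction = 0.5,
                            tail_fraction = 0.30, outlier_cutoff = 10) {
  stopifnot(alpha > 0, alpha < 1, z_threshold > 0, dependency_threshold < 0,
            line_fraction > 0, line_fraction <= 1,
            tail_fraction > 0, tail_fraction < 1)
  child <- function(k) as.integer((as.numeric(seed) * 131 + k) %% .Machine$integer.max)
  if (is.null(cohort))
    cohort <- cohort_config(
      n_tumor = 120, n_nat = 120, n_genes = 160,
      planted_direct = data.frame(target = c("OAS1", "STING1"),
                                  anchor_state = 1L, target_state = -1L,
                                  precision = 0.9),
      planted_twohop = data.frame(intermediate = "MED1", target = "TRIM5",
                                  s_anchor = 1L, s_intermediate = 1L,
                                  s_target = -1L, p1 = 0.9, p2 = 0.9),
      planted_prognostic = data.frame(gene = c("MED1", "DAG1"),
                                      beta = c(0.7, -0.7)),
      planted_de = data.frame(gene = c("MED1", "DAG1", "OAS1"),
                              shift = c(1.5, -1.5, -1)),
      tail_fraction = tail_fraction, seed = child(1))
  if (is.null(panel))
    panel <- cell_panel_config(
      n_cell_lines = 45,
      essential_genes = c("MED1", sprintf("ESS%03d", 1:19)),
      drug_ids = c("drugA", "drugB", "drugC"),
      planted_sensitive = list(drugA = "OAS1"),
      planted_resistant = list(drugA = "KRT8"),
      other_genes = c("OAS1", "STING1", "TRIM5", "DAG1", "KRT8", "ZNF71"),
      seed = child(2))
  structure(list(seed = as.integer(seed), outdir = outdir, cohort = cohort,
                 panel = panel, stages = stages, alpha = alpha,
                 z_threshold = z_threshold,
                 dependency_threshold = dependency_threshold,
                 line_fraction = line_fraction,
                 tail_fraction = tail_fraction,
                 outlier_cutoff = outlier_cutoff),
            class = "PipelineConfig")
}

#' Run the pipeline
#'
#' @param config a `PipelineConfig`.
#' @return list with `artifacts` (named list of in-memory stage results) and
#'   `manifest` (data.frame of written files with md5 hashes). A stage
#'   failure halts with the stage name in the error; artifacts written by
#'   earlier stages are preserved on disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$outdir, name)
    writer(path)
    files <<- c(files, path)
  }
  stage <- function(name, code) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  stage("simulate", {
    art$cohort <- generate_cohort(config$cohort)
    art$panel <- generate_cell_panel(config$panel)
    emit("mrna_tumor.tsv", function(p) write_matrix(art$cohort$mrna_tumor, p))
    emit("mrna_nat.tsv", function(p) write_matrix(art$cohort$mrna_nat, p))
    emit("survival.tsv", function(p)
      utils::write.table(art$cohort$survival, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })
  stage("discretize", {
    co <- art$cohort
    art$record_tumor <- calibrate_k(co$mrna_tumor,
                                     config$cohort$housekeeping_ids,
                                     target_fraction = config$tail_fraction)
    art$tern_tumor <- discretize(co$mrna_tumor, art$record_tumor)
    rec_p <- calibrate_k(co$protein_tumor, config$cohort$housekeeping_ids,
                         target_fraction = config$tail_fraction)
    art$tern_protein <- discretize(co$protein_tumor, rec_p)
    emit("discretization_record.json", function(p)
      jsonlite::write_json(art$record_tumor[c("k", "achieved_fraction",
                                              "target_fraction", "tail_mode")],
                           p, auto_unbox = TRUE, digits = NA))
  })
  stage("network", {
    co <- art$cohort
    targets <- unique(c(co$truth$direct$target, co$truth$twohop$target))
    art$net_direct <- direct_network(art$tern_tumor, co$truth$anchor, 1L,
                                      targets, z_threshold = config$z_threshold)
    art$net_twohop <- twohop_network(art$tern_tumor, co$truth$anchor, 1L,
                                      targets,
                                      intermediates = co$truth$twohop$intermediate,
                                      z_threshold = config$z_threshold)
    art$net_cross <- crosslayer_network(art$tern_tumor, art$tern_protein,
                                         co$truth$anchor, 1L, targets,
                                         intermediates = co$truth$twohop$intermediate,
                                         z_threshold = config$z_threshold)
    emit("network_direct.sif", function(p)
      suppressWarnings(write_network_sif(art$net_direct, p)))
    emit("network_twohop.sif", function(p)
      suppressWarnings(write_network_sif(art$net_twohop, p)))
  })
  stage("filters", {
    co <- art$cohort
    cand <- unique(c(co$truth$twohop$intermediate, co$truth$de$gene))
    de <- differential_expression(co$mrna_tumor, co$mrna_nat, config$alpha)
    prolif <- proliferation_screen(art$panel$dep_crispr, art$panel$dep_rnai,
                                   cand, threshold = config$dependency_threshold,
                                   line_fraction = config$line_fraction)
    prog <- prognostic_screen(list(list(expr = co$mrna_tumor,
                                        survival = co$survival)),
                              cand, alpha = config$alpha)
    art$filter_report <- intermediate_gene_filter(cand, de, prolif, prog)
    emit("filter_report.tsv", function(p)
      utils::write.table(art$filter_report, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })
  stage("survival", {
    co <- art$cohort
    genes <- co$truth$prognostic$gene
    art$risk_model <- backward_stepwise_cox(co$mrna_tumor, co$survival, genes)
    oc <- optimal_cutoff(art$risk_model$score,
                         co$survival[match(names(art$risk_model$score),
                                           co$survival$sample_id), ])
    art$risk_cutoff <- oc
    emit("risk_model.json", function(p)
      jsonlite::write_json(list(coefficients = as.list(art$risk_model$coefficients),
                                cutoff = oc$cutoff,
                                logrank_p_optimized = oc$result$p),
                           p, auto_unbox = TRUE, digits = NA))
  })
  stage("immune", {
    co <- art$cohort
    groups <- split(names(art$risk_model$score),
                    art$risk_model$score >= art$risk_cutoff$cutoff)
    art$cell_contrast <- cellscore_contrast(co$cell_scores,
                                             groups[["TRUE"]], groups[["FALSE"]],
                                             alpha = config$alpha)
    anchor_expr <- co$mrna_tumor$values[co$truth$anchor, ]
    dc <- co$cell_scores$scores["DC", colnames(co$mrna_tumor$values)]
    art$chi2 <- gene_cellscore_chi2(anchor_expr, dc)
    art$quadrant <- quadrant_stratification(anchor_expr, dc, co$survival)
    emit("cell_contrast.tsv", function(p)
      utils::write.table(art$cell_contrast, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  })
  stage("drugs", {
    pa <- art$panel
    labels <- lapply(rownames(pa$response$measure), function(d)
      categorize_cell_lines(pa$response, d))
    names(labels) <- rownames(pa$response$measure)
    cand <- rownames(pa$expr$values)
    art$drug_calls <- call_drug_genes(pa$expr, labels, cand,
                                       alpha = config$alpha)
    art$pan <- pan_classification(art$drug_calls)
    emit("drug_calls.tsv", function(p)
      utils::write.table(data.frame(gene = rownames(art$drug_calls$calls),
                                    art$drug_calls$calls),
                         p, sep = "\t", quote = FALSE, row.names = FALSE))
  })
  stage("signature", {
    prolif_and <- proliferation_screen(
      art$panel$dep_crispr, art$panel$dep_rnai,
      unique(c(art$pan$pan_sensitive, art$pan$pan_resistant)),
      threshold = config$dependency_threshold,
      line_fraction = config$line_fraction, mode = "and")
    ann <- gene_annotation(
      proliferation_both = prolif_and$gene[prolif_and$pass])
    art$signature <- build_signature(art$pan$pan_sensitive,
                                      art$pan$pan_resistant, ann)
    emit("signature_up.txt", function(p) writeLines(art$signature$up, p))
    emit("signature_down.txt", function(p) writeLines(art$signature$down, p))
    emit("signature_audit.json", function(p)
      jsonlite::write_json(art$signature$audit, p, auto_unbox = TRUE,
                           digits = NA))
  })

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  emit("manifest.tsv", function(p)
    utils::write.table(manifest, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  list(artifacts = art, manifest = manifest)
}
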