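# Shared configuration for the analysis drivers. Each numbered script is
# self-contained: it rebuilds what it needs from these seeded configs, so any
# stage can be rerun standalone and reproduces its outputs exactly.

library(impnet)

analysis_seed <- 2026L
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

# Synthetic LUAD-like cohort: anchor gene ZNF71, two direct repression
# targets, one two-hop chain through an intermediate that also carries
# survival and tumor/NAT differential signal (so it can pass the
# intermediate-gene filter), and a protein layer covering 80% of genes
# (the anchor itself is uncovered, as in the motivating datasets).
cohort_cfg <- cohort_config(
  n_tumor = 200, n_nat = 100, n_genes = 200,
  planted_direct = data.frame(target = c("OAS1", "STING1"),
                              anchor_state = 1L, target_state = -1L,
                              precision = 0.95),
  planted_twohop = data.frame(intermediate = "MED1", target = "TRIM5",
                              s_anchor = 1L, s_intermediate = 1L,
                              s_target = -1L, p1 = 0.95, p2 = 0.95),
  planted_prognostic = data.frame(gene = c("MED1", "DAG1", "SLC39A8"),
                                  beta = c(0.7, -0.7, -0.5)),
  planted_de = data.frame(gene = c("MED1", "DAG1", "SLC39A8", "OAS1"),
                          shift = c(1.5, -1.5, -1.5, -1)),
  seed = analysis_seed)

# Cell-line panel: the network intermediate is a common-essential gene; one
# drug carries planted sensitivity/resistance biomarkers.
panel_cfg <- cell_panel_config(
  n_cell_lines = 60,
  essential_genes = c("MED1", sprintf("ESS%03d", 1:19)),
  nonessential_genes = sprintf("NES%03d", 1:40),
  other_genes = c("OAS1", "STING1", "TRIM5", "DAG1", "SLC39A8", "KRT8", "ZNF71"),
  drug_ids = c("drugA", "drugB", "drugC"),
  planted_sensitive = list(drugA = "OAS1"),
  planted_resistant = list(drugA = "KRT8"),
  sensitive_fraction = 0.5, effect_size = 2,
  seed = analysis_seed + 1L)

write_tsv <- function(df, name) {
  path <- file.path(results_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
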