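# Generate the synthetic cohort and cell-line panel and write the raw
# matrices. Everything downstream is recomputed from the same seeded configs.

source("analysis/00_config.R")

cohort <- generate_cohort(cohort_cfg)
panel <- generate_cell_panel(panel_cfg)

# raw matrices are bulky working data, not result tables; keep them under
# scratch/ and the compact survival table under results/
raw_dir <- file.path("scratch", "synthetic")
dir.create(raw_dir, showWarnings = FALSE, recursive = TRUE)
write_matrix(cohort$mrna_tumor, file.path(raw_dir, "mrna_tumor.tsv"))
write_matrix(cohort$mrna_nat, file.path(raw_dir, "mrna_nat.tsv"))
write_matrix(cohort$protein_tumor, file.path(raw_dir, "protein_tumor.tsv"))
write_matrix(cohort$protein_nat, file.path(raw_dir, "protein_nat.tsv"))
write_tsv(cohort$survival, "survival.tsv")

message(sprintf("cohort: %d tumor / %d NAT samples, %d genes (protein covers %d)",
                ncol(cohort$mrna_tumor$values), ncol(cohort$mrna_nat$values),
                nrow(cohort$mrna_tumor$values),
                length(cohort$truth$protein_covered)))
message(sprintf("panel: %d cell lines, %d drugs; censoring rate %.2f",
                ncol(panel$expr$values), nrow(panel$response$measure),
                1 - mean(cohort$survival$event)))
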