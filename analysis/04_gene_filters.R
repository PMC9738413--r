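# The three intermediate-gene criteria: tumor/NAT differential expression,
# CRISPR-or-RNAi proliferation dependency, and prognostic stratification.
# Only genes passing all three feed the indirect networks.

source("analysis/00_config.R")

cohort <- generate_cohort(cohort_cfg)
panel <- generate_cell_panel(panel_cfg)

candidates <- unique(c(cohort$truth$twohop$intermediate, cohort$truth$de$gene,
                       grep("^BG00[0-3]", rownames(cohort$mrna_tumor$values),
                            value = TRUE)))

de <- differential_expression(cohort$mrna_tumor, cohort$mrna_nat)
prolif <- proliferation_screen(panel$dep_crispr, panel$dep_rnai, candidates)
prognostic <- prognostic_screen(list(list(expr = cohort$mrna_tumor,
                                          survival = cohort$survival)),
                                candidates)
report <- intermediate_gene_filter(candidates, de, prolif, prognostic)
write_tsv(report, "filter_report.tsv")
print(report[report$de_pass | report$dependency_pass | report$prognostic_pass, ],
      row.names = FALSE)
message("genes passing all three criteria: ",
        paste(report$gene[report$all_pass], collapse = ", "))
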