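# Drug-response gene calling on the synthetic panel, pan classification of
# the packaged 21-drug reference tables, signature construction, and
# oncogene / tumor-suppressor calling.

source("analysis/00_config.R")

panel <- generate_cell_panel(panel_cfg)
cohort <- generate_cohort(cohort_cfg)

# per-drug categorization and gene calls on the synthetic panel
labels <- sapply(rownames(panel$response$measure), function(d)
  list(categorize_cell_lines(panel$response, d)))
calls <- call_drug_genes(panel$expr, labels,
                         c("OAS1", "STING1", "TRIM5", "DAG1", "SLC39A8",
                           "KRT8", "ZNF71"))
pan <- pan_classification(calls)
write_tsv(data.frame(gene = rownames(calls$calls), calls$calls), "drug_calls.tsv")
message("synthetic pan-sensitive: ", paste(pan$pan_sensitive, collapse = ", "),
        " | pan-resistant: ", paste(pan$pan_resistant, collapse = ", "))

# packaged 21-drug reference tables: union counts across the panel
tab <- read_pan_gene_table("rnaseq")
message(sprintf("packaged RNA-seq panel: %d drugs, %d unique pan-sensitive, %d unique pan-resistant genes",
                length(unique(tab$drug)),
                length(unique(unlist(tab$pan_sensitive))),
                length(unique(unlist(tab$pan_resistant)))))

# checkpoint-gene correlation with drug response (planted sensitive gene is
# anti-correlated with IC50 by construction: high expression, low measure)
ici <- ici_correlation(panel$response, "drugA",
                       panel$expr$values["OAS1", ])
message(sprintf("drugA IC50 vs OAS1 expression: R = %.2f (p = %.2g, %d outliers removed)",
                ici$r, ici$p, ici$n_outliers))

# signature lists from the synthetic pan sets
prolif_and <- proliferation_screen(panel$dep_crispr, panel$dep_rnai,
                                   unique(c(pan$pan_sensitive, pan$pan_resistant)),
                                   mode = "and")
ann <- gene_annotation(proliferation_both = prolif_and$gene[prolif_and$pass])
sig <- build_signature(pan$pan_sensitive, pan$pan_resistant, ann)
writeLines(sig$up, file.path(results_dir, "signature_up.txt"))
writeLines(sig$down, file.path(results_dir, "signature_down.txt"))
message("signature: up = ", paste(sig$up, collapse = ", "),
        " | down = ", paste(sig$down, collapse = ", "))

# oncogene / tumor-suppressor calls on the protein layers
ot <- call_onco_tsg(cohort$protein_tumor, cohort$protein_nat, cohort$survival,
                    c(cohort_cfg$planted_prognostic$gene, "OAS1", "BG0001"))
write_tsv(ot$detail, "onco_tsg_detail.tsv")
message("oncogene candidates: ", paste(ot$oncogenes, collapse = ", "),
        " | tumor suppressors: ", paste(ot$tumor_suppressors, collapse = ", "))
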