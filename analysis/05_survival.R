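# Survival analyses: backward-stepwise Cox risk score over the designated
# prognostic genes, risk-score cutoff search, immune cell-score contrasts
# between the resulting risk groups, and the gene x dendritic-cell quadrant
# stratification of the anchor.

source("analysis/00_config.R")

cohort <- generate_cohort(cohort_cfg)

genes <- c(cohort_cfg$planted_prognostic$gene, "BG0001", "BG0002")
model <- backward_stepwise_cox(cohort$mrna_tumor, cohort$survival, genes)
print(model)

surv <- cohort$survival[match(names(model$score), cohort$survival$sample_id), ]
oc <- optimal_cutoff(model$score, surv)
message(sprintf("risk-score cutoff %.3f: optimized log-rank p = %.3g (selection-biased), HR %.2f",
                oc$cutoff, oc$result$p, oc$result$hr[["hr"]]))
jsonlite::write_json(list(coefficients = as.list(model$coefficients),
                          dropped = model$drop_sequence$gene,
                          cutoff = oc$cutoff, logrank_p_optimized = oc$result$p),
                     file.path(results_dir, "risk_model.json"),
                     auto_unbox = TRUE, digits = NA)

high <- names(model$score)[model$score >= oc$cutoff]
low <- setdiff(names(model$score), high)
contrast <- cellscore_contrast(cohort$cell_scores, high, low)
write_tsv(contrast, "cellscore_contrast.tsv")
message(sprintf("cell types with significant high- vs low-risk differences: %d/%d",
                sum(contrast$pass), nrow(contrast)))

anchor_expr <- cohort$mrna_tumor$values[cohort$truth$anchor, ]
dc <- cohort$cell_scores$scores["DC", names(anchor_expr)]
chi <- gene_cellscore_chi2(anchor_expr, dc)
message(sprintf("anchor x DC-score chi-squared = %.1f (p = %.2g)", chi$chisq, chi$p))
quad <- quadrant_stratification(anchor_expr, dc, cohort$survival)
print(quad)
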