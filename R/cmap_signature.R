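#' Connectivity-map signature construction and oncogene/TSG calling
#'
#' The up/down input lists for a connectivity-map query start from the
#' pan-sensitive and pan-resistant gene sets and are pruned by six rules, in
#' printed order:
#' (1) drop proliferation genes (dependency < -0.5 in >= 50% of lines in BOTH
#' CRISPR and RNAi) from the up list; (2) drop survival-protective genes
#' (Cox p < 0.05, HR < 1 in all cohorts) from the down list; (3) drop
#' survival-hazardous genes (p < 0.05, HR > 1 in all cohorts) from the up
#' list; (4) drop mesenchymal genes from the up list; (5) drop epithelial
#' genes from the down list; (6) append the immune-checkpoint genes to the
#' down list. Removals are independent set subtractions, so final membership
#' does not depend on rule order; the audit attribution does, and follows the
#' printed order (first matching rule wins).
#'
#' @name cmap-signature
NULL

#' Per-gene annotations feeding the signature rules
#'
#' Convenience constructor; any flag vector may be empty.
#'
#' @param proliferation_both genes with a dependency effect in >= 50% of lines
#'   in both CRISPR and RNAi (see [proliferation_screen()] with mode "and").
#' @param protective genes with Cox p < 0.05 and HR < 1 in all cohorts.
#' @param hazardous genes with Cox p < 0.05 and HR > 1 in all cohorts.
#' @param epithelial,mesenchymal marker sets; packaged defaults.
#' @return a `GeneAnnotation` list.
#' @export
gene_annotation <- function(proliferation_both = character(0),
                            protective = character(0),
                            hazardous = character(0),
                            epithelial = epithelial_genes(),
                            mesenchymal = mesenchymal_genes()) {
  both <- intersect(protective, hazardous)
  if (length(both))
    stop("genes flagged both protective and hazardous: ",
         paste(both, collapse = ", "))
  structure(list(proliferation_both = proliferation_both,
                 protective = protective, hazardous = hazardous,
                 epithelial = epithelial, mesenchymal = mesenchymal),
            class = "GeneAnnotation")
}

#' Build the up/down signature lists
#'
#' @param pan_sensitive,pan_resistant gene sets from [pan_classification()].
#' @param ann a `GeneAnnotation`.
#' @param ici immune-checkpoint genes appended to the down list; canonical
#'   symbols (aliases are resolved).
#' @return a `SignatureLists` object: `up`, `down`, and an `audit` data.frame
#'   recording every removal/addition with its rule number.
#' @export
build_signature <- function(pan_sensitive, pan_resistant,
                            ann = gene_annotation(), ici = ici_genes()) {
  stopifnot(inherits(ann, "GeneAnnotation"))
  ici <- unique(normalize_gene_ids(ici))
  audit <- data.frame(gene = character(0), list = character(0),
                      action = character(0), rule = integer(0))
  note <- function(genes, list_, action, rule) {
    if (length(genes) == 0) return(invisible())
    audit <<- rbind(audit, data.frame(gene = genes, list = list_,
                                      action = action, rule = rule))
  }
  up <- unique(pan_sensitive)
  down <- unique(pan_resistant)

  # printed rule order; first matching rule gets the audit attribution
  r1 <- intersect(up, ann$proliferation_both)
  note(r1, "up", "removed", 1L); up <- setdiff(up, r1)
  r2 <- intersect(down, ann$protective)
  note(r2, "down", "removed", 2L); down <- setdiff(down, r2)
  r3 <- intersect(up, ann$hazardous)
  note(r3, "up", "removed", 3L); up <- setdiff(up, r3)
  r4 <- intersect(up, ann$mesenchymal)
  note(r4, "up", "removed", 4L); up <- setdiff(up, r4)
  r5 <- intersect(down, ann$epithelial)
  note(r5, "down", "removed", 5L); down <- setdiff(down, r5)
  conflict <- intersect(ici, up)
  if (length(conflict))
    stop("checkpoint gene(s) already in the up list: ",
         paste(conflict, collapse = ", "))
  added <- setdiff(ici, down)
  note(added, "down", "added", 6L)
  down <- union(down, added)

  overlap <- intersect(up, down)
  if (length(overlap))
    stop("up and down lists overlap: ", paste(overlap, collapse = ", "))
  structure(list(up = sort(up), down = sort(down), audit = audit),
            class = "SignatureLists")
}

#' @export
print.SignatureLists <- function(x, ...) {
  cat(sprintf("SignatureLists: %d up, %d down (%d audit records)\n",
              length(x$up), length(x$down), nrow(x$audit)))
  invisible(x)
}

#' Call candidate oncogenes and tumor suppressors from protein profiles
#'
#' An oncogene candidate has significantly higher protein expression in
#' tumors than NATs (two-sample t-test, p < alpha) and is survival-hazardous
#' (univariate Cox on tumor protein expression, p < alpha, HR > 1); a tumor
#' suppressor candidate is higher in NATs and survival-protective (HR < 1).
#' Everything else is unclassified.
#'
#' @param protein_tumor,protein_nat protein-layer `ExpressionMatrix` objects.
#' @param survival a `SurvivalTable` for the tumor samples.
#' @param candidates genes to classify; genes lacking protein data in either
#'   compartment or survival-aligned expression are unclassified with a note.
#' @param alpha significance level, default 0.05.
#' @return list with `oncogenes`, `tumor_suppressors`, and a per-gene `detail`
#'   data.frame (t p, direction, HR, Cox p, class).
#' @export
call_onco_tsg <- function(protein_tumor, protein_nat, survival, candidates,
                          alpha = 0.05) {
  stopifnot(inherits(protein_tumor, "ExpressionMatrix"),
            inherits(protein_nat, "ExpressionMatrix"))
  common <- intersect(colnames(protein_tumor$values), survival$sample_id)
  surv <- survival[match(common, survival$sample_id), ]
  y <- survival::Surv(surv$time_months, surv$event)
  rows <- lapply(candidates, function(g) {
    if (!g %in% rownames(protein_tumor$values) ||
        !g %in% rownames(protein_nat$values))
      return(data.frame(gene = g, t_p = NA_real_, direction = NA_character_,
                        hr = NA_real_, cox_p = NA_real_,
                        class = "unclassified", note = "no protein coverage"))
    a <- protein_tumor$values[g, ]; b <- protein_nat$values[g, ]
    tt <- tryCatch(stats::t.test(a[!is.na(a)], b[!is.na(b)]),
                   error = function(e) NULL)
    x <- protein_tumor$values[g, common]
    ok <- !is.na(x)
    cx <- if (sum(ok) >= 10 && sum(surv$event[ok]) > 0)
      tryCatch(survival::coxph(y[ok] ~ x[ok]), error = function(e) NULL)
    else NULL
    if (is.null(tt) || is.null(cx))
      return(data.frame(gene = g, t_p = NA_real_, direction = NA_character_,
                        hr = NA_real_, cox_p = NA_real_,
                        class = "unclassified",
                        note = "insufficient aligned data"))
    s <- summary(cx)
    hr <- unname(s$conf.int[1, "exp(coef)"])
    cox_p <- unname(s$coefficients[1, "Pr(>|z|)"])
    dir <- if (mean(a, na.rm = TRUE) > mean(b, na.rm = TRUE))
      "higher_in_tumor" else "higher_in_nat"
    cls <- "unclassified"
    if (tt$p.value < alpha && cox_p < alpha) {
      if (dir == "higher_in_tumor" && hr > 1) cls <- "oncogene"
      if (dir == "higher_in_nat" && hr < 1) cls <- "tumor_suppressor"
    }
    data.frame(gene = g, t_p = tt$p.value, direction = dir, hr = hr,
               cox_p = cox_p, class = cls, note = "")
  })
  detail <- do.call(rbind, rows)
  list(oncogenes = detail$gene[detail$class == "oncogene"],
       tumor_suppressors = detail$gene[detail$class == "tumor_suppressor"],
       detail = detail)
}
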