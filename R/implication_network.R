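#' Boolean implication rules
#'
#' A rule "gene A in state sa implies gene B in state sb" is scored by how far
#' the conditional frequency of the consequent (precision) rises above its
#' marginal (baseline), with coverage measured by scope (fraction of samples
#' where the premise holds). Significance uses a one-tailed z statistic on the
#' precision against the baseline:
#' z = (precision - baseline) / sqrt(baseline * (1 - baseline) / n_premise),
#' filtered at z >= 1.64 (one-sided 5%). Premise and consequent states are
#' restricted to {-1, +1}; the normal state never anchors a rule.
#'
#' @name implication-rules
NULL

IMPLICATION_Z <- 1.64

rule_row <- function(premise_gene = NA_character_, premise_state = NA_integer_,
                     consequent_gene = NA_character_, consequent_state = NA_integer_,
                     n = 0L, n_premise = 0L, scope = NA_real_, precision = NA_real_,
                     baseline = NA_real_, z = NA_real_, significant = FALSE,
                     reason = "", layer_from = "mrna", layer_to = "mrna") {
  data.frame(premise_gene = premise_gene, premise_state = premise_state,
             consequent_gene = consequent_gene, consequent_state = consequent_state,
             n = n, n_premise = n_premise, scope = scope, precision = precision,
             baseline = baseline, z = z, significant = significant,
             reason = reason, layer_from = layer_from, layer_to = layer_to,
             stringsAsFactors = FALSE)
}

#' Score a single implication rule from two ternary state vectors
#'
#' @param states_a,states_b equal-length ternary vectors (values in {-1,0,1});
#'   NA entries (or entries flagged via `missing_a`/`missing_b`) are dropped
#'   pairwise.
#' @param sa,sb premise and consequent states, each -1 or +1.
#' @param min_support minimum number of premise-true samples for the z test.
#' @param scope_floor minimum scope for a rule to be significant.
#' @param z_threshold one-tailed z cutoff, default 1.64 (95% one-sided).
#' @param missing_a,missing_b optional logical vectors of missingness flags.
#' @param genes,layers optional length-2 character vectors of gene names and
#'   layer tags for labeling.
#' @return one-row data.frame with fields n, n_premise, scope, precision,
#'   baseline, z, significant and a failure `reason` when not significant.
#' @export
rule_stats <- function(states_a, states_b, sa, sb, min_support = 5L,
                       scope_floor = 0.10, z_threshold = IMPLICATION_Z,
                       missing_a = NULL, missing_b = NULL,
                       genes = c(NA_character_, NA_character_),
                       layers = c("mrna", "mrna")) {
  stopifnot(length(states_a) == length(states_b),
            sa %in% c(-1L, 1L), sb %in% c(-1L, 1L), min_support >= 1)
  drop <- is.na(states_a) | is.na(states_b)
  if (!is.null(missing_a)) drop <- drop | missing_a
  if (!is.null(missing_b)) drop <- drop | missing_b
  a <- states_a[!drop]; b <- states_b[!drop]
  n <- length(a)
  out <- rule_row(genes[1], as.integer(sa), genes[2], as.integer(sb),
                  layer_from = layers[1], layer_to = layers[2])
  out$n <- n
  if (n == 0) { out$reason <- "no paired samples"; return(out) }
  n_premise <- sum(a == sa)
  n_joint <- sum(a == sa & b == sb)
  n_conseq <- sum(b == sb)
  out$n_premise <- n_premise
  out$scope <- n_premise / n
  out$baseline <- n_conseq / n
  if (n_premise < min_support) {
    out$precision <- if (n_premise > 0) n_joint / n_premise else NA_real_
    out$reason <- "insufficient support"
    return(out)
  }
  out$precision <- n_joint / n_premise
  if (out$baseline <= 0 || out$baseline >= 1) {
    out$reason <- "degenerate baseline"
    return(out)
  }
  out$z <- (out$precision - out$baseline) /
    sqrt(out$baseline * (1 - out$baseline) / n_premise)
  if (out$z >= z_threshold && out$scope >= scope_floor) {
    out$significant <- TRUE
  } else if (out$z < z_threshold) {
    out$reason <- "z below threshold"
  } else {
    out$reason <- "scope below floor"
  }
  out
}

empty_rules <- function() rule_row()[0, ]

new_network <- function(anchor, anchor_state, rules, hop_structure = list(),
                        compartment = NA_character_, layers = "mrna",
                        notes = character(0)) {
  structure(list(anchor = anchor, anchor_state = as.integer(anchor_state),
                 rules = rules, hop_structure = hop_structure,
                 compartment = compartment, layers = layers, notes = notes),
            class = "ImplicationNetwork")
}

#' @export
print.ImplicationNetwork <- function(x, ...) {
  cat(sprintf("ImplicationNetwork: anchor %s(%+d), %d rule(s), %d path(s)\n",
              x$anchor, x$anchor_state, nrow(x$rules), length(x$hop_structure)))
  if (length(x$notes)) cat(" notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

tern_vec <- function(tern, gene) tern$states[gene, ]
tern_miss <- function(tern, gene) tern$missing[gene, ]

# Score (premise_gene, ps) -> target for both consequent states and keep the
# winning significant rule, if any. Both consequent states passing indicates
# small support; the larger z wins (they are mutually exclusive events).
best_rule <- function(tern_from, tern_to, premise_gene, ps, target,
                      min_support, scope_floor, z_threshold, layers,
                      shared = NULL) {
  a <- tern_vec(tern_from, premise_gene); ma <- tern_miss(tern_from, premise_gene)
  b <- tern_vec(tern_to, target); mb <- tern_miss(tern_to, target)
  if (!is.null(shared)) {
    a <- a[shared]; ma <- ma[shared]; b <- b[shared]; mb <- mb[shared]
  }
  cand <- do.call(rbind, lapply(c(-1L, 1L), function(sb)
    rule_stats(a, b, ps, sb, min_support = min_support,
               scope_floor = scope_floor, z_threshold = z_threshold,
               missing_a = ma, missing_b = mb,
               genes = c(premise_gene, target), layers = layers)))
  cand <- cand[cand$significant, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_rules())
  cand[which.max(cand$z), , drop = FALSE]
}

#' Direct implication network around an anchor gene
#'
#' For each target, the rule (anchor, anchor_state) -> (target, state) is
#' scored for both consequent states and included when significant (keeping
#' the larger-z state if both pass).
#'
#' @param tern a `TernaryMatrix`.
#' @param anchor anchor gene id (must be present).
#' @param anchor_state -1 or +1.
#' @param targets candidate target gene ids; absent genes are skipped and
#'   listed in the network notes.
#' @param min_support,scope_floor,z_threshold rule-filter settings, see
#'   [rule_stats()].
#' @return an `ImplicationNetwork`.
#' @export
direct_network <- function(tern, anchor, anchor_state, targets,
                           min_support = 5L, scope_floor = 0.10,
                           z_threshold = IMPLICATION_Z) {
  stopifnot(inherits(tern, "TernaryMatrix"))
  if (!anchor %in% rownames(tern$states)) stop("anchor gene absent: ", anchor)
  notes <- character(0)
  missing_targets <- setdiff(targets, rownames(tern$states))
  if (length(missing_targets))
    notes <- paste0("targets absent from matrix: ",
                    paste(missing_targets, collapse = ", "))
  targets <- setdiff(intersect(targets, rownames(tern$states)), anchor)
  layers <- c(tern$record$layer, tern$record$layer)
  if (sum(tern$states[anchor, ] == anchor_state, na.rm = TRUE) == 0) {
    warning("anchor has no samples in the premise state; empty network")
    return(new_network(anchor, anchor_state, empty_rules(),
                       compartment = tern$record$compartment,
                       layers = tern$record$layer, notes = notes))
  }
  rules <- do.call(rbind, c(list(empty_rules()), lapply(targets, function(tg)
    best_rule(tern, tern, anchor, anchor_state, tg,
              min_support, scope_floor, z_threshold, layers))))
  new_network(anchor, anchor_state, rules,
              compartment = tern$record$compartment,
              layers = tern$record$layer, notes = notes)
}

# Shared two-hop engine; hop 2 may run on a different matrix / sample subset.
hop_paths <- function(tern1, tern2, anchor, anchor_state, targets,
                      intermediates, min_support, scope_floor, z_threshold,
                      layers1, layers2, shared2 = NULL) {
  rules <- empty_rules()
  hop_structure <- list()
  intermediates <- setdiff(intersect(intermediates, rownames(tern1$states)),
                           c(anchor, targets))
  targets <- setdiff(intersect(targets, rownames(tern2$states)), anchor)
  for (m in intermediates) {
    h1 <- best_rule(tern1, tern1, anchor, anchor_state, m,
                    min_support, scope_floor, z_threshold, layers1)
    if (nrow(h1) == 0) next
    sm <- h1$consequent_state
    if (!m %in% rownames(tern2$states)) next
    for (tg in targets) {
      h2 <- best_rule(tern2, tern2, m, sm, tg,
                      min_support, scope_floor, z_threshold, layers2,
                      shared = shared2)
      if (nrow(h2) == 0) next
      rules <- rbind(rules, h1, h2)
      hop_structure[[tg]] <- c(hop_structure[[tg]],
                               list(list(intermediate = m,
                                         states = c(anchor_state, sm,
                                                    h2$consequent_state),
                                         z = c(h1$z, h2$z))))
    }
  }
  rules <- unique(rules)
  list(rules = rules, hop_structure = hop_structure)
}

#' Two-hop (indirect) implication network through intermediate genes
#'
#' A path anchor -> M -> target is included iff both hops are significant and
#' state-consistent: the consequent state of hop 1 is the premise state of hop
#' 2. Intermediates are expected to be pre-screened (see
#' [intermediate_gene_filter()]); targets reachable directly remain eligible.
#'
#' @inheritParams direct_network
#' @param intermediates candidate intermediate gene ids.
#' @return an `ImplicationNetwork` with per-target paths in `hop_structure`.
#' @export
twohop_network <- function(tern, anchor, anchor_state, targets, intermediates,
                           min_support = 5L, scope_floor = 0.10,
                           z_threshold = IMPLICATION_Z) {
  stopifnot(inherits(tern, "TernaryMatrix"))
  if (!anchor %in% rownames(tern$states)) stop("anchor gene absent: ", anchor)
  layer <- tern$record$layer
  res <- hop_paths(tern, tern, anchor, anchor_state, targets, intermediates,
                   min_support, scope_floor, z_threshold,
                   c(layer, layer), c(layer, layer))
  new_network(anchor, anchor_state, res$rules, res$hop_structure,
              compartment = tern$record$compartment, layers = layer)
}

#' Cross-layer implication network (mRNA -> mRNA -> protein)
#'
#' Hop 1 runs within the mRNA layer; hop 2 connects the intermediate's mRNA
#' state to the target's protein state on the samples shared between the two
#' matrices. Targets absent from the protein layer (coverage gaps are common)
#' are skipped silently and listed in the network notes.
#'
#' @param tern_mrna,tern_protein `TernaryMatrix` objects for the two layers.
#' @inheritParams twohop_network
#' @return an `ImplicationNetwork` with layer tags on each rule.
#' @export
crosslayer_network <- function(tern_mrna, tern_protein, anchor, anchor_state,
                               targets, intermediates, min_support = 5L,
                               scope_floor = 0.10, z_threshold = IMPLICATION_Z) {
  stopifnot(inherits(tern_mrna, "TernaryMatrix"),
            inherits(tern_protein, "TernaryMatrix"))
  if (!anchor %in% rownames(tern_mrna$states)) stop("anchor gene absent: ", anchor)
  shared <- intersect(colnames(tern_mrna$states), colnames(tern_protein$states))
  if (length(shared) < min_support) stop("no (or too few) shared samples between layers")
  skipped <- setdiff(targets, rownames(tern_protein$states))
  notes <- if (length(skipped))
    paste0("targets without protein coverage: ", paste(skipped, collapse = ", "))
  else character(0)

  # hop-2 view: intermediate rows carry mRNA states, target rows protein
  # states, both restricted to the shared samples, so a single matrix feeds
  # best_rule() with the premise on the mRNA layer and the consequent on the
  # protein layer.
  targ_ok <- intersect(setdiff(targets, skipped), rownames(tern_protein$states))
  inter_ok <- setdiff(intersect(intermediates, rownames(tern_mrna$states)), targ_ok)
  comb <- structure(list(
    states = rbind(tern_mrna$states[inter_ok, shared, drop = FALSE],
                   tern_protein$states[targ_ok, shared, drop = FALSE]),
    missing = rbind(tern_mrna$missing[inter_ok, shared, drop = FALSE],
                    tern_protein$missing[targ_ok, shared, drop = FALSE]),
    record = tern_protein$record), class = "TernaryMatrix")
  res <- hop_paths(tern_mrna, comb, anchor, anchor_state, targ_ok, inter_ok,
                   min_support, scope_floor, z_threshold,
                   c("mrna", "mrna"), c("mrna", "protein"))
  net <- new_network(anchor, anchor_state, res$rules, res$hop_structure,
                     compartment = tern_mrna$record$compartment,
                     layers = c("mrna", "protein"), notes = notes)
  net
}
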