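#' Synthetic multi-omics cohort generator
#'
#' Generates a seeded cohort with the statistical structure the downstream
#' pipeline assumes: paired tumor/NAT mRNA and protein layers with partially
#' overlapping gene coverage, designated housekeeping genes, a planted
#' anchor-centered implication structure (direct, two-hop), proportional-
#' hazards survival linked to designated genes, and an xCell-style cell-score
#' matrix with one dendritic-cell-like type anti-correlated with the anchor.
#'
#' The generative model is latent-state first: each gene draws a ternary state
#' per sample (tail fraction split evenly between -1 and +1), and the
#' continuous value is the state mean (-delta, 0, +delta) plus Gaussian noise.
#' Planted implication edges fix the conditional state distribution so that
#' P(target_state | anchor_state) equals the planted precision, which makes
#' planted precision directly comparable to the precision recovered by
#' [rule_stats()] after re-discretization.
#'
#' @name synthetic-cohort
NULL

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Cohort configuration
#'
#' @param n_tumor,n_nat sample counts per compartment.
#' @param n_genes total number of genes in the mRNA layer (planted and
#'   housekeeping genes count toward the total; background genes are added to
#'   reach it).
#' @param housekeeping_ids designated housekeeping genes (14 by default).
#' @param anchor_id the anchor gene.
#' @param planted_direct data.frame with columns `target`, `anchor_state`,
#'   `target_state`, `precision` (each in (marginal, 1]).
#' @param planted_twohop data.frame with columns `intermediate`, `target`,
#'   `s_anchor`, `s_intermediate`, `s_target`, `p1`, `p2`.
#' @param planted_prognostic data.frame with columns `gene`, `beta`
#'   (log-hazard per standardized expression unit).
#' @param planted_de data.frame with columns `gene`, `shift` (tumor-minus-NAT
#'   mean shift on the expression scale).
#' @param protein_coverage fraction of genes present in the protein layer.
#'   The anchor is always excluded from the protein layer, mimicking the
#'   coverage gap of the motivating datasets; planted targets are always
#'   included.
#' @param delta over/under-expression state mean (state means are -delta, 0,
#'   +delta).
#' @param noise_sd Gaussian emission noise sd.
#' @param protein_noise_sd extra noise added when deriving protein from mRNA.
#' @param tail_fraction combined fraction of non-normal latent states (0.30,
#'   matching the discretization calibration target).
#' @param censor_rate approximate fraction of censored survival times.
#' @param n_cell_types number of cell-score rows besides the DC-like type.
#' @param seed integer seed; all outputs are deterministic given the config.
#' @return a `CohortConfig` list.
#' @export
cohort_config <- function(n_tumor = 100, n_nat = 100, n_genes = 200,
                          housekeeping_ids = housekeeping_genes(),
                          anchor_id = "ZNF71",
                          planted_direct = NULL, planted_twohop = NULL,
                          planted_prognostic = NULL, planted_de = NULL,
                          protein_coverage = 0.8, delta = 2, noise_sd = 1,
                          protein_noise_sd = 0.5, tail_fraction = 0.30,
                          censor_rate = 0.3, n_cell_types = 20, seed = 1L) {
  stopifnot(protein_coverage > 0, protein_coverage <= 1, delta > 0,
            noise_sd > 0, tail_fraction > 0, tail_fraction < 1,
            censor_rate >= 0, censor_rate < 1, n_tumor >= 2, n_nat >= 2)
  base_tail <- tail_fraction / 2
  chk_prec <- function(p, state_prob) {
    # implied marginal of the consequent state under the planted model
    marg <- state_prob * p + (1 - state_prob) * base_tail
    if (any(p <= marg))
      stop("planted precision at or below the consequent's marginal; ",
           "the rule would be unlearnable")
    if (any(p > 1)) stop("precision must be in (marginal, 1]")
  }
  if (!is.null(planted_direct)) chk_prec(planted_direct$precision, base_tail)
  if (!is.null(planted_twohop)) {
    chk_prec(planted_twohop$p1, base_tail)
    chk_prec(planted_twohop$p2, base_tail)
  }
  structure(list(n_tumor = n_tumor, n_nat = n_nat, n_genes = n_genes,
                 housekeeping_ids = housekeeping_ids, anchor_id = anchor_id,
                 planted_direct = planted_direct,
                 planted_twohop = planted_twohop,
                 planted_prognostic = planted_prognostic,
                 planted_de = planted_de,
                 protein_coverage = protein_coverage, delta = delta,
                 noise_sd = noise_sd, protein_noise_sd = protein_noise_sd,
                 tail_fraction = tail_fraction, censor_rate = censor_rate,
                 n_cell_types = n_cell_types, seed = as.integer(seed)),
            class = "CohortConfig")
}

draw_states <- function(n, tail) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE,
         prob = c(tail / 2, 1 - tail, tail / 2))
}

# Draw a state vector conditional on a parent state vector: where the parent
# is in `ps`, emit `cs` with probability `prec`, otherwise a state drawn from
# the base distribution restricted to the other two states; where the parent
# is not in `ps`, draw from the base distribution.
draw_conditional <- function(parent, ps, cs, prec, tail) {
  n <- length(parent)
  out <- draw_states(n, tail)
  idx <- which(parent == ps)
  if (length(idx)) {
    hit <- stats::runif(length(idx)) < prec
    others <- setdiff(c(-1L, 0L, 1L), cs)
    pother <- c(`-1` = tail / 2, `0` = 1 - tail, `1` = tail / 2)[as.character(others)]
    out[idx] <- ifelse(hit, cs,
                       sample(others, length(idx), replace = TRUE,
                              prob = pother / sum(pother)))
  }
  out
}

#' Generate a synthetic cohort
#'
#' @param config a `CohortConfig` from [cohort_config()].
#' @return a list with elements `mrna_tumor`, `mrna_nat`, `protein_tumor`,
#'   `protein_nat` (ExpressionMatrix), `survival` (SurvivalTable),
#'   `cell_scores` (CellScoreMatrix), and `truth` (planted edges, paths,
#'   hazard coefficients, DE shifts, protein coverage, and the latent tumor
#'   state matrix for recovery tests).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  with_seed(config$seed, {
    cfg <- config
    planted_genes <- unique(c(
      cfg$anchor_id,
      cfg$planted_direct$target,
      cfg$planted_twohop$intermediate, cfg$planted_twohop$target,
      cfg$planted_prognostic$gene, cfg$planted_de$gene))
    hk <- setdiff(cfg$housekeeping_ids, planted_genes)
    n_bg <- cfg$n_genes - length(planted_genes) - length(hk)
    if (n_bg < 0) stop("n_genes too small for the planted gene sets")
    bg <- sprintf("BG%04d", seq_len(n_bg))
    genes <- c(planted_genes, hk, bg)
    tum <- sprintf("T%03d", seq_len(cfg$n_tumor))
    nat <- sprintf("N%03d", seq_len(cfg$n_nat))

    gen_compartment <- function(samples, planted) {
      n <- length(samples)
      states <- matrix(0L, length(genes), n, dimnames = list(genes, samples))
      for (g in setdiff(genes, hk)) states[g, ] <- draw_states(n, cfg$tail_fraction)
      if (planted) {
        anc <- states[cfg$anchor_id, ]
        pd <- cfg$planted_direct
        if (!is.null(pd)) for (i in seq_len(nrow(pd)))
          states[pd$target[i], ] <- draw_conditional(
            anc, pd$anchor_state[i], pd$target_state[i], pd$precision[i],
            cfg$tail_fraction)
        pt <- cfg$planted_twohop
        if (!is.null(pt)) for (i in seq_len(nrow(pt))) {
          states[pt$intermediate[i], ] <- draw_conditional(
            anc, pt$s_anchor[i], pt$s_intermediate[i], pt$p1[i],
            cfg$tail_fraction)
          states[pt$target[i], ] <- draw_conditional(
            states[pt$intermediate[i], ], pt$s_intermediate[i],
            pt$s_target[i], pt$p2[i], cfg$tail_fraction)
        }
      }
      vals <- states * cfg$delta +
        matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
               length(genes), n)
      # housekeeping genes are state-independent by construction
      vals[hk, ] <- matrix(stats::rnorm(length(hk) * n, sd = cfg$noise_sd),
                           length(hk), n)
      states[hk, ] <- 0L
      dimnames(vals) <- list(genes, samples)
      list(states = states, values = vals)
    }

    tu <- gen_compartment(tum, planted = TRUE)
    na_ <- gen_compartment(nat, planted = FALSE)
    if (!is.null(cfg$planted_de))
      tu$values[cfg$planted_de$gene, ] <-
        tu$values[cfg$planted_de$gene, ] + cfg$planted_de$shift

    # protein layer: anchor always absent; planted targets always covered
    must <- setdiff(unique(c(cfg$planted_direct$target,
                             cfg$planted_twohop$intermediate,
                             cfg$planted_twohop$target)), cfg$anchor_id)
    eligible <- setdiff(genes, c(cfg$anchor_id, must))
    n_cov <- max(length(must), round(cfg$protein_coverage * length(genes)))
    covered <- c(must, sample(eligible, min(length(eligible), n_cov - length(must))))
    prot <- function(comp) {
      v <- comp$values[covered, , drop = FALSE] +
        matrix(stats::rnorm(length(covered) * ncol(comp$values),
                            sd = cfg$protein_noise_sd),
               length(covered), ncol(comp$values))
      v
    }

    # survival on tumor samples: exponential hazard proportional to
    # exp(sum beta * standardized expression); independent exponential
    # censoring tuned to the configured censor rate
    lp <- rep(0, cfg$n_tumor)
    pp <- cfg$planted_prognostic
    if (!is.null(pp)) for (i in seq_len(nrow(pp)))
      lp <- lp + pp$beta[i] * as.numeric(scale(tu$values[pp$gene[i], ]))
    base_h <- log(2) / 24  # median survival 24 months at lp = 0
    t_event <- stats::rexp(cfg$n_tumor, rate = base_h * exp(lp))
    if (cfg$censor_rate > 0) {
      c_rate <- base_h * cfg$censor_rate / (1 - cfg$censor_rate)
      t_cens <- stats::rexp(cfg$n_tumor, rate = c_rate)
    } else t_cens <- rep(Inf, cfg$n_tumor)
    surv <- survival_table(tum, pmin(t_event, t_cens),
                           as.integer(t_event <= t_cens))

    # cell scores: log-normal positives; DC-like type anti-correlated with
    # the anchor's tumor expression
    ct <- sprintf("CT%02d", seq_len(cfg$n_cell_types))
    sc <- matrix(exp(stats::rnorm(cfg$n_cell_types * cfg$n_tumor, sd = 0.5)),
                 cfg$n_cell_types, cfg$n_tumor, dimnames = list(ct, tum))
    anchor_z <- as.numeric(scale(tu$values[cfg$anchor_id, ]))
    dc <- exp(-0.8 * anchor_z + stats::rnorm(cfg$n_tumor, sd = 0.5))
    sc <- rbind(sc, DC = dc)
    cells <- cell_score_matrix(sc)

    list(
      mrna_tumor = expression_matrix(tu$values, "mrna", "tumor"),
      mrna_nat = expression_matrix(na_$values, "mrna", "nat"),
      protein_tumor = expression_matrix(prot(tu), "protein", "tumor"),
      protein_nat = expression_matrix(prot(na_), "protein", "nat"),
      survival = surv,
      cell_scores = cells,
      truth = list(direct = cfg$planted_direct, twohop = cfg$planted_twohop,
                   prognostic = cfg$planted_prognostic, de = cfg$planted_de,
                   protein_covered = covered, housekeeping = hk,
                   anchor = cfg$anchor_id,
                   latent_tumor_states = tu$states))
  })
}
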