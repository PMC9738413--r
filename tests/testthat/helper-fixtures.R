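# Small programmatic fixtures shared across test files.

make_expr <- function(values, layer = "mrna", compartment = "tumor",
                      genes = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  expression_matrix(values, layer, compartment)
}

# TernaryMatrix straight from a state matrix (record is a stub; tests that
# exercise calibration build records via calibrate_k instead)
make_tern <- function(states, layer = "mrna", compartment = "tumor") {
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("G%03d", seq_len(nrow(states)))
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("S%03d", seq_len(ncol(states)))
  rec <- structure(list(k = 1, target_fraction = 0.3, tail_mode = "combined",
                        achieved_fraction = NA_real_,
                        housekeeping_ids = character(0),
                        center = stats::setNames(rep(0, nrow(states)), rownames(states)),
                        sd = stats::setNames(rep(1, nrow(states)), rownames(states)),
                        layer = layer, compartment = compartment),
                   class = "DiscretizationRecord")
  structure(list(states = states,
                 missing = matrix(FALSE, nrow(states), ncol(states),
                                  dimnames = dimnames(states)),
                 record = rec),
            class = "TernaryMatrix")
}

# Independent count-based oracle for implication rule statistics.
rule_oracle <- function(a, b, sa, sb, min_support = 5, scope_floor = 0.10,
                        z_threshold = 1.64) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  np <- 0; nj <- 0; nc <- 0
  for (i in seq_len(n)) {
    if (a[i] == sa) {
      np <- np + 1
      if (b[i] == sb) nj <- nj + 1
    }
    if (b[i] == sb) nc <- nc + 1
  }
  prec <- if (np > 0) nj / np else NA_real_
  base <- if (n > 0) nc / n else NA_real_
  z <- NA_real_
  sig <- FALSE
  if (np >= min_support && !is.na(base) && base > 0 && base < 1) {
    z <- (prec - base) / sqrt(base * (1 - base) / np)
    sig <- z >= z_threshold && (np / n) >= scope_floor
  }
  list(n = n, n_premise = np, scope = if (n > 0) np / n else NA_real_,
       precision = prec, baseline = base, z = z, significant = sig)
}

# Brute-force pan classification of one gene's call vector.
pan_oracle_gene <- function(calls) {
  if (all(calls != "resistant") && any(calls == "sensitive")) return("pan_sensitive")
  if (all(calls != "sensitive") && any(calls == "resistant")) return("pan_resistant")
  "neither"
}

std_cohort <- function(seed, ...) {
  generate_cohort(cohort_config(seed = seed, ...))
}
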