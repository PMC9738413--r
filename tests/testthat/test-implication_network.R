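test_that("rule statistics match direct arithmetic on worked examples", {
  # n=100, premise true in 50, joint 45, consequent marginal 50:
  # precision .9, baseline .5, z = .4 / sqrt(.25/50) = 5.657
  a <- c(rep(1L, 50), rep(0L, 50))
  b <- c(rep(1L, 45), rep(-1L, 5), rep(1L, 5), rep(-1L, 45))
  r <- rule_stats(a, b, 1L, 1L)
  expect_equal(r$precision, 0.9)
  expect_equal(r$baseline, 0.5)
  expect_equal(r$z, 0.4 / sqrt(0.25 / 50), tolerance = 1e-12)
  expect_true(r$significant)

  # perfect implication: precision 1, baseline .5, n_premise 20 => z ~ 4.47
  a2 <- c(rep(1L, 20), rep(0L, 20))
  b2 <- c(rep(-1L, 20), rep(0L, 10), rep(-1L, 0), rep(1L, 10))
  r2 <- rule_stats(a2, b2, 1L, -1L)
  expect_equal(r2$precision, 1)
  expect_equal(r2$z, 0.5 / sqrt(0.25 / 20), tolerance = 1e-12)
  expect_true(r2$significant)

  # independence: precision equals baseline => z = 0, not significant
  a3 <- rep(c(1L, 0L), 50)
  b3 <- rep(c(1L, 1L, -1L, -1L), 25)
  r3 <- rule_stats(a3, b3, 1L, 1L)
  expect_equal(r3$z, 0)
  expect_false(r3$significant)
})

test_that("rule edge cases: support floor, degenerate baseline, missing cells", {
  r <- rule_stats(c(1L, 0L, 0L, 0L), c(1L, 1L, 1L, 0L), 1L, 1L, min_support = 5)
  expect_false(r$significant)
  expect_match(r$reason, "insufficient support")

  r2 <- rule_stats(rep(1L, 10), rep(1L, 10), 1L, 1L)
  expect_false(r2$significant)
  expect_match(r2$reason, "degenerate baseline")

  a <- c(1L, 1L, 0L, 0L, 1L, 0L)
  b <- c(1L, 1L, -1L, -1L, 1L, 1L)
  r3 <- rule_stats(a, b, 1L, 1L, min_support = 1,
                   missing_a = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                   missing_b = rep(FALSE, 6))
  expect_identical(r3$n, 5L)
  expect_identical(r3$n_premise, 2L)
})

test_that("rule statistics agree exactly with a count-based oracle", {
  set.seed(33)
  for (i in 1:400) {
    len <- sample(4:8, 1)
    a <- sample(c(-1L, 0L, 1L), len, replace = TRUE)
    b <- sample(c(-1L, 0L, 1L), len, replace = TRUE)
    sa <- sample(c(-1L, 1L), 1); sb <- sample(c(-1L, 1L), 1)
    got <- rule_stats(a, b, sa, sb, min_support = 2)
    exp <- rule_oracle(a, b, sa, sb, min_support = 2)
    expect_identical(got$n, as.integer(exp$n))
    expect_identical(got$n_premise, as.integer(exp$n_premise))
    expect_equal(got$precision, exp$precision)
    expect_equal(got$baseline, exp$baseline)
    if (!is.na(exp$z)) expect_equal(got$z, exp$z, tolerance = 1e-12)
    expect_identical(got$significant, exp$significant)
  }
})

test_that("direct networks recover planted edges and handle degenerate anchors", {
  co <- std_cohort(101, n_tumor = 200, n_nat = 10, n_genes = 80,
                   planted_direct = data.frame(target = "TG1", anchor_state = 1L,
                                               target_state = 1L, precision = 0.95))
  tern <- discretize(co$mrna_tumor, calibrate_k(co$mrna_tumor))
  net <- direct_network(tern, "ZNF71", 1L, c("TG1", "BG0001", "BG0002"))
  expect_true("TG1" %in% net$rules$consequent_gene)
  expect_identical(unique(net$rules$premise_gene), "ZNF71")

  expect_identical(nrow(direct_network(tern, "ZNF71", 1L, character(0))$rules), 0L)
  expect_error(direct_network(tern, "NOPE", 1L, "TG1"), "anchor")

  flat <- make_tern(rbind(A = rep(0L, 20), B = rep(c(1L, 0L), 10)))
  expect_warning(net0 <- direct_network(flat, "A", 1L, "B"), "premise state")
  expect_identical(nrow(net0$rules), 0L)
})

test_that("two-hop paths require state consistency across hops", {
  # A(+1) -> M(+1) and M(+1) -> T(-1) planted deterministically
  n <- 40
  set.seed(5)
  A <- rep(c(1L, 0L), each = n / 2)
  M <- A
  T_ <- ifelse(M == 1L, -1L, sample(c(0L, 1L), n, TRUE))
  tern <- make_tern(rbind(A = A, M = M, T1 = T_,
                          N1 = sample(c(-1L, 0L, 1L), n, TRUE)))
  net <- twohop_network(tern, "A", 1L, targets = "T1", intermediates = "M")
  expect_true("T1" %in% names(net$hop_structure))
  path <- net$hop_structure$T1[[1]]
  expect_identical(path$intermediate, "M")
  expect_identical(path$states, c(1L, 1L, -1L))

  # a mismatched intermediate (hop-1 consequent -1, hop-2 premise must be -1;
  # T follows M == +1 instead) yields no path
  M2 <- ifelse(A == 1L, -1L, 0L)
  T2 <- ifelse(M2 == 1L, -1L, 1L)  # depends on the +1 state M2 never visits with A
  tern2 <- make_tern(rbind(A = A, M = M2, T1 = T2))
  net2 <- twohop_network(tern2, "A", 1L, "T1", "M")
  expect_false("T1" %in% names(net2$hop_structure))
})

test_that("two intermediates to the same target keep both paths", {
  n <- 60
  A <- rep(c(1L, 0L, 0L), each = n / 3)
  M1 <- A; M2 <- A
  T_ <- ifelse(A == 1L, 1L, 0L)
  tern <- make_tern(rbind(A = A, M1 = M1, M2 = M2, T1 = T_))
  net <- twohop_network(tern, "A", 1L, "T1", c("M1", "M2"))
  expect_length(net$hop_structure$T1, 2)
})

test_that("cross-layer networks run on shared samples and report coverage gaps", {
  co <- std_cohort(102, n_tumor = 200, n_nat = 10, n_genes = 100,
                   planted_twohop = data.frame(intermediate = "MM1", target = "TH1",
                                               s_anchor = 1L, s_intermediate = 1L,
                                               s_target = -1L, p1 = 0.98, p2 = 0.98))
  tern_m <- discretize(co$mrna_tumor, calibrate_k(co$mrna_tumor))
  tern_p <- discretize(co$protein_tumor, calibrate_k(co$protein_tumor))
  net <- crosslayer_network(tern_m, tern_p, "ZNF71", 1L,
                            targets = c("TH1", "ZNF71_MISSING"),
                            intermediates = "MM1")
  expect_true("TH1" %in% names(net$hop_structure))
  h2 <- net$rules[net$rules$consequent_gene == "TH1", ]
  expect_identical(unique(h2$layer_to), "protein")
  expect_match(net$notes, "ZNF71_MISSING")

  # disjoint sample sets are an input error
  tp2 <- tern_p
  colnames(tp2$states) <- paste0("X", colnames(tp2$states))
  colnames(tp2$missing) <- colnames(tp2$states)
  expect_error(crosslayer_network(tern_m, tp2, "ZNF71", 1L, "TH1", "MM1"),
               "shared samples")
})

test_that("identical inputs give identical networks", {
  co <- std_cohort(103, n_tumor = 120, n_nat = 10, n_genes = 60)
  tern <- discretize(co$mrna_tumor, calibrate_k(co$mrna_tumor))
  n1 <- direct_network(tern, "ZNF71", 1L, rownames(tern$states)[1:30])
  n2 <- direct_network(tern, "ZNF71", 1L, rownames(tern$states)[1:30])
  expect_identical(n1, n2)
})
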