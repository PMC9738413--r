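test_that("the same seed reproduces every cohort output", {
  cfg <- cohort_config(n_tumor = 40, n_nat = 30, n_genes = 50, seed = 9,
                       planted_prognostic = data.frame(gene = "PG1", beta = 0.7))
  c1 <- generate_cohort(cfg); c2 <- generate_cohort(cfg)
  expect_identical(c1$mrna_tumor$values, c2$mrna_tumor$values)
  expect_identical(c1$protein_nat$values, c2$protein_nat$values)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$cell_scores$scores, c2$cell_scores$scores)

  p1 <- generate_cell_panel(cell_panel_config(seed = 9))
  p2 <- generate_cell_panel(cell_panel_config(seed = 9))
  expect_identical(p1$expr$values, p2$expr$values)
  expect_identical(p1$response$measure, p2$response$measure)
})

test_that("planted precision is realized on the latent states", {
  co <- std_cohort(12, n_tumor = 200, n_nat = 10, n_genes = 40,
                   delta = 5, noise_sd = 0.5,
                   planted_direct = data.frame(target = "TG1", anchor_state = 1L,
                                               target_state = 1L, precision = 1.0))
  lat <- co$truth$latent_tumor_states
  anc <- lat["ZNF71", ]
  expect_gte(mean(lat["TG1", anc == 1L] == 1L), 0.95)
  # anchor tail fraction ~ 30%
  expect_lt(abs(mean(anc != 0L) - 0.30), 0.1)
})

test_that("unlearnable planted precision is rejected at config time", {
  expect_error(cohort_config(
    planted_direct = data.frame(target = "TG1", anchor_state = 1L,
                                target_state = 1L, precision = 0.15)),
    "unlearnable")
})

test_that("housekeeping genes are state-independent of the anchor", {
  co <- std_cohort(13, n_tumor = 150, n_nat = 10, n_genes = 60)
  hk <- co$truth$housekeeping
  expect_true(all(co$truth$latent_tumor_states[hk, ] == 0L))
})

test_that("dependency normalization pins control-set medians exactly", {
  pa <- generate_cell_panel(cell_panel_config(n_cell_lines = 20, seed = 3))
  for (dep in list(pa$dep_crispr, pa$dep_rnai)) {
    ess <- apply(dep$scores[pa$truth$essential, ], 2, median)
    nes <- apply(dep$scores[pa$truth$nonessential, ], 2, median)
    expect_equal(unname(ess), rep(-1, 20), tolerance = 1e-12)
    expect_equal(unname(nes), rep(0, 20), tolerance = 1e-12)
  }
  expect_error(cell_panel_config(essential_genes = character(0)), "non-empty")
  expect_error(cell_panel_config(planted_sensitive = list(d = "G1"),
                                 planted_resistant = list(d = "G1"),
                                 drug_ids = "d"), "overlap")
})

test_that("planted drug-response genes are recovered and nulls stay near alpha", {
  pc <- cell_panel_config(n_cell_lines = 60, drug_ids = "d1",
                          planted_sensitive = list(d1 = "GS1"),
                          planted_resistant = list(d1 = "GR1"),
                          other_genes = c("GS1", "GR1"),
                          effect_size = 2, seed = 21)
  pa <- generate_cell_panel(pc)
  labels <- list(d1 = categorize_cell_lines(pa$response, "d1"))
  calls <- call_drug_genes(pa$expr, labels, c("GS1", "GR1"))
  expect_identical(calls$calls["GS1", "d1"], "sensitive")
  expect_identical(calls$calls["GR1", "d1"], "resistant")

  # zero effect size: positive-call rate across null genes stays near the
  # nominal 5% level
  rates <- vapply(1:30, function(s) {
    pa0 <- generate_cell_panel(cell_panel_config(
      n_cell_lines = 60, drug_ids = "d1", effect_size = 0, seed = s,
      other_genes = sprintf("NULL%02d", 1:30)))
    lab <- list(d1 = categorize_cell_lines(pa0$response, "d1"))
    cl <- call_drug_genes(pa0$expr, lab, sprintf("NULL%02d", 1:30))
    mean(cl$calls != "neither")
  }, numeric(1))
  expect_lt(mean(rates), 0.08)
  expect_gt(mean(rates), 0.02)
})

test_that("univariate Cox recovers the sign of planted hazard coefficients", {
  hits <- vapply(1:5, function(s) {
    co <- std_cohort(s, n_tumor = 200, n_nat = 10, n_genes = 40,
                     planted_prognostic = data.frame(gene = c("PG1", "PG2"),
                                                     beta = c(0.7, -0.7)))
    x1 <- co$mrna_tumor$values["PG1", ]
    x2 <- co$mrna_tumor$values["PG2", ]
    y <- survival::Surv(co$survival$time_months, co$survival$event)
    all(coef(survival::coxph(y ~ x1)) > 0, coef(survival::coxph(y ~ x2)) < 0)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
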