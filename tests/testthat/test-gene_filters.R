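test_that("differential expression flags direction and handles degenerate genes", {
  set.seed(41)
  a <- make_expr(rbind(G1 = rnorm(20, 1, 0.1), G2 = rnorm(20, 0, 1),
                       G3 = rep(2, 20)),
                 compartment = "tumor")
  b <- make_expr(rbind(G1 = rnorm(20, 0, 0.1), G2 = rnorm(20, 0, 1),
                       G3 = rep(2, 20), G4 = rnorm(20)),
                 compartment = "nat")
  de <- differential_expression(a, b)
  expect_true(de$pass[de$gene == "G1"])
  expect_identical(de$direction[de$gene == "G1"], "higher_in_a")
  expect_identical(de$p[de$gene == "G3"], 1)    # zero variance, equal means
  expect_false(de$pass[de$gene == "G3"])
  expect_identical(attr(de, "excluded"), "G4")  # absent on one side

  # identical groups: p = 1
  de2 <- differential_expression(a, a)
  expect_true(all(de2$p[is.finite(de2$p)] >= 0.999))

  # group swap flips t but keeps p
  de3 <- differential_expression(b, a)
  expect_equal(de3$t[de3$gene == "G1"], -de$t[de$gene == "G1"])
  expect_equal(de3$p[de3$gene == "G1"], de$p[de$gene == "G1"])
})

test_that("proliferation screen uses strict threshold and OR/AND assay logic", {
  mk <- function(v, assay) dependency_matrix(
    matrix(v, 1, 10, dimnames = list("G1", sprintf("CL%02d", 1:10))), assay)
  # exactly -0.5 everywhere: strict inequality fails
  scr <- proliferation_screen(mk(rep(-0.5, 10), "crispr"),
                              mk(rep(-0.5, 10), "rnai"), "G1")
  expect_false(scr$pass)
  # below threshold in 6/10 CRISPR lines, 0/10 RNAi: OR passes, AND fails
  crispr <- mk(c(rep(-0.8, 6), rep(0, 4)), "crispr")
  rnai <- mk(rep(0, 10), "rnai")
  expect_true(proliferation_screen(crispr, rnai, "G1")$pass)
  expect_false(proliferation_screen(crispr, rnai, "G1", mode = "and")$pass)
  # absent gene excluded with note
  scr2 <- proliferation_screen(crispr, rnai, c("G1", "GX"))
  expect_identical(attr(scr2, "excluded"), "GX")
})

test_that("relaxing the dependency threshold never removes genes", {
  set.seed(42)
  dep <- dependency_matrix(
    matrix(rnorm(50 * 12, -0.5, 0.4), 50, 12,
           dimnames = list(sprintf("G%02d", 1:50), sprintf("CL%02d", 1:12))),
    "crispr")
  passed <- lapply(c(-0.8, -0.6, -0.4, -0.2), function(th) {
    scr <- proliferation_screen(dep, NULL, rownames(dep$scores), threshold = th)
    scr$gene[scr$pass]
  })
  for (i in 1:3) expect_true(all(passed[[i]] %in% passed[[i + 1]]))
})

test_that("synthetic essential genes pass the screen, non-essential fail", {
  pa <- generate_cell_panel(cell_panel_config(n_cell_lines = 30, seed = 5))
  scr <- proliferation_screen(pa$dep_crispr, pa$dep_rnai,
                              c(pa$truth$essential, pa$truth$nonessential))
  expect_true(all(scr$pass[scr$gene %in% pa$truth$essential]))
  expect_false(any(scr$pass[scr$gene %in% pa$truth$nonessential]))
})

test_that("prognostic screen takes the conjunction over cohorts", {
  co1 <- std_cohort(61, n_tumor = 150, n_nat = 10, n_genes = 40,
                    planted_prognostic = data.frame(gene = "PG1", beta = 1))
  co2 <- std_cohort(62, n_tumor = 150, n_nat = 10, n_genes = 40,
                    planted_prognostic = data.frame(gene = "PG1", beta = 1))
  one <- list(expr = co1$mrna_tumor, survival = co1$survival)
  two <- list(expr = co2$mrna_tumor, survival = co2$survival)
  scr <- prognostic_screen(list(one, two), c("PG1", "BG0001"))
  expect_true(scr$pass[scr$gene == "PG1"])
  # single-cohort input reduces to that cohort's test
  scr1 <- prognostic_screen(list(one), "PG1")
  expect_true(scr1$pass)
  # a cohort with too few events is skipped with a warning
  co3 <- co2
  no_events <- survival_table(co1$survival$sample_id, co1$survival$time_months,
                              rep(0L, nrow(co1$survival)))
  expect_warning(
    prognostic_screen(list(one, list(expr = co1$mrna_tumor,
                                     survival = no_events)), "PG1"),
    "skipped")
})

test_that("the intermediate filter is the strict conjunction of three flags", {
  # brute force over all 8 flag combinations
  combos <- expand.grid(de = c(TRUE, FALSE), dep = c(TRUE, FALSE),
                        prog = c(TRUE, FALSE))
  genes <- sprintf("G%d", seq_len(nrow(combos)))
  de <- data.frame(gene = genes, pass = combos$de)
  dep <- data.frame(gene = genes, pass = combos$dep)
  prog <- data.frame(gene = genes, pass = combos$prog)
  rep_ <- intermediate_gene_filter(genes, de, dep, prog)
  expect_identical(rep_$all_pass, combos$de & combos$dep & combos$prog)
  expect_identical(sum(rep_$all_pass), 1L)
  # empty candidate set
  expect_identical(nrow(intermediate_gene_filter(character(0), de, dep, prog)), 0L)
})
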