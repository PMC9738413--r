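mk_response <- function(v, lines = sprintf("CL%02d", seq_along(v)), drug = "d1") {
  drug_response_table(matrix(v, 1, length(v), dimnames = list(drug, lines)), "ic50")
}

test_that("tertile categorization splits ordered measures deterministically", {
  resp <- mk_response(1:9)
  lab <- suppressWarnings(categorize_cell_lines(resp, "d1"))
  expect_identical(unname(lab[sprintf("CL%02d", 1:3)]), rep("sensitive", 3))
  expect_identical(unname(lab[sprintf("CL%02d", 7:9)]), rep("resistant", 3))
  expect_identical(unname(lab[sprintf("CL%02d", 4:6)]), rep("intermediate", 3))

  # ties straddling a boundary resolve by cell-line id order
  resp2 <- mk_response(c(1, 1, 1, 1, 2, 2, 3, 3, 3))
  lab2a <- suppressWarnings(categorize_cell_lines(resp2, "d1"))
  lab2b <- suppressWarnings(categorize_cell_lines(resp2, "d1"))
  expect_identical(lab2a, lab2b)
  expect_identical(unname(lab2a[c("CL01", "CL02", "CL03")]), rep("sensitive", 3))

  # partition is exhaustive with near-equal tertiles for any n
  for (n in c(10, 11, 12, 17)) {
    labn <- suppressWarnings(categorize_cell_lines(mk_response(seq_len(n)), "d1"))
    counts <- table(factor(labn, c("sensitive", "intermediate", "resistant")))
    expect_identical(sum(counts), as.integer(n))
    expect_lte(max(counts) - min(counts), 1)
  }

  # median mode has no intermediate class
  labm <- suppressWarnings(categorize_cell_lines(mk_response(1:8), "d1",
                                                 mode = "median"))
  expect_identical(sort(unique(labm)), c("resistant", "sensitive"))
  expect_error(categorize_cell_lines(mk_response(rep(NA_real_, 10)), "d1"),
               "missing")
})

test_that("gene calls follow the direction of significant expression shifts", {
  set.seed(91)
  lines <- sprintf("CL%02d", 1:30)
  lab <- setNames(rep(c("sensitive", "intermediate", "resistant"), each = 10),
                  lines)
  expr <- rbind(UP_S = c(rnorm(10, 3), rnorm(10), rnorm(10, 0)),
                UP_R = c(rnorm(10, 0), rnorm(10), rnorm(10, 3)),
                FLAT = rnorm(30))
  colnames(expr) <- lines
  calls <- call_drug_genes(make_expr(expr, compartment = "cell_line"),
                           list(d1 = lab), c("UP_S", "UP_R", "FLAT"))
  expect_identical(unname(calls$calls[, "d1"]),
                   c("sensitive", "resistant", "neither"))

  # too few lines per class: everything neither, with a warning
  small <- setNames(c(rep("sensitive", 2), rep("resistant", 2)), lines[1:4])
  expect_warning(c2 <- call_drug_genes(make_expr(expr, compartment = "cell_line"),
                                       list(d1 = small), "UP_S"),
                 "fewer than 3")
  expect_identical(unname(c2$calls[, "d1"]), "neither")
})

test_that("pan classification matches brute force on every per-gene call vector", {
  states <- c("sensitive", "resistant", "neither")
  vecs <- expand.grid(d1 = states, d2 = states, d3 = states,
                      stringsAsFactors = FALSE)
  m <- as.matrix(vecs)
  rownames(m) <- sprintf("G%02d", seq_len(nrow(m)))
  got <- pan_classification(m)
  for (g in rownames(m)) {
    expected <- pan_oracle_gene(m[g, ])
    expect_identical(g %in% got$pan_sensitive, expected == "pan_sensitive")
    expect_identical(g %in% got$pan_resistant, expected == "pan_resistant")
  }
  expect_length(intersect(got$pan_sensitive, got$pan_resistant), 0)

  # random larger matrices keep the sets disjoint and oracle-consistent
  set.seed(92)
  for (i in 1:50) {
    mm <- matrix(sample(states, 12, TRUE), 4, 3,
                 dimnames = list(paste0("G", 1:4), paste0("d", 1:3)))
    pc <- pan_classification(mm)
    expect_length(intersect(pc$pan_sensitive, pc$pan_resistant), 0)
    for (g in rownames(mm)) {
      expected <- pan_oracle_gene(mm[g, ])
      expect_identical(g %in% pc$pan_sensitive, expected == "pan_sensitive")
      expect_identical(g %in% pc$pan_resistant, expected == "pan_resistant")
    }
  }
})

test_that("pan classification excludes genes with unknown calls and toy cases work", {
  m <- rbind(G1 = c("sensitive", "neither", "neither"),
             G2 = c("sensitive", "resistant", "neither"),
             G3 = c("neither", "neither", "resistant"),
             G4 = c("neither", "neither", "neither"),
             G5 = c("sensitive", NA, "neither"))
  colnames(m) <- paste0("d", 1:3)
  pc <- pan_classification(m)
  expect_identical(pc$pan_sensitive, "G1")
  expect_identical(pc$pan_resistant, "G3")
  expect_identical(pc$excluded, "G5")
  expect_error(pan_classification(m[, 1:2], drugs = paste0("d", 1:3)),
               "missing for drug")
})

test_that("checkpoint correlations drop outliers and flag negative associations", {
  # perfect anticorrelation
  resp <- mk_response(seq(0.5, 5, length.out = 10))
  e <- setNames(-seq(0.5, 5, length.out = 10), sprintf("CL%02d", 1:10))
  r <- ici_correlation(resp, "d1", e)
  expect_equal(r$r, -1, tolerance = 1e-12)
  expect_true(r$flagged)

  # one value above the cutoff is excluded
  resp2 <- mk_response(c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 11))
  e2 <- setNames(rnorm(7), sprintf("CL%02d", 1:7))
  r2 <- ici_correlation(resp2, "d1", e2)
  expect_identical(r2$n_outliers, 1L)
  expect_identical(r2$n_used, 6L)

  # too few pairs: insufficient, never flagged
  r3 <- ici_correlation(mk_response(c(1, 2, 3, 12, 13)), "d1",
                        setNames(c(-1, -2, -3, -4, -5), sprintf("CL%02d", 1:5)))
  expect_false(r3$sufficient)
  expect_false(r3$flagged)
})

test_that("potency summaries average retained measures only", {
  resp <- mk_response(c(0.5, 1.5, 12))
  ps <- suppressWarnings(potency_summary(resp))
  expect_equal(ps$mean, 1.0)
  expect_identical(ps$n, 2L)
  expect_identical(ps$n_outliers, 1L)
  # no outliers: plain average
  ps2 <- suppressWarnings(potency_summary(mk_response(c(1, 2, 3))))
  expect_equal(ps2$mean, 2)
})

test_that("packaged pan-gene tables parse with normalized symbols", {
  tab <- read_pan_gene_table("rnaseq")
  expect_identical(nrow(tab), 21L)
  vem <- tab$pan_resistant[[which(tab$drug == "vemurafenib")]]
  expect_true("RNASEL" %in% vem)   # printed as "RNASE L" in the source table
  prot <- read_pan_gene_table("protein")
  expect_identical(nrow(prot), 21L)
  carb <- prot$pan_resistant[[which(prot$drug == "carboplatin")]]
  expect_identical(carb, "TJP1")   # isoform accession suffix stripped
})
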