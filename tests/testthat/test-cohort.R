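test_that("null design yields expected group folds of exactly 1", {
  ann <- generate_annotation(50, marker_config = c(CD4T = 3L), seed = 1)
  sig <- generate_signatures(ann, seed = 1)
  design <- cohort_design(seed = 1)
  ef <- expected_folds(ann, sig, design)
  expect_equal(ef$fold_RAA_C, rep(1, 50))
  expect_equal(ef$fold_RAC_C, rep(1, 50))
  expect_equal(ef$fold_RAA_RAC, rep(1, 50))
})

test_that("expected folds match an independent mixture-formula oracle", {
  set.seed(42)
  ann <- generate_annotation(120, marker_config = c(CD4T = 6L,
                                                    MONO_CLASSICAL = 6L),
                             seed = 9)
  sig <- generate_signatures(ann, seed = 9)
  design <- default_paper_scenario(9, ann)
  ef <- expected_folds(ann, sig, design)
  mu <- mixture_oracle(ann, sig, design)
  expect_equal(ef$fold_RAA_C, unname(mu[, "RAA"] / mu[, "C"]),
               tolerance = 1e-12)
  expect_equal(ef$fold_RAC_C, unname(mu[, "RAC"] / mu[, "C"]),
               tolerance = 1e-12)
})

test_that("a pure CD4 marker's fold is the count multiplier over the renormalization", {
  ann <- tiny_annotation(40)
  ann$marker_of[1] <- "CD4T"
  sig <- generate_signatures(ann, seed = 4)
  sig[1, ] <- 0
  sig[1, "CD4T"] <- 100   # strictly CD4-specific transcript
  cm <- matrix(1, 3, 8, dimnames = list(c("RAA", "RAC", "C"),
                                        blood_cell_types()))
  cm["RAA", "CD4T"] <- 1 / 1.5
  design <- cohort_design(cellcount_multiplier = cm, seed = 4)

  base <- design$base_proportions
  p_raa <- base * cm["RAA", ]; p_raa <- p_raa / sum(p_raa)
  # proportion fold of the CD4 compartment...
  prop_fold <- p_raa[["CD4T"]] / base[["CD4T"]]
  # ...further shrunk by the total-RNA renormalization of the bulk library
  B <- unclass(sig)[, design$cell_types]
  renorm <- sum(B %*% p_raa) / sum(B %*% base)
  ef <- expected_folds(ann, sig, design)
  expect_equal(ef$fold_RAA_C[1], prop_fold / renorm, tolerance = 1e-12)
  expect_lt(ef$fold_RAA_C[1], 1)
})

test_that("the monocyte scenario plants a raw marker fold near 3.25 inside 1.8-4.6", {
  ann <- tiny_annotation(60)
  ann$marker_of[1] <- "MONO_CLASSICAL"
  sig <- generate_signatures(ann, seed = 6)
  sig[1, ] <- 0
  sig[1, "MONO_CLASSICAL"] <- 50
  cm <- matrix(1, 3, 8, dimnames = list(c("RAA", "RAC", "C"),
                                        blood_cell_types()))
  cm["RAA", "MONO_CLASSICAL"] <- 1.3
  reg <- data.frame(group = "RAA", cell_type = "MONO_CLASSICAL",
                    transcript_id = ann$transcript_id[1], multiplier = 2.5)
  design <- cohort_design(cellcount_multiplier = cm, regulation = reg,
                          seed = 6)
  base <- design$base_proportions
  p_raa <- base * cm["RAA", ]; p_raa <- p_raa / sum(p_raa)
  raw_fold <- 2.5 * p_raa[["MONO_CLASSICAL"]] / base[["MONO_CLASSICAL"]]
  expect_equal(raw_fold, 3.25, tolerance = 0.03)
  expect_gt(raw_fold, 1.8)
  expect_lt(raw_fold, 4.6)
})

test_that("the cohort realizes counts, splits and cell tables consistently", {
  ann <- generate_annotation(150, marker_config = c(CD4T = 4L), seed = 12)
  sig <- generate_signatures(ann, seed = 12)
  design <- cohort_design(group_sizes = c(RAA = 5L, RAC = 6L, C = 5L),
                          months_since_event = seq(3, 15, length.out = 6),
                          library_size = 5e4, seed = 12)
  co <- generate_cohort(ann, sig, design)

  expect_s3_class(co$exonic, "expr_matrix")
  expect_identical(dim(co$exonic), c(150L, 16L))
  expect_true(all(co$exonic$values >= 0))
  expect_true(all(co$intronic$values >= 0))
  expect_identical(co$exonic$samples, co$intronic$samples)
  expect_identical(table(co$exonic$samples$group),
                   table(factor(rep(c("RAA", "RAC", "C"), c(5, 6, 5)))))
  expect_equal(sum(!is.na(co$exonic$samples$months_since_event)), 6)

  # parent-child consistency of the cell-count table
  cc <- co$cellcounts
  expect_true(all(cc$cd3 <= cc$lymphocytes))
  expect_equal(cc$cd4 + cc$cd8, cc$cd3)
  expect_equal(cc$mono_classical + cc$mono_intermediate +
                 cc$mono_nonclassical, cc$monocytes)
  expect_true(all(unlist(cc[, -(1:2)]) >= 0))

  # determinism
  co2 <- generate_cohort(ann, sig, design)
  expect_identical(co$exonic$values, co2$exonic$values)
  expect_identical(co$cellcounts, co2$cellcounts)
})

test_that("a zero pre-mRNA fraction gives no intronic reads; planted fractions are recovered", {
  ann <- generate_annotation(80, seed = 2)
  sig <- generate_signatures(ann, seed = 2)
  d0 <- cohort_design(premrna_baseline = 0, library_size = 1e5, seed = 2)
  co0 <- generate_cohort(ann, sig, d0)
  expect_true(all(co0$intronic$values == 0))

  ov <- data.frame(group = "RAA", transcript_id = ann$transcript_id[1:10],
                   fraction = 0.4)
  d <- cohort_design(premrna_baseline = 0.1, premrna_override = ov,
                     library_size = 2e5, seed = 2)
  co <- generate_cohort(ann, sig, d)
  raa <- co$exonic$samples$group == "RAA"
  tot <- co$exonic$values + co$intronic$values
  frac_hi <- sum(co$intronic$values[1:10, raa]) / sum(tot[1:10, raa])
  frac_lo <- sum(co$intronic$values[-(1:10), raa]) / sum(tot[-(1:10), raa])
  expect_equal(frac_hi, 0.4, tolerance = 0.02)
  expect_equal(frac_lo, 0.1, tolerance = 0.02)
})

test_that("empirical group means converge to the closed-form expectation", {
  ann <- generate_annotation(300, marker_config = c(CD4T = 8L,
                                                    MONO_CLASSICAL = 8L),
                             seed = 21)
  sig <- generate_signatures(ann, seed = 21)
  rel_err <- function(library_size, dispersion) {
    d <- cohort_design(group_sizes = c(RAA = 20L, RAC = 20L, C = 20L),
                       library_size = library_size, dispersion = dispersion,
                       seed = 21)
    co <- generate_cohort(ann, sig, d)
    mu <- mixture_oracle(ann, sig, d)
    g <- co$exonic$samples$group
    tot <- co$exonic$values + co$intronic$values
    err <- sapply(c("RAA", "RAC", "C"), function(gg) {
      abs(rowMeans(tot[, g == gg]) - mu[, gg]) / mu[, gg]
    })
    median(err)
  }
  # at low dispersion the sampling error is dominated by counting noise and
  # shrinks with depth; at 1e6 fragments, 20 samples/group it is well < 5%
  expect_lt(rel_err(1e6, 0.01), 0.05)
  expect_lt(rel_err(1e6, 0.01), rel_err(1e4, 0.01))
})

test_that("design validation enforces the control-reference invariants", {
  cm <- matrix(1, 3, 8, dimnames = list(c("RAA", "RAC", "C"),
                                        blood_cell_types()))
  cm["C", "CD4T"] <- 2
  expect_error(cohort_design(cellcount_multiplier = cm), "identically 1")
  expect_error(cohort_design(premrna_baseline = 1), "premrna")
  expect_error(
    cohort_design(regulation = data.frame(group = "RAA", cell_type = "CD4T",
                                          transcript_id = "t1",
                                          multiplier = -1)),
    "multiplier")
  d <- default_paper_scenario(1)
  expect_s3_class(d, "cohort_design")
  expect_true(all(d$cellcount_multiplier["RAC", ] == 1))
  expect_true(all(d$regulation$group != "RAC"))
  expect_identical(default_paper_scenario(5)$regulation,
                   default_paper_scenario(5)$regulation)
})
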