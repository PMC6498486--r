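test_that("count folds summarize per-group counts as stated", {
  cc <- data.frame(sample_id = sprintf("S%d", 1:4),
                   group = c("RAA", "RAA", "C", "C"),
                   monocytes = c(1.3, 1.3, 1.0, 1.0),
                   cd4 = c(5, 5, 5, 5))
  expect_equal(count_fold(cc, "monocytes", "RAA", "C"), 1.3)
  expect_equal(count_fold(cc, "cd4", "RAA", "C"), 1.0)
  expect_equal(count_fold(cc, "monocytes", "RAA", "C", summary = mean), 1.3)
  expect_error(count_fold(cc, "neutrophils", "RAA", "C"), "population")
  cc0 <- transform(cc, monocytes = c(1, 1, 0, 0))
  expect_error(count_fold(cc0, "monocytes", "RAA", "C"), "zero summary")
})

test_that("marker folds aggregate by geometric mean with an envelope", {
  m <- rbind(m1 = c(4, 4, 2, 2), m2 = c(16, 16, 2, 2), flat = c(3, 3, 3, 3))
  g <- c("RAA", "RAA", "C", "C")
  x <- make_expr(m, g, unit = "FPKM")
  mf <- marker_fold(x, c("m1", "m2"), "RAA", "C", pseudocount = 0)
  expect_equal(unname(mf$folds), c(2, 8))
  expect_equal(mf$geomean, 4.0)
  expect_equal(mf$range, c(2, 8))
  mf_flat <- marker_fold(x, "flat", "RAA", "C", pseudocount = 0)
  expect_equal(mf_flat$geomean, 1)
  expect_error(marker_fold(x, character(), "RAA", "C"), "empty")
  expect_error(marker_fold(x, "nope", "RAA", "C"), "absent")
})

test_that("the attribution rule reproduces its closed-form cases", {
  # lymphopenia case: 1.5-fold count drop, twofold expression drop
  v1 <- attribute(1 / 1.5, 1 / 2)
  expect_equal(v1$discordance, abs(log2(0.5) - log2(1 / 1.5)),
               tolerance = 1e-12)
  expect_equal(round(v1$discordance, 3), 0.415)
  expect_identical(v1$verdict, "composition_driven")

  # monocyte case: 1.3-fold count rise, ~2.9-fold marker rise
  v2 <- attribute(1.3, 2.9)
  expect_equal(v2$discordance, abs(log2(2.9) - log2(1.3)), tolerance = 1e-12)
  expect_gt(v2$discordance, 0.5)
  expect_identical(v2$verdict, "actively_regulated")

  # exact agreement
  v3 <- attribute(1.7, 1.7)
  expect_equal(v3$discordance, 0)
  expect_identical(v3$verdict, "composition_driven")

  # conflicting directions beyond tau
  v4 <- attribute(2, 1 / 2)
  expect_identical(v4$verdict, "indeterminate")
  expect_error(attribute(-1, 2), "count_fold")
})

test_that("discordance is symmetric under swapping the contrast", {
  set.seed(51)
  for (i in 1:20) {
    cf <- rlnorm(1); ef <- rlnorm(1)
    a <- attribute(cf, ef)
    b <- attribute(1 / cf, 1 / ef)
    expect_equal(a$discordance, b$discordance, tolerance = 1e-12)
    expect_identical(a$verdict, b$verdict)
  }
})

test_that("scenario cohorts attribute CD4 to composition and MN to regulation", {
  s <- simulate_scenario(53)
  fpkm <- compute_fpkm(s$cohort$exonic, s$annotation)
  tab <- attribution_table(
    fpkm, s$cohort$cellcounts,
    list(CD4 = list(count_column = "cd4", markers = s$marker_sets$CD4),
         MONOCYTES = list(count_column = "monocytes",
                          markers = s$marker_sets$MN)))
  expect_identical(tab$verdict[tab$population == "CD4"],
                   "composition_driven")
  expect_identical(tab$verdict[tab$population == "MONOCYTES"],
                   "actively_regulated")
  # planted CD14 markers land inside the expected acute envelope
  mf <- marker_fold(fpkm, s$marker_sets$CD14, "RAA", "C")
  expect_gt(mf$geomean, count_fold(s$cohort$cellcounts, "monocytes",
                                   "RAA", "C"))
})

test_that("a null cohort is composition driven with near-zero discordance", {
  ann <- generate_annotation(400, marker_config = default_marker_config(),
                             seed = 55)
  sig <- generate_signatures(ann, seed = 56)
  co <- generate_cohort(ann, sig, cohort_design(seed = 55))
  fpkm <- compute_fpkm(co$exonic, ann)
  cf <- count_fold(co$cellcounts, "cd4", "RAA", "C")
  mf <- marker_fold(fpkm, marker_transcripts(ann, "CD4T"), "RAA", "C")
  v <- attribute(cf, mf)
  expect_identical(v$verdict, "composition_driven")
  expect_lt(v$discordance, 0.3)
})
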