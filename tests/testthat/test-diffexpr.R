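test_that("constant transcripts get F = 0, p = 1; identical group values too", {
  m <- rbind(rep(2, 9), c(rep(1, 3), rep(2, 3), rep(3, 3)))
  rownames(m) <- c("const", "sep")
  g <- rep(c("RAA", "RAC", "C"), each = 3)
  x <- expr_matrix(m, make_samples(g), "log2FPKMp1")
  res <- anova_screen(x)
  expect_equal(res$F[res$transcript_id == "const"], 0)
  expect_equal(res$p[res$transcript_id == "const"], 1)
  # within-group constant but between-group separated: perfect evidence
  expect_equal(res$p[res$transcript_id == "sep"], 0)
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(5)
  m <- matrix(rnorm(40), 4, 10)
  rownames(m) <- paste0("t", 1:4)
  g <- rep(c("RAA", "C"), each = 5)
  res <- anova_screen(m, groups = g)
  for (i in 1:4) {
    tt <- t.test(m[i, g == "RAA"], m[i, g == "C"], var.equal = TRUE)
    expect_equal(res$F[i], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("vectorized ANOVA matches anova(lm()) across random transcripts", {
  set.seed(8)
  g <- rep(c("RAA", "RAC", "C"), c(6, 7, 5))
  m <- matrix(rnorm(30 * 18, sd = 2), 30, 18)
  rownames(m) <- paste0("t", 1:30)
  res <- anova_screen(m, groups = g)
  for (i in sample(30, 10)) {
    fit <- anova(lm(m[i, ] ~ factor(g)))
    expect_equal(res$F[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("ANOVA screen rejects undersized groups", {
  m <- matrix(rnorm(8), 2, 4)
  rownames(m) <- c("a", "b")
  expect_error(anova_screen(m, groups = c("RAA", "RAA", "RAC", "C")),
               ">= 2 samples")
  expect_error(anova_screen(m, groups = rep("C", 4)), "2 groups")
})

test_that("BH adjustment matches the closed form and the brute-force definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-14)
  }
  # monotone nondecreasing in p-rank
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("fold changes follow the pseudocount formula and an oracle", {
  m <- rbind(c(4, 4, 2, 2), c(3, 3, 3, 3))
  rownames(m) <- c("a", "b")
  g <- c("RAA", "RAA", "C", "C")
  f0 <- fold_changes(m, groups = g, pseudocount = 0)
  expect_equal(f0$fold_RAA_C, c(2, 1))
  set.seed(14)
  m2 <- matrix(rexp(60), 10, 6)
  rownames(m2) <- paste0("t", 1:10)
  g2 <- rep(c("RAA", "RAC", "C"), each = 2)
  f <- fold_changes(m2, groups = g2, pseudocount = 0.1)
  for (i in 1:10) {
    expect_equal(f$fold_RAA_C[i],
                 (mean(m2[i, 1:2]) + 0.1) / (mean(m2[i, 5:6]) + 0.1),
                 tolerance = 1e-12)
    expect_equal(f$fold_RAA_RAC[i],
                 (mean(m2[i, 1:2]) + 0.1) / (mean(m2[i, 3:4]) + 0.1),
                 tolerance = 1e-12)
  }
})

test_that("planted anti-correlated blocks are recovered perfectly without noise", {
  skip_if_not_installed("mclust")
  set.seed(17)
  g <- rep(c("RAA", "RAC", "C"), c(6, 6, 6))
  base <- c(rnorm(6, 2), rnorm(6, 0), rnorm(6, 0))
  m <- rbind(matrix(rep(-base, 10), 10, byrow = TRUE),
             matrix(rep(base, 10), 10, byrow = TRUE))
  rownames(m) <- paste0("t", 1:20)
  truth <- rep(c("A", "B"), each = 10)  # block 1 is down in RAA
  pa <- assign_patterns(m, groups = g)
  expect_false(pa$degenerate)
  expect_equal(mclust::adjustedRandIndex(pa$pattern[rownames(m)], truth), 1.0)
  expect_identical(unname(pa$pattern[1]), "A")
  expect_identical(unname(pa$pattern[20]), "B")
})

test_that("pattern assignment is invariant to sample order and affine rescaling", {
  set.seed(19)
  g <- rep(c("RAA", "RAC", "C"), each = 5)
  v <- c(rnorm(5, 1.5), rnorm(5, 0), rnorm(5, 0))
  m <- rbind(matrix(rep(v, 8), 8, byrow = TRUE) + rnorm(120, sd = 0.3),
             matrix(rep(-v, 8), 8, byrow = TRUE) + rnorm(120, sd = 0.3))
  rownames(m) <- paste0("t", 1:16)
  pa <- assign_patterns(m, groups = g)
  perm <- sample(ncol(m))
  pa_perm <- assign_patterns(m[, perm], groups = g[perm])
  expect_identical(pa$pattern[rownames(m)], pa_perm$pattern[rownames(m)])
  scaled <- m * 3.7 + 11
  pa_scaled <- assign_patterns(scaled, groups = g)
  expect_identical(pa$pattern[rownames(m)], pa_scaled$pattern[rownames(m)])
})

test_that("identical profiles give a degenerate single-cluster cut", {
  g <- rep(c("RAA", "C"), each = 4)
  prof <- c(1, 2, 1, 2, 3, 4, 3, 4)
  m <- matrix(rep(prof, 6), 6, byrow = TRUE)
  rownames(m) <- paste0("t", 1:6)
  m <- rbind(m, flat = rep(5, 8))
  expect_warning(pa <- assign_patterns(m, groups = g), "zero-variance")
  expect_true(pa$degenerate)
  expect_equal(length(unique(pa$pattern)), 1L)
  expect_identical(pa$excluded, "flat")
})

test_that("time-course screen flags monotone decay and skips constants", {
  months <- seq(3, 15, length.out = 13)
  m <- rbind(rev(seq_len(13)), rep(5, 13))
  rownames(m) <- c("decay", "flat")
  tc <- timecourse_screen(m, months_since_event = months)
  expect_equal(nrow(tc), 1L)        # constant transcript excluded, no error
  expect_equal(tc$R[1], -1)
  expect_true(tc$hit[1])
  expect_identical(tc$direction[1], "down")
  expect_error(timecourse_screen(m[, 1:4], months_since_event = months[1:4]),
               ">= 5")
})

test_that("Spearman screen matches a rank-correlation oracle", {
  set.seed(23)
  months <- sort(runif(13, 3, 15))
  m <- matrix(rexp(13 * 8), 8, 13)
  rownames(m) <- paste0("t", 1:8)
  tc <- timecourse_screen(m, months_since_event = months)
  for (i in 1:8) {
    o <- spearman_oracle(m[i, ], months)
    expect_equal(tc$R[i], o$rho, tolerance = 1e-10)
    expect_equal(tc$p[i], o$p, tolerance = 1e-6)
  }
})

test_that("null ANOVA p-values are uniform across seeds (KS check)", {
  g <- rep(c("RAA", "RAC", "C"), c(19, 20, 20))
  pass <- logical(50)
  for (s in 1:50) {
    set.seed(s)
    m <- matrix(rnorm(200 * 59), 200, 59)
    rownames(m) <- paste0("t", 1:200)
    p <- anova_screen(m, groups = g)$p
    pass[s] <- suppressWarnings(ks.test(p, "punif")$p.value) > 0.01
  }
  expect_gte(sum(pass), 47)
})
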