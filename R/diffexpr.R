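#' Per-transcript one-way ANOVA screen
#'
#' Classical fixed-effects one-way ANOVA of each transcript's
#' `log2(1 + FPKM)` values on the clinical-status factor, computed by
#' vectorized sums of squares across all transcripts, with
#' Benjamini-Hochberg adjustment over the whole screen. A transcript with
#' zero within- and between-group variance (constant across all samples) is
#' assigned `F = 0, p = 1`.
#'
#' @param logmatrix An `expr_matrix` with unit `log2FPKMp1`, or a plain
#'   numeric matrix (then `groups` is required).
#' @param groups Optional group labels per column.
#' @param q_threshold FDR gate for the `significant` flag (default `1e-5`,
#'   i.e. FDR < 0.001%).
#' @return `data.frame(transcript_id, F, p, q, significant)` with the group
#'   labels kept as an attribute.
#' @export
anova_screen <- function(logmatrix, groups = NULL, q_threshold = 1e-5) {
  if (inherits(logmatrix, "expr_matrix")) {
    stop_unless_unit(logmatrix, "log2FPKMp1")
  }
  x <- expr_values(logmatrix)
  g <- factor(expr_groups(logmatrix, groups))
  stopifnot(ncol(x) == length(g))
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("each group needs >= 2 samples; offending group: ",
         names(sizes)[which(sizes < 2)[1]])
  }
  n <- ncol(x)
  k <- nlevels(g)
  # group means via indicator algebra; SSB/SSW per row
  G <- stats::model.matrix(~ g - 1)
  gm <- x %*% G %*% diag(1 / as.numeric(sizes), k)   # row x group means
  grand <- rowMeans(x)
  ssb <- rowSums(sweep(gm, 2, as.numeric(sizes), function(m, w) w * m^2)) -
    n * grand^2
  sst <- rowSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(F, k - 1, n - k, lower.tail = FALSE)
  const <- sst < 1e-12
  degenerate <- ssw < 1e-12 & !const   # perfect separation: p -> 0
  F[const] <- 0
  p[const] <- 1
  p[degenerate] <- 0
  F[degenerate] <- Inf
  q <- bh_adjust(p)
  res <- data.frame(transcript_id = rownames(x), F = F, p = p, q = q,
                    significant = q < q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "groups") <- as.character(g)
  attr(res, "q_threshold") <- q_threshold
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j: p(j) >= p(i)} m * p(j) / rank(j)`, capped at 1, with
#' stable handling of ties.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Pairwise group fold changes on linear FPKM
#'
#' `fold(a/b) = (mean_a + pseudocount) / (mean_b + pseudocount)` per
#' transcript, on linear group means. The default pseudocount equals the
#' 0.1-FPKM detection floor and stabilizes ratios of weakly expressed
#' transcripts.
#'
#' @param fpkm An `expr_matrix` with unit `FPKM` (or a plain matrix with
#'   `groups`).
#' @param groups Optional group labels per column.
#' @param pseudocount Nonnegative pseudocount (default 0.1).
#' @return `data.frame` with `transcript_id` and one `fold_<a>_<b>` column
#'   per ordered group pair (RAA/C, RAC/C, RAA/RAC when all three present).
#' @export
fold_changes <- function(fpkm, groups = NULL, pseudocount = 0.1) {
  if (inherits(fpkm, "expr_matrix")) stop_unless_unit(fpkm, "FPKM")
  x <- expr_values(fpkm)
  g <- expr_groups(fpkm, groups)
  lv <- intersect(c("RAA", "RAC", "C"), unique(g))
  if (!length(lv)) lv <- unique(g)
  if (any(!table(factor(g, levels = lv)))) stop("empty group")
  means <- sapply(lv, function(l) rowMeans(x[, g == l, drop = FALSE]))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1, dimnames = list(rownames(x), lv))
  }
  pairs <- if (all(c("RAA", "RAC", "C") %in% lv)) {
    list(c("RAA", "C"), c("RAC", "C"), c("RAA", "RAC"))
  } else {
    utils::combn(lv, 2, simplify = FALSE)
  }
  out <- data.frame(transcript_id = rownames(x), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (pr in pairs) {
    out[[paste0("fold_", pr[1], "_", pr[2])]] <-
      (means[, pr[1]] + pseudocount) / (means[, pr[2]] + pseudocount)
  }
  out
}

#' Two-cluster expression pattern assignment
#'
#' Hierarchical clustering of the significant transcripts with distance
#' `1 - Pearson correlation` across samples and average linkage, cut into
#' `k = 2` clusters. The cluster whose mean acute-vs-control (RAA/C) change
#' is negative is labeled `A` (down after rupture), the other `B` (up).
#' Zero-variance rows are excluded with a warning; if all pairwise
#' distances are (numerically) zero the cut is reported as degenerate and a
#' single cluster is returned instead of fabricating two.
#'
#' @param logmatrix An `expr_matrix` (unit `log2FPKMp1`) restricted to the
#'   significant transcripts, or a plain matrix with `groups`.
#' @param groups Optional group labels per column.
#' @param k Number of clusters (default 2).
#' @return List of class `pattern_assignment`: `pattern` (named character
#'   vector, `A`/`B`), `leaf_order` (dendrogram order of transcript ids),
#'   `degenerate` flag, `excluded` (zero-variance transcript ids), and the
#'   `hclust` tree.
#' @export
assign_patterns <- function(logmatrix, groups = NULL, k = 2L) {
  x <- expr_values(logmatrix)
  g <- expr_groups(logmatrix, groups)
  if (nrow(x) < 2) stop("need at least 2 transcripts to cluster")
  v <- apply(x, 1, sd)
  excluded <- rownames(x)[v < 1e-12]
  if (length(excluded)) {
    warning(length(excluded),
            " zero-variance transcripts excluded from clustering")
    x <- x[v >= 1e-12, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 variable transcripts")

  d <- as.dist(1 - cor(t(x)))
  tree <- hclust(d, method = "average")
  degenerate <- max(tree$height) < 1e-8
  cl <- if (degenerate) rep(1L, nrow(x)) else cutree(tree, k = k)

  # label by direction of the acute-vs-control shift
  has_contrast <- all(c("RAA", "C") %in% g)
  delta <- if (has_contrast) {
    rowMeans(x[, g == "RAA", drop = FALSE]) -
      rowMeans(x[, g == "C", drop = FALSE])
  } else {
    rowMeans(x) - stats::median(rowMeans(x))
  }
  lab <- character(max(cl))
  mean_delta <- tapply(delta, cl, mean)
  ord <- order(mean_delta)   # most decreased cluster first
  lab[as.integer(names(mean_delta))[ord]] <- LETTERS[seq_along(ord)]
  pattern <- setNames(lab[cl], rownames(x))

  structure(list(pattern = pattern,
                 leaf_order = rownames(x)[tree$order],
                 degenerate = degenerate,
                 excluded = excluded,
                 tree = tree),
            class = "pattern_assignment")
}

#' @export
print.pattern_assignment <- function(x, ...) {
  cat("pattern assignment:", length(x$pattern), "transcripts;",
      paste(sprintf("%s=%d", names(table(x$pattern)), table(x$pattern)),
            collapse = " "),
      if (x$degenerate) "(degenerate cut)" else "", "\n")
  invisible(x)
}

#' Spearman time-course screen on chronic-phase samples
#'
#' Rank-correlates each transcript's expression in the chronic (RAC) samples
#' against months since the event. A hit requires `|R| > R_threshold` and
#' `p < p_threshold`; the magnitude is used because post-rupture transcripts
#' typically decay back toward control levels (negative correlation).
#' Constant transcripts are excluded (correlation undefined), not errors.
#'
#' @param fpkm An `expr_matrix` restricted to RAC samples (any unit), or a
#'   plain matrix.
#' @param months_since_event Time values per sample; taken from the sample
#'   sheet when `NULL`.
#' @param R_threshold Correlation-magnitude threshold (default 0.7).
#' @param p_threshold P-value threshold (default 0.01).
#' @return `data.frame(transcript_id, R, p, direction, hit)` for all
#'   non-constant transcripts.
#' @export
timecourse_screen <- function(fpkm, months_since_event = NULL,
                              R_threshold = 0.7, p_threshold = 0.01) {
  x <- expr_values(fpkm)
  if (is.null(months_since_event)) {
    if (!inherits(fpkm, "expr_matrix") ||
        is.null(fpkm$samples$months_since_event)) {
      stop("months_since_event missing")
    }
    keep <- fpkm$samples$group == "RAC" &
      !is.na(fpkm$samples$months_since_event)
    x <- x[, keep, drop = FALSE]
    months_since_event <- fpkm$samples$months_since_event[keep]
  }
  stopifnot(length(months_since_event) == ncol(x))
  if (ncol(x) < 5) stop("need >= 5 timed samples")

  variable <- apply(x, 1, function(r) sd(r) > 0)
  x <- x[variable, , drop = FALSE]
  res <- apply(x, 1, function(r) {
    ct <- suppressWarnings(cor.test(r, months_since_event,
                                    method = "spearman", exact = FALSE))
    c(ct$estimate, ct$p.value)
  })
  out <- data.frame(transcript_id = rownames(x),
                    R = res[1, ], p = res[2, ],
                    direction = ifelse(res[1, ] >= 0, "up", "down"),
                    hit = abs(res[1, ]) > R_threshold & res[2, ] < p_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- sum(!variable)
  out
}

#' Full differential-expression table
#'
#' Convenience wrapper joining the ANOVA screen, pairwise fold changes and
#' the two-cluster pattern labels of the significant transcripts.
#'
#' @param counts,annotation Inputs to [compute_fpkm()].
#' @param q_threshold,pseudocount Passed to the component stages.
#' @return `data.frame` with F/p/q, folds, `significant` and `pattern`
#'   (`NA` for non-significant transcripts), plus the `pattern_assignment`
#'   as attribute `patterns` (NULL when < 2 significant transcripts).
#' @export
diffexpr_table <- function(counts, annotation, q_threshold = 1e-5,
                           pseudocount = 0.1) {
  fpkm <- compute_fpkm(counts, annotation)
  logm <- log_transform(fpkm)
  scr <- anova_screen(logm, q_threshold = q_threshold)
  folds <- fold_changes(fpkm, pseudocount = pseudocount)
  res <- merge(scr, folds, by = "transcript_id", sort = FALSE)
  res$pattern <- NA_character_
  sig <- res$transcript_id[res$significant]
  pat <- NULL
  if (length(sig) >= 2) {
    pat <- assign_patterns(logm[match(sig, rownames(logm$values)), ])
    res$pattern[match(names(pat$pattern), res$transcript_id)] <- pat$pattern
  }
  attr(res, "patterns") <- pat
  res
}
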