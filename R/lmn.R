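#' Standardized expression folds
#'
#' Per-gene, per-sample standardization of expression prior to gene-set
#' averaging. The default rule divides each sample's value by the gene's
#' mean over all samples (`fold` rule), which is positive and scale-free:
#' multiplying a gene by any constant leaves its standardized folds
#' unchanged. Alternatives: `zscore` (center/scale, then shift by +1 so set
#' means stay near 1) and `control_mean` (divide by the control-group mean).
#'
#' @param fpkm An `expr_matrix` with unit `FPKM` (or plain matrix; then
#'   `groups` needed for `control_mean`).
#' @param transcripts Optional transcript ids to restrict to.
#' @param rule `"fold"` (default), `"zscore"` or `"control_mean"`.
#' @param groups Optional group labels (for `control_mean`).
#' @return Numeric matrix of standardized folds (genes x samples).
#' @export
standardize_folds <- function(fpkm, transcripts = NULL,
                              rule = c("fold", "zscore", "control_mean"),
                              groups = NULL) {
  rule <- match.arg(rule)
  x <- expr_values(fpkm)
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, rownames(x))
    if (length(missing)) {
      stop("transcripts absent from matrix, e.g. ", missing[1])
    }
    x <- x[transcripts, , drop = FALSE]
  }
  switch(rule,
    fold = {
      m <- rowMeans(x)
      if (any(m == 0)) {
        stop("all-zero expression for ", rownames(x)[which(m == 0)[1]])
      }
      sweep(x, 1, m, `/`)
    },
    zscore = {
      m <- rowMeans(x)
      s <- apply(x, 1, sd)
      if (any(s == 0)) stop("zero-variance gene under zscore rule")
      sweep(sweep(x, 1, m, `-`), 1, s, `/`) + 1
    },
    control_mean = {
      g <- expr_groups(fpkm, groups)
      if (!any(g == "C")) stop("control_mean rule needs C samples")
      m <- rowMeans(x[, g == "C", drop = FALSE])
      if (any(m == 0)) stop("all-zero control expression")
      sweep(x, 1, m, `/`)
    })
}

#' Per-sample L/MN index
#'
#' Ratio of the mean standardized fold of the lymphocyte gene set to that of
#' the monocyte-and-neutrophil gene set. Values below 1 indicate lymphocyte
#' depression relative to myeloid activation.
#'
#' @param std_folds Matrix from [standardize_folds()] containing all set
#'   members as rows.
#' @param genesets `data.frame(symbol, set, transcript_id)` with
#'   `set` in `{L, MN}`; `transcript_id` may be omitted when rows of
#'   `std_folds` are named by symbol.
#' @return Named numeric vector of per-sample L/MN values.
#' @export
lmn_value <- function(std_folds, genesets) {
  ids <- genesets$transcript_id %||% genesets$symbol
  l_ids <- ids[genesets$set == "L"]
  mn_ids <- ids[genesets$set == "MN"]
  if (!length(l_ids) || !length(mn_ids)) stop("both gene sets must be nonempty")
  if (length(intersect(l_ids, mn_ids))) stop("L and MN sets must be disjoint")
  missing <- setdiff(c(l_ids, mn_ids), rownames(std_folds))
  if (length(missing)) stop("gene-set member absent, e.g. ", missing[1])
  l_mean <- colMeans(std_folds[l_ids, , drop = FALSE])
  mn_mean <- colMeans(std_folds[mn_ids, , drop = FALSE])
  if (any(mn_mean == 0)) stop("zero MN set mean")
  l_mean / mn_mean
}

#' Welch group comparisons
#'
#' Two-sided Welch (unequal-variance) t-tests with Satterthwaite degrees of
#' freedom for every pair of groups.
#'
#' @param values Numeric vector (e.g. per-sample L/MN values).
#' @param groups Group label per value.
#' @return `data.frame(group_a, group_b, t, df, p)`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lv <- intersect(c("RAA", "RAC", "C"), unique(groups))
  if (!length(lv)) lv <- unique(groups)
  if (any(table(factor(groups, levels = lv)) < 2)) {
    stop("each group needs >= 2 values")
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      # Welch t is 0/0 for two identical constant groups; no evidence of
      # difference
      return(data.frame(group_a = pr[1], group_b = pr[2], t = 0,
                        df = length(a) + length(b) - 2, p = 1,
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(a, b, var.equal = FALSE)
    data.frame(group_a = pr[1], group_b = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
}

#' Compute the L/MN index for a cohort
#'
#' Standardizes the gene-set transcripts, forms per-sample L/MN values,
#' summarizes per group and runs pairwise Welch tests.
#'
#' @param fpkm An `expr_matrix` with unit `FPKM`.
#' @param genesets `data.frame(symbol, set, transcript_id)`; defaults to the
#'   canonical symbols of [lmn_geneset_symbols()] (rows must then be named
#'   by symbol).
#' @param rule Standardization rule, see [standardize_folds()].
#' @return List of class `lmn_result`: `values` (per sample), `samples`,
#'   `group_summary` (`data.frame(group, n, mean, sd)`), `comparisons`
#'   (Welch tests).
#' @export
lmn_index <- function(fpkm, genesets = lmn_geneset_symbols(),
                      rule = "fold") {
  stop_unless_unit(fpkm, "FPKM")
  ids <- genesets$transcript_id %||% genesets$symbol
  std <- standardize_folds(fpkm, transcripts = unique(ids), rule = rule)
  vals <- lmn_value(std, genesets)
  g <- expr_groups(fpkm)
  summary <- do.call(rbind, lapply(split(vals, g), function(v) {
    data.frame(n = length(v), mean = mean(v), sd = sd(v))
  }))
  summary <- data.frame(group = rownames(summary), summary,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(values = vals, samples = fpkm$samples,
                 group_summary = summary,
                 comparisons = compare_groups(vals, g)),
            class = "lmn_result")
}

#' @export
print.lmn_result <- function(x, ...) {
  cat("L/MN index:\n")
  print(x$group_summary, row.names = FALSE)
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
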