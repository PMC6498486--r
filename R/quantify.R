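#' Convert fragment counts to FPKM
#'
#' `FPKM(t,s) = count(t,s) / (exonic_length(t)/1e3 * total_fragments(s)/1e6)`.
#' Only the exonic (mature-mRNA) length enters the normalization; intronic
#' reads are quantified separately by the exon/intron scoring stage.
#'
#' @param counts An `expr_matrix` with unit `counts`.
#' @param annotation A `transcript_annotation` covering every row.
#' @param total_fragments Optional per-sample mapped-fragment totals;
#'   defaults to the column sums of `counts`.
#' @return An `expr_matrix` with unit `FPKM`.
#' @export
compute_fpkm <- function(counts, annotation, total_fragments = NULL) {
  stop_unless_unit(counts, "counts")
  validate_annotation(annotation)
  values <- expr_values(counts)
  idx <- match(rownames(values), annotation$transcript_id)
  if (anyNA(idx)) {
    stop("transcripts missing from annotation, e.g. ",
         rownames(values)[which(is.na(idx))[1]])
  }
  len_kb <- annotation$exonic_length[idx] / 1e3
  totals <- total_fragments %||% colSums(values)
  if (any(totals <= 0)) {
    stop("zero-depth sample: ", colnames(values)[which(totals <= 0)[1]])
  }
  fpkm <- sweep(sweep(values, 1, len_kb, `/`), 2, totals / 1e6, `/`)
  expr_matrix(fpkm, counts$samples, "FPKM")
}

#' Detection / basal-expression filter
#'
#' Returns the transcripts whose FPKM satisfies the comparator against the
#' threshold. Detection uses `>=` at 0.1 FPKM; basal expression uses `>` at
#' 0.5 FPKM. By default the mean across all samples is compared; `mode =
#' "any"` keeps a transcript if any single sample satisfies the comparator.
#'
#' @param fpkm An `expr_matrix` with unit `FPKM`.
#' @param threshold FPKM threshold (default 0.1, the detection floor).
#' @param comparator `">="` (detection) or `">"` (basal expression).
#' @param mode `"mean"` (default) or `"any"`.
#' @return Character vector of transcript ids passing the filter.
#' @export
detection_filter <- function(fpkm, threshold = 0.1,
                             comparator = c(">=", ">"),
                             mode = c("mean", "any")) {
  stop_unless_unit(fpkm, "FPKM")
  comparator <- match.arg(comparator)
  mode <- match.arg(mode)
  values <- expr_values(fpkm)
  cmp <- match.fun(comparator)
  keep <- if (mode == "mean") {
    cmp(rowMeans(values), threshold)
  } else {
    apply(cmp(values, threshold), 1, any)
  }
  rownames(values)[keep]
}

#' log2(1 + x) transform
#'
#' Maps FPKM onto an approximately normal continuous scale for per-transcript
#' ANOVA; strictly monotone and invertible.
#'
#' @param fpkm An `expr_matrix` with unit `FPKM`.
#' @return An `expr_matrix` with unit `log2FPKMp1`.
#' @export
log_transform <- function(fpkm) {
  stop_unless_unit(fpkm, "FPKM")
  values <- expr_values(fpkm)
  if (any(values < 0)) stop("negative expression values")
  expr_matrix(log2(1 + values), fpkm$samples, "log2FPKMp1")
}
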