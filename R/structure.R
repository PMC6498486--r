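#' Biotype composition of a transcript set
#'
#' Exact per-biotype counts and proportions for a named transcript set,
#' e.g. the regulated transcripts versus all transcripts expressed at basal
#' conditions.
#'
#' @param transcripts Character vector of transcript ids (nonempty).
#' @param annotation A `transcript_annotation` covering every id.
#' @return `data.frame(biotype, count, proportion)` of class
#'   `biotype_profile`, sorted by decreasing count.
#' @export
biotype_profile <- function(transcripts, annotation) {
  if (!length(transcripts)) stop("empty transcript set")
  validate_annotation(annotation)
  idx <- match(transcripts, annotation$transcript_id)
  if (anyNA(idx)) {
    stop("unannotated transcript, e.g. ", transcripts[which(is.na(idx))[1]])
  }
  tab <- table(annotation$biotype[idx])
  out <- data.frame(biotype = names(tab),
                    count = as.integer(tab),
                    proportion = as.numeric(tab) / length(transcripts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("biotype_profile", "data.frame")
  out
}

#' Exon/intron ratio score and up/down comparison
#'
#' Per gene, `ratio = (sum exonic + pseudocount) / (sum intronic +
#' pseudocount)` with counts summed across the supplied samples. A low
#' ratio means a large unspliced pre-mRNA fraction, read as active
#' transcriptional pressure. The up- and downregulated sets are compared by
#' a two-sided Mann-Whitney U test on the per-gene ratios.
#'
#' @param exonic,intronic `expr_matrix` objects (unit `counts`) over the
#'   same transcripts and samples.
#' @param up_set,down_set Transcript-id vectors of the up- and downregulated
#'   genes (must be present in both matrices).
#' @param pseudocount Positive pseudocount (default 1) keeping ratios finite
#'   for intronless observations.
#' @param samples Optional sample ids or logical/integer index restricting
#'   the summation (e.g. acute-phase samples only).
#' @return List of class `exon_intron_score`: `scores`
#'   (`data.frame(transcript_id, set, exonic, intronic, ratio)`),
#'   `median_up`, `median_down`, `p` (Mann-Whitney).
#' @export
exon_intron_score <- function(exonic, intronic, up_set, down_set,
                              pseudocount = 1, samples = NULL) {
  stopifnot(pseudocount > 0)
  ex <- expr_values(exonic)
  intr <- expr_values(intronic)
  stopifnot(identical(dimnames(ex), dimnames(intr)))
  if (!is.null(samples)) {
    ex <- ex[, samples, drop = FALSE]
    intr <- intr[, samples, drop = FALSE]
  }
  ids <- c(up_set, down_set)
  if (!length(up_set) || !length(down_set)) stop("both gene sets required")
  missing <- setdiff(ids, rownames(ex))
  if (length(missing)) stop("gene absent from matrices, e.g. ", missing[1])

  ex_sum <- rowSums(ex[ids, , drop = FALSE])
  in_sum <- rowSums(intr[ids, , drop = FALSE])
  ratio <- (ex_sum + pseudocount) / (in_sum + pseudocount)
  set <- rep(c("up", "down"), c(length(up_set), length(down_set)))
  scores <- data.frame(transcript_id = ids, set = set,
                       exonic = ex_sum, intronic = in_sum, ratio = ratio,
                       stringsAsFactors = FALSE, row.names = NULL)
  mw <- wilcox.test(ratio[set == "up"], ratio[set == "down"],
                    alternative = "two.sided", exact = FALSE)
  structure(list(scores = scores,
                 median_up = median(ratio[set == "up"]),
                 median_down = median(ratio[set == "down"]),
                 p = mw$p.value),
            class = "exon_intron_score")
}

#' @export
print.exon_intron_score <- function(x, ...) {
  cat("exon/intron ratio score: median up =", signif(x$median_up, 4),
      ", median down =", signif(x$median_down, 4),
      ", Mann-Whitney p =", format(x$p, digits = 3), "\n")
  invisible(x)
}
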