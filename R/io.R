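# TSV + sidecar-JSON persistence for expression matrices, sample sheets,
# gene sets and cell-count tables.

#' Write / read an expression matrix as TSV
#'
#' The matrix goes to `<path>` (rows = transcripts, columns = samples, first
#' column `transcript_id`); the unit tag and sample sheet go to a sidecar
#' JSON header at `<path>.json`.
#'
#' @param x An `expr_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); an `expr_matrix` (reader).
#' @export
write_expr_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(transcript_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(unit = x$unit, samples = x$samples),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- as.data.frame(side$samples, stringsAsFactors = FALSE)
  if (is.null(samples$months_since_event)) {
    samples$months_since_event <- NA_real_
  }
  expr_matrix(values, samples, side$unit)
}

#' Write transcript annotation as GTF
#'
#' Emits exon features on a single synthetic contig: each transcript is laid
#' out as two exons separated by its intron (or a single exon when
#' `intronic_length` is 0), so introns can be re-derived as within-transcript
#' gaps. Biotype and marker labels travel as attributes. Requires the
#' `rtracklayer` package.
#'
#' @param annotation A `transcript_annotation`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("writing GTF requires the ", pkg, " package")
    }
  }
  validate_annotation(annotation)
  n <- nrow(annotation)
  exon1 <- pmax(1L, annotation$exonic_length %/% 2L)
  exon2 <- annotation$exonic_length - exon1
  two_exons <- annotation$intronic_length > 0 & exon2 > 0
  span <- annotation$exonic_length + annotation$intronic_length
  tx_start <- cumsum(c(1, head(span + 1000L, -1)))

  starts <- c(tx_start, tx_start[two_exons] + exon1[two_exons] +
                annotation$intronic_length[two_exons])
  widths <- c(ifelse(two_exons, exon1, annotation$exonic_length),
              exon2[two_exons])
  tx <- c(annotation$transcript_id, annotation$transcript_id[two_exons])
  gene <- c(annotation$gene_id, annotation$gene_id[two_exons])
  bio <- c(annotation$biotype, annotation$biotype[two_exons])
  marker <- c(annotation$marker_of, annotation$marker_of[two_exons])
  exon_no <- c(rep(1L, n), rep(2L, sum(two_exons)))

  ord <- order(starts)
  gr <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = starts[ord], width = widths[ord]),
    strand = "+",
    type = "exon",
    source = "bloodshift",
    gene_id = gene[ord],
    transcript_id = tx[ord],
    transcript_biotype = bio[ord],
    marker_of = ifelse(is.na(marker[ord]), "NONE", marker[ord]),
    exon_number = exon_no[ord]
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a gene-set file
#'
#' Two-column TSV `(symbol, set)` with `set` in `{L, MN}` and an optional
#' third column `transcript_id`.
#'
#' @param path TSV path.
#' @return `data.frame(symbol, set[, transcript_id])`.
#' @export
read_genesets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "set") %in% names(df)),
            all(df$set %in% c("L", "MN")))
  df
}

#' @rdname read_genesets
#' @param genesets Gene-set `data.frame` to write.
#' @export
write_genesets <- function(genesets, path) {
  write.table(genesets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a cell-count table as TSV
#' @param cellcounts Cell-count `data.frame`.
#' @param path TSV path.
#' @export
write_cellcounts <- function(cellcounts, path) {
  write.table(cellcounts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cellcounts
#' @export
read_cellcounts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
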