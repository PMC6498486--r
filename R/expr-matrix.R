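#' Expression matrix with sample metadata and a unit tag
#'
#' A light container in the style of limma's `EList`: a numeric matrix of
#' transcripts x samples plus a sample sheet and a unit tag
#' (`"counts"`, `"FPKM"` or `"log2FPKMp1"`).
#'
#' @param values Numeric matrix, rows = transcripts, columns = samples.
#' @param samples `data.frame` with at least `sample_id` and `group`
#'   (levels among `RAA`, `RAC`, `C`); optional `months_since_event`.
#' @param unit One of `"counts"`, `"FPKM"`, `"log2FPKMp1"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples, unit = c("counts", "FPKM",
                                                  "log2FPKMp1")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  stopifnot(is.numeric(values))
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "group") %in% names(samples)),
            nrow(samples) == ncol(values))
  if (any(!samples$group %in% c("RAA", "RAC", "C"))) {
    stop("sample group labels must be among RAA, RAC, C")
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  stopifnot(identical(colnames(values), as.character(samples$sample_id)))
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Subset an expression matrix
#'
#' Row subsetting keeps all samples; column subsetting also subsets the
#' sample sheet.
#' @param x An `expr_matrix`.
#' @param i,j Row (transcript) and column (sample) indices.
#' @param ... Ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expr_matrix(x$values[i, j, drop = FALSE], x$samples[j, , drop = FALSE],
              x$unit)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "transcripts x", ncol(x$values),
      "samples [", x$unit, "]\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = " "), "\n")
  invisible(x)
}

expr_unit <- function(x) {
  if (inherits(x, "expr_matrix")) x$unit else stop("not an expr_matrix")
}

expr_values <- function(x) if (inherits(x, "expr_matrix")) x$values else x

expr_groups <- function(x, groups = NULL) {
  if (!is.null(groups)) return(as.character(groups))
  if (inherits(x, "expr_matrix")) return(as.character(x$samples$group))
  stop("group labels required for a plain matrix")
}

stop_unless_unit <- function(x, unit) {
  if (inherits(x, "expr_matrix") && x$unit != unit) {
    stop("expected unit '", unit, "', got '", x$unit, "'")
  }
  invisible(x)
}
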