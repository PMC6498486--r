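#' Supported transcript biotypes and blood cell types
#'
#' The biotype vocabulary is a configurable subset of the Ensembl/Vega
#' transcript classes commonly seen in whole-blood RNA-seq; `"other"` pools
#' the long tail of rare classes. Cell types are the major peripheral-blood
#' leukocyte populations resolved by standard flow panels, with monocytes
#' split into classical (CD14++CD16-), intermediate (CD14++CD16+) and
#' nonclassical (CD14+CD16++) subsets.
#'
#' @return Character vector of labels.
#' @export
biotype_vocabulary <- function() {
  c("protein_coding", "retained_intron", "processed_transcript",
    "lincRNA", "antisense", "nonsense_mediated_decay", "other")
}

#' @rdname biotype_vocabulary
#' @export
blood_cell_types <- function() {
  c("CD4T", "CD8T", "B", "NK",
    "MONO_CLASSICAL", "MONO_INTERMEDIATE", "MONO_NONCLASSICAL", "NEUTROPHIL")
}

#' Default biotype mixture
#'
#' Proportions of transcript biotypes among transcripts expressed at basal
#' conditions in whole blood: about half protein coding, with retained-intron
#' and processed transcripts the dominant noncoding classes.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_biotype_mix <- function() {
  c(protein_coding = 0.502, retained_intron = 0.217,
    processed_transcript = 0.120, lincRNA = 0.060, antisense = 0.050,
    other = 0.051)
}

#' Generate a synthetic transcript annotation
#'
#' Draws `n_transcripts` transcript records with biotypes sampled from
#' `biotype_mix`, log-normal exonic lengths, intronic lengths (a fraction of
#' transcripts are single-exon with no intron), and optional cell-type marker
#' labels. One transcript per gene is generated; `gene_symbol` defaults to
#' the gene id and can be overwritten to map named gene sets onto planted
#' markers.
#'
#' @param n_transcripts Number of transcripts (positive integer).
#' @param biotype_mix Named probability vector over [biotype_vocabulary()].
#'   Need not be normalized exactly but must be nonnegative with positive sum.
#' @param marker_config Named integer vector: number of marker transcripts to
#'   plant per cell type (names from [blood_cell_types()]). Total must not
#'   exceed `n_transcripts`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `data.frame` of class `transcript_annotation` with columns
#'   `transcript_id`, `gene_id`, `gene_symbol`, `biotype`, `exonic_length`,
#'   `intronic_length`, `marker_of` (`NA` for non-markers).
#' @export
generate_annotation <- function(n_transcripts,
                                biotype_mix = default_biotype_mix(),
                                marker_config = NULL,
                                seed = 1L) {
  stopifnot(length(n_transcripts) == 1L, n_transcripts >= 1)
  if (is.null(names(biotype_mix)) || any(biotype_mix < 0) ||
      sum(biotype_mix) <= 0 || !all(is.finite(biotype_mix))) {
    stop("biotype_mix must be a named nonnegative vector with positive sum")
  }
  unknown <- setdiff(names(biotype_mix), biotype_vocabulary())
  if (length(unknown)) {
    stop("unknown biotypes in biotype_mix: ", paste(unknown, collapse = ", "))
  }
  biotype_mix <- biotype_mix / sum(biotype_mix)
  if (!is.null(marker_config)) {
    bad <- setdiff(names(marker_config), blood_cell_types())
    if (length(bad)) stop("unknown cell types: ", paste(bad, collapse = ", "))
    if (sum(marker_config) > n_transcripts) {
      stop("marker demand (", sum(marker_config),
           ") exceeds n_transcripts (", n_transcripts, ")")
    }
  }

  with_seed(seed, {
    ids <- sprintf("TX%06d", seq_len(n_transcripts))
    biotype <- sample(names(biotype_mix), n_transcripts, replace = TRUE,
                      prob = biotype_mix)
    exonic <- pmax(200L, as.integer(round(rlnorm(n_transcripts,
                                                 meanlog = log(2000),
                                                 sdlog = 0.6))))
    single_exon <- runif(n_transcripts) < 0.2
    intronic <- as.integer(round(rlnorm(n_transcripts,
                                        meanlog = log(8000), sdlog = 1)))
    intronic[single_exon] <- 0L

    marker_of <- rep(NA_character_, n_transcripts)
    if (!is.null(marker_config) && sum(marker_config) > 0) {
      slots <- sample.int(n_transcripts, sum(marker_config))
      marker_of[slots] <- rep(names(marker_config), times = marker_config)
    }

    ann <- data.frame(
      transcript_id = ids,
      gene_id = sprintf("GN%06d", seq_len(n_transcripts)),
      gene_symbol = sprintf("GN%06d", seq_len(n_transcripts)),
      biotype = biotype,
      exonic_length = exonic,
      intronic_length = intronic,
      marker_of = marker_of,
      stringsAsFactors = FALSE
    )
    class(ann) <- c("transcript_annotation", "data.frame")
    ann
  })
}

validate_annotation <- function(annotation) {
  stopifnot(is.data.frame(annotation))
  req <- c("transcript_id", "gene_id", "biotype", "exonic_length",
           "intronic_length")
  missing <- setdiff(req, names(annotation))
  if (length(missing)) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(annotation$transcript_id)) {
    stop("transcript_id values must be unique")
  }
  if (any(annotation$exonic_length < 1)) stop("exonic_length must be >= 1")
  if (any(annotation$intronic_length < 0)) stop("intronic_length must be >= 0")
  invisible(annotation)
}

#' Marker transcripts of a cell type
#'
#' @param annotation A `transcript_annotation`.
#' @param cell_type One or more cell-type labels.
#' @return Character vector of transcript ids planted as markers.
#' @export
marker_transcripts <- function(annotation, cell_type) {
  annotation$transcript_id[!is.na(annotation$marker_of) &
                             annotation$marker_of %in% cell_type]
}
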