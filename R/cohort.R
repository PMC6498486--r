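# per-transcript x cell-type regulation matrix for one group (default 1)
regulation_matrix <- function(design, annotation, group) {
  R <- matrix(1, nrow(annotation), length(design$cell_types),
              dimnames = list(annotation$transcript_id, design$cell_types))
  reg <- design$regulation[design$regulation$group == group, , drop = FALSE]
  if (nrow(reg)) {
    missing <- setdiff(reg$transcript_id, annotation$transcript_id)
    if (length(missing)) {
      stop("regulation references unknown transcripts, e.g. ", missing[1])
    }
    R[cbind(match(reg$transcript_id, annotation$transcript_id),
            match(reg$cell_type, design$cell_types))] <- reg$multiplier
  }
  R
}

# expected cell-number proportions per group after count multipliers
group_proportions <- function(design) {
  p <- sweep(design$cellcount_multiplier, 2, design$base_proportions, `*`)
  sweep(p, 1, rowSums(p), `/`)
}

# pre-mRNA fraction per transcript for one group
premrna_fractions <- function(design, annotation, group) {
  f <- rep(design$premrna_baseline, nrow(annotation))
  names(f) <- annotation$transcript_id
  ov <- design$premrna_override
  if (!is.null(ov)) {
    ov <- ov[ov$group == group, , drop = FALSE]
    f[ov$transcript_id] <- ov$fraction
  }
  f
}

#' Closed-form expected group fold changes
#'
#' Expected bulk abundance of transcript `t` in group `g` is the
#' cell-proportion-weighted sum of per-cell baselines times regulation,
#' renormalized so the expected library size is constant across samples:
#' `mu(t,g) = L * w(t,g) / sum_t' w(t',g)` with
#' `w(t,g) = sum_c pbar(c,g) * baseline(t,c) * regulation(g,c,t)`.
#' The expected fold between two groups is the ratio of these renormalized
#' means; the renormalization makes folds compositional, shrinking marker
#' folds relative to the raw multipliers.
#'
#' @param annotation,signatures,design As in [generate_cohort()].
#' @return `data.frame(transcript_id, fold_RAA_C, fold_RAC_C, fold_RAA_RAC)`.
#' @export
expected_folds <- function(annotation, signatures, design) {
  validate_annotation(annotation)
  validate_signatures(signatures, annotation)
  B <- unclass(signatures)[annotation$transcript_id, design$cell_types,
                           drop = FALSE]
  pbar <- group_proportions(design)
  mu <- sapply(rownames(pbar), function(g) {
    w <- (B * regulation_matrix(design, annotation, g)) %*% pbar[g, ]
    design$library_size * w / sum(w)
  })
  data.frame(transcript_id = annotation$transcript_id,
             fold_RAA_C = mu[, "RAA"] / mu[, "C"],
             fold_RAC_C = mu[, "RAC"] / mu[, "C"],
             fold_RAA_RAC = mu[, "RAA"] / mu[, "RAC"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a bulk blood cohort from cell-type signatures
#'
#' Realizes the design: per-sample absolute leukocyte counts are drawn from
#' gamma distributions around the group means (so that cell proportions
#' follow a Dirichlet with the design's concentration), bulk expected counts
#' are the proportion-weighted mixture of per-cell signatures times
#' regulation, rescaled to a constant expected library size, total fragment
#' counts are drawn negative-binomially with the design's dispersion, and
#' each transcript's fragments are split binomially into intronic
#' (pre-mRNA) and exonic reads.
#'
#' @param annotation A `transcript_annotation`.
#' @param signatures A `cell_signatures` matrix covering every transcript.
#' @param design A `cohort_design`.
#' @return List with elements
#'   `exonic`, `intronic` (`expr_matrix` objects, unit `counts`),
#'   `cellcounts` (a `data.frame`: absolute counts per leukocyte subset,
#'   cells/uL), and `truth` (the realized design, closed-form
#'   [expected_folds()], per-sample realized cell proportions).
#' @export
generate_cohort <- function(annotation, signatures, design) {
  validate_annotation(annotation)
  validate_signatures(signatures, annotation)
  stopifnot(inherits(design, "cohort_design"))
  if (design$library_size <= 0) stop("library_size must be positive")
  B <- unclass(signatures)[annotation$transcript_id, design$cell_types,
                           drop = FALSE]
  n_tx <- nrow(annotation)
  groups <- names(design$group_sizes)

  with_seed(design$seed, {
    sample_group <- rep(groups, design$group_sizes)
    sample_id <- sprintf("%s_%02d", sample_group,
                         unlist(lapply(design$group_sizes, seq_len)))
    n_s <- length(sample_id)

    # absolute leukocyte counts: gamma around group means so proportions are
    # Dirichlet(concentration * group mean) and count folds track multipliers
    conc <- design$concentration
    base_counts <- design$wbc_base * design$base_proportions
    counts_cells <- matrix(0, n_s, length(design$cell_types),
                           dimnames = list(sample_id, design$cell_types))
    for (ct in design$cell_types) {
      shape <- conc * design$base_proportions[ct] *
        design$cellcount_multiplier[sample_group, ct]
      counts_cells[, ct] <- design$wbc_base * rgamma(n_s, shape = shape,
                                                     rate = conc)
    }
    props <- counts_cells / rowSums(counts_cells)

    # expected bulk counts, then NB noise and the exon/intron binomial split
    total <- matrix(0, n_tx, n_s,
                    dimnames = list(annotation$transcript_id, sample_id))
    intronic <- total
    for (g in groups) {
      idx <- which(sample_group == g)
      W <- (B * regulation_matrix(design, annotation, g)) %*%
        t(props[idx, , drop = FALSE])
      mu <- design$library_size * sweep(W, 2, colSums(W), `/`)
      draw <- if (design$dispersion == 0) {
        rpois(length(mu), lambda = mu)
      } else {
        rnbinom(length(mu), mu = mu, size = 1 / design$dispersion)
      }
      tot_g <- matrix(draw, nrow = n_tx)
      f <- premrna_fractions(design, annotation, g)
      intr_g <- matrix(rbinom(length(tot_g), size = as.vector(tot_g),
                              prob = rep(f, ncol(tot_g))),
                       nrow = n_tx)
      total[, idx] <- tot_g
      intronic[, idx] <- intr_g
    }
    exonic <- total - intronic

    months <- rep(NA_real_, n_s)
    months[sample_group == "RAC"] <- design$months_since_event
    samples <- data.frame(sample_id = sample_id, group = sample_group,
                          months_since_event = months,
                          stringsAsFactors = FALSE)

    cellcounts <- data.frame(
      sample_id = sample_id,
      group = sample_group,
      lymphocytes = rowSums(counts_cells[, c("CD4T", "CD8T", "B", "NK")]),
      cd3 = rowSums(counts_cells[, c("CD4T", "CD8T")]),
      cd4 = counts_cells[, "CD4T"],
      cd8 = counts_cells[, "CD8T"],
      monocytes = rowSums(counts_cells[, c("MONO_CLASSICAL",
                                           "MONO_INTERMEDIATE",
                                           "MONO_NONCLASSICAL")]),
      mono_classical = counts_cells[, "MONO_CLASSICAL"],
      mono_intermediate = counts_cells[, "MONO_INTERMEDIATE"],
      mono_nonclassical = counts_cells[, "MONO_NONCLASSICAL"],
      neutrophils = counts_cells[, "NEUTROPHIL"],
      stringsAsFactors = FALSE, row.names = NULL
    )

    truth <- list(design = design,
                  expected_folds = expected_folds(annotation, signatures,
                                                  design),
                  proportions = props)

    list(exonic = expr_matrix(exonic, samples, "counts"),
         intronic = expr_matrix(intronic, samples, "counts"),
         cellcounts = cellcounts,
         truth = truth)
  })
}

#' Canonical gene sets of the L/MN index
#'
#' Lymphocyte-related (`L`) and monocyte-and-neutrophil-related (`MN`) gene
#' symbols whose mean standardized-fold expression forms the index.
#' @return `data.frame(symbol, set)`.
#' @export
lmn_geneset_symbols <- function() {
  data.frame(
    symbol = c("BCL11B", "CCR7", "CD2", "CD27", "CD3D", "CD3E", "CD8A",
               "KLRB1",
               "ANXA3", "ARG1", "CD14", "GYG1", "FCGR1A", "FCGR2A", "IRAK3",
               "MMP9"),
    set = rep(c("L", "MN"), each = 8L),
    stringsAsFactors = FALSE
  )
}

#' Simulate the full acute-rupture scenario
#'
#' One-call driver: generates annotation (with planted markers), cell-type
#' signatures, the [default_paper_scenario()] design and the simulated
#' cohort, and maps the canonical L/MN gene symbols onto planted marker
#' transcripts (L genes onto CD4/CD8 T-cell and NK markers, MN genes onto
#' classical-monocyte and neutrophil markers).
#'
#' @param seed Integer seed controlling every draw.
#' @param n_transcripts Transcriptome size.
#' @return List: `annotation`, `signatures`, `design`, `cohort` (see
#'   [generate_cohort()]), `genesets`
#'   (`data.frame(symbol, set, transcript_id)`), `marker_sets` (list of
#'   transcript-id vectors per population: `CD4`, `CD14`, `MN`), and
#'   `up_set`/`down_set` (planted regulated blocks).
#' @export
simulate_scenario <- function(seed = 1L, n_transcripts = 2000L) {
  annotation <- generate_annotation(n_transcripts,
                                    marker_config = default_marker_config(),
                                    seed = seed)
  design <- default_paper_scenario(seed, annotation)
  signatures <- generate_signatures(annotation, seed = seed + 1L)

  gs <- lmn_geneset_symbols()
  cd4 <- head(marker_transcripts(annotation, "CD4T"), 4L)
  cd8 <- head(marker_transcripts(annotation, "CD8T"), 3L)
  nk <- head(marker_transcripts(annotation, "NK"), 1L)
  mc <- head(marker_transcripts(annotation, "MONO_CLASSICAL"), 4L)
  neu <- head(marker_transcripts(annotation, "NEUTROPHIL"), 4L)
  gs$transcript_id <- c(
    cd4,                      # BCL11B CCR7 CD2 CD27
    cd8,                      # CD3D CD3E CD8A
    nk,                       # KLRB1
    neu[1:2],                 # ANXA3 ARG1
    mc[1:2],                  # CD14 GYG1
    mc[3], neu[3],            # FCGR1A FCGR2A
    mc[4], neu[4]             # IRAK3 MMP9
  )
  # keep symbol -> transcript unique and sets disjoint
  stopifnot(!anyDuplicated(gs$transcript_id))
  annotation$gene_symbol[match(gs$transcript_id,
                               annotation$transcript_id)] <- gs$symbol

  cohort <- generate_cohort(annotation, signatures, design)
  marker_sets <- list(
    CD4 = marker_transcripts(annotation, "CD4T"),
    CD14 = head(marker_transcripts(annotation, "MONO_CLASSICAL"), 8L),
    MN = gs$transcript_id[gs$set == "MN"]
  )
  list(annotation = annotation, signatures = signatures, design = design,
       cohort = cohort, genesets = gs, marker_sets = marker_sets,
       up_set = attr(design, "up_set"), down_set = attr(design, "down_set"))
}
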