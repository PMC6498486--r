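#' Construct a cohort simulation design
#'
#' Describes the three-group study design the generator realizes: group
#' sizes, baseline cell-type composition, per-group cell-count multipliers,
#' per-cell-type/per-transcript regulation multipliers, pre-mRNA fractions,
#' sampling noise and sequencing depth. The control group (`C`) is the
#' reference: its multipliers must be identically 1.
#'
#' @param group_sizes Named integer vector over `RAA`, `RAC`, `C`.
#' @param cell_types Cell-type labels; defaults to [blood_cell_types()].
#' @param base_proportions Named baseline cell proportions (control group);
#'   normalized to sum to 1.
#' @param cellcount_multiplier Numeric matrix groups x cell types of positive
#'   factors applied to expected cell counts; `C` row must be all 1.
#' @param regulation `data.frame(group, cell_type, transcript_id, multiplier)`
#'   of per-cell transcriptional regulation factors (> 0); absent entries are 1.
#' @param premrna_baseline Baseline intronic (pre-mRNA) read fraction in
#'   `[0, 1)`, applied to every transcript unless overridden.
#' @param premrna_override `data.frame(group, transcript_id, fraction)` with
#'   fractions in `[0, 1)`.
#' @param months_since_event Positive months since the bleed for each RAC
#'   sample (length must match `group_sizes["RAC"]`).
#' @param dispersion Negative-binomial dispersion (> 0; variance
#'   `mu + dispersion * mu^2`). `0` selects the Poisson limit.
#' @param library_size Expected sequenced fragments per sample (> 0).
#' @param concentration Dirichlet-like concentration of per-sample cell
#'   proportions around group means (larger = less compositional noise).
#' @param wbc_base Expected total white-blood-cell count in the control
#'   group, cells per microliter.
#' @param seed Integer seed realized by [generate_cohort()].
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(RAA = 19L, RAC = 20L, C = 20L),
                          cell_types = blood_cell_types(),
                          base_proportions = default_blood_proportions(),
                          cellcount_multiplier = NULL,
                          regulation = NULL,
                          premrna_baseline = 0.1,
                          premrna_override = NULL,
                          months_since_event = NULL,
                          dispersion = 0.1,
                          library_size = 1e6,
                          concentration = 200,
                          wbc_base = 7000,
                          seed = 1L) {
  groups <- c("RAA", "RAC", "C")
  stopifnot(all(groups %in% names(group_sizes)), all(group_sizes >= 1))
  base_proportions <- base_proportions[cell_types]
  stopifnot(!anyNA(base_proportions), all(base_proportions > 0))
  base_proportions <- base_proportions / sum(base_proportions)

  if (is.null(cellcount_multiplier)) {
    cellcount_multiplier <- matrix(1, 3, length(cell_types),
                                   dimnames = list(groups, cell_types))
  }
  stopifnot(identical(rownames(cellcount_multiplier), groups),
            identical(colnames(cellcount_multiplier), cell_types),
            all(cellcount_multiplier > 0))
  if (any(cellcount_multiplier["C", ] != 1)) {
    stop("control-group cell-count multipliers must be identically 1")
  }

  if (is.null(regulation)) {
    regulation <- data.frame(group = character(), cell_type = character(),
                             transcript_id = character(),
                             multiplier = numeric(),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "cell_type", "transcript_id", "multiplier") %in%
                  names(regulation)),
            all(regulation$multiplier > 0),
            all(regulation$cell_type %in% cell_types),
            all(regulation$group %in% groups))
  if (any(regulation$group == "C" & regulation$multiplier != 1)) {
    stop("control-group regulation multipliers must be identically 1")
  }

  stopifnot(premrna_baseline >= 0, premrna_baseline < 1)
  if (!is.null(premrna_override)) {
    stopifnot(all(c("group", "transcript_id", "fraction") %in%
                    names(premrna_override)),
              all(premrna_override$fraction >= 0),
              all(premrna_override$fraction < 1))
  }

  if (is.null(months_since_event)) {
    months_since_event <- seq(3, 15, length.out = group_sizes[["RAC"]])
  }
  stopifnot(length(months_since_event) == group_sizes[["RAC"]],
            all(months_since_event > 0))
  stopifnot(dispersion >= 0, library_size > 0, concentration > 0,
            wbc_base > 0)

  structure(list(group_sizes = group_sizes[groups],
                 cell_types = cell_types,
                 base_proportions = base_proportions,
                 cellcount_multiplier = cellcount_multiplier,
                 regulation = regulation,
                 premrna_baseline = premrna_baseline,
                 premrna_override = premrna_override,
                 months_since_event = as.numeric(months_since_event),
                 dispersion = dispersion,
                 library_size = library_size,
                 concentration = concentration,
                 wbc_base = wbc_base,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Baseline leukocyte composition of whole blood
#'
#' Typical cell-number proportions in adult peripheral blood:
#' neutrophil-dominated, with CD4 T cells the largest lymphocyte subset and
#' classical monocytes the dominant monocyte subset.
#' @return Named numeric vector summing to 1.
#' @export
default_blood_proportions <- function() {
  c(CD4T = 0.15, CD8T = 0.08, B = 0.04, NK = 0.03,
    MONO_CLASSICAL = 0.06, MONO_INTERMEDIATE = 0.01,
    MONO_NONCLASSICAL = 0.01, NEUTROPHIL = 0.62)
}

#' Default marker layout used by the acute-rupture scenario
#'
#' Enough planted markers per cell type to cover the L and MN gene sets plus
#' spare markers for attribution analyses.
#' @return Named integer vector of marker counts per cell type.
#' @export
default_marker_config <- function() {
  c(CD4T = 12L, CD8T = 10L, B = 8L, NK = 8L,
    MONO_CLASSICAL = 12L, MONO_INTERMEDIATE = 6L, MONO_NONCLASSICAL = 6L,
    NEUTROPHIL = 14L)
}

#' The canonical acute-rupture recovery scenario
#'
#' Encodes the planted truth the analysis stages are expected to recover
#' from a simulated cohort:
#' * CD4 T-cell count reduced 1.5-fold and CD8 count reduced 1.3-fold in
#'   the acute group (RAA), mirroring post-rupture lymphopenia;
#' * classical and intermediate monocyte counts increased 1.3-fold in RAA;
#' * per-cell transcriptional upregulation (x2.5) of the MN gene-set
#'   transcripts in the myeloid compartment of RAA, so that monocyte marker
#'   expression rises well beyond the count change (active regulation);
#' * a block of broadly downregulated transcripts (x0.5 in every cell type)
#'   carrying an elevated pre-mRNA fraction (0.4 vs baseline 0.1) in RAA,
#'   and a block of upregulated transcripts (x2.0), both drawn
#'   preferentially from protein-coding biotypes;
#' * chronic-phase (RAC) multipliers identically 1: the chronic group is
#'   indistinguishable from controls.
#'
#' @param seed Integer seed (controls months-since-event draws and the
#'   choice of regulated transcript blocks).
#' @param annotation A `transcript_annotation` holding the planted markers;
#'   defaults to [generate_annotation()] with [default_marker_config()] and
#'   2000 transcripts.
#' @param n_regulated Number of transcripts in each planted up/down block.
#' @return A `cohort_design` with attributes `up_set` and `down_set`
#'   (transcript ids of the planted regulation blocks).
#' @export
default_paper_scenario <- function(seed = 1L, annotation = NULL,
                                   n_regulated = 40L) {
  if (is.null(annotation)) {
    annotation <- generate_annotation(2000L,
                                      marker_config = default_marker_config(),
                                      seed = seed)
  }
  validate_annotation(annotation)
  cell_types <- blood_cell_types()
  groups <- c("RAA", "RAC", "C")

  cm <- matrix(1, 3, length(cell_types),
               dimnames = list(groups, cell_types))
  cm["RAA", "CD4T"] <- 1 / 1.5
  cm["RAA", "CD8T"] <- 1 / 1.3
  cm["RAA", "MONO_CLASSICAL"] <- 1.3
  cm["RAA", "MONO_INTERMEDIATE"] <- 1.3

  mn_markers <- c(head(marker_transcripts(annotation, "MONO_CLASSICAL"), 8L),
                  head(marker_transcripts(annotation, "NEUTROPHIL"), 8L))
  myeloid <- c("MONO_CLASSICAL", "MONO_INTERMEDIATE", "MONO_NONCLASSICAL",
               "NEUTROPHIL")
  reg_mn <- expand.grid(cell_type = myeloid, transcript_id = mn_markers,
                        stringsAsFactors = FALSE)
  reg_mn$group <- "RAA"
  reg_mn$multiplier <- 2.5

  with_seed(seed + 101L, {
    # regulated blocks drawn preferentially from protein-coding transcripts
    free <- which(is.na(annotation$marker_of))
    w <- ifelse(annotation$biotype[free] == "protein_coding", 2.6, 1)
    picked <- sample(free, 2L * n_regulated, prob = w)
    down_set <- annotation$transcript_id[picked[seq_len(n_regulated)]]
    up_set <- annotation$transcript_id[picked[n_regulated + seq_len(n_regulated)]]
    months <- sort(runif(20L, 3, 15))
  })

  reg_down <- expand.grid(cell_type = cell_types, transcript_id = down_set,
                          stringsAsFactors = FALSE)
  reg_down$group <- "RAA"
  reg_down$multiplier <- 0.5
  reg_up <- expand.grid(cell_type = cell_types, transcript_id = up_set,
                        stringsAsFactors = FALSE)
  reg_up$group <- "RAA"
  reg_up$multiplier <- 2.0

  regulation <- rbind(reg_mn, reg_down, reg_up)[
    , c("group", "cell_type", "transcript_id", "multiplier")]

  premrna_override <- data.frame(group = "RAA", transcript_id = down_set,
                                 fraction = 0.4, stringsAsFactors = FALSE)

  design <- cohort_design(cellcount_multiplier = cm,
                          regulation = regulation,
                          premrna_override = premrna_override,
                          months_since_event = months,
                          seed = seed)
  attr(design, "up_set") <- up_set
  attr(design, "down_set") <- down_set
  design
}
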