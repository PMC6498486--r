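#' Cell-count fold between groups
#'
#' Ratio of the per-group summary (default: median, matching how clinical
#' counts are usually reported) of absolute cell counts for one population.
#'
#' @param cellcounts Cell-count table (`data.frame` with `group` and one
#'   column per population, cells/uL).
#' @param population Column name, e.g. `"cd4"` or `"monocytes"`.
#' @param group_a,group_b Group labels (fold is a over b).
#' @param summary Summary function (default [median]).
#' @return Positive scalar fold.
#' @export
count_fold <- function(cellcounts, population, group_a, group_b,
                       summary = median) {
  stopifnot(population %in% names(cellcounts))
  a <- cellcounts[[population]][cellcounts$group == group_a]
  b <- cellcounts[[population]][cellcounts$group == group_b]
  if (!length(a) || !length(b)) stop("empty group")
  sb <- summary(b)
  if (sb == 0) stop("zero summary count in denominator group")
  summary(a) / sb
}

#' Marker-set expression folds
#'
#' Linear fold of group-mean FPKM for each marker transcript of a cell
#' population, with the geometric mean (log-symmetric aggregate) and the
#' min-max envelope across markers.
#'
#' @param fpkm An `expr_matrix` with unit `FPKM`.
#' @param markers Transcript ids of the population's marker set.
#' @param group_a,group_b Group labels (fold is a over b).
#' @param pseudocount Pseudocount added to group means (default 0.1, the
#'   detection floor, as in [fold_changes()]).
#' @return List of class `marker_fold`: `folds` (named per-marker vector),
#'   `geomean`, `range` (min-max envelope).
#' @export
marker_fold <- function(fpkm, markers, group_a, group_b, pseudocount = 0.1) {
  if (inherits(fpkm, "expr_matrix")) stop_unless_unit(fpkm, "FPKM")
  if (!length(markers)) stop("empty marker set")
  x <- expr_values(fpkm)
  missing <- setdiff(markers, rownames(x))
  if (length(missing)) stop("marker absent from matrix, e.g. ", missing[1])
  g <- expr_groups(fpkm)
  ma <- rowMeans(x[markers, g == group_a, drop = FALSE])
  mb <- rowMeans(x[markers, g == group_b, drop = FALSE])
  folds <- (ma + pseudocount) / (mb + pseudocount)
  structure(list(folds = folds, geomean = geometric_mean(folds),
                 range = range(folds)),
            class = "marker_fold")
}

#' Attribute an expression shift to composition or regulation
#'
#' Compares the cell-count fold with the marker-set expression fold on the
#' log2 scale: `discordance = |log2(geomean expression fold) - log2(count
#' fold)|`. When the two agree within `tau` log2 units the shift is
#' explained by the cell-number change (`composition_driven`). When the
#' expression fold overshoots the count fold in the same direction by more
#' than `tau`, per-cell transcription must have changed
#' (`actively_regulated`). Conflicting directions (or an expression fold
#' smaller than the count change beyond `tau`) are `indeterminate`.
#'
#' @param count_fold Positive scalar from [count_fold()].
#' @param marker_fold A `marker_fold` object (or positive scalar geomean).
#' @param tau Discordance threshold in log2 units (default 0.5).
#' @param population Optional population label carried into the result.
#' @return List of class `attribution_verdict`: `population`, `count_fold`,
#'   `expression_fold` (geomean), `marker_folds`, `discordance`, `verdict`.
#' @export
attribute <- function(count_fold, marker_fold, tau = 0.5,
                      population = NA_character_) {
  ef <- if (inherits(marker_fold, "marker_fold")) marker_fold$geomean
        else marker_fold
  stopifnot(count_fold > 0, ef > 0, tau >= 0)
  lc <- log2(count_fold)
  le <- log2(ef)
  discordance <- abs(le - lc)
  verdict <- if (discordance <= tau) {
    "composition_driven"
  } else if (sign(le) == sign(lc) && abs(le) > abs(lc)) {
    "actively_regulated"
  } else {
    "indeterminate"
  }
  structure(list(population = population,
                 count_fold = count_fold,
                 expression_fold = ef,
                 marker_folds = if (inherits(marker_fold, "marker_fold"))
                   marker_fold$folds else NULL,
                 discordance = discordance,
                 verdict = verdict,
                 tau = tau),
            class = "attribution_verdict")
}

#' @export
print.attribution_verdict <- function(x, ...) {
  cat(sprintf("%s: count fold %.3f, expression fold %.3f, discordance %.3f log2 -> %s\n",
              x$population %||% "population", x$count_fold,
              x$expression_fold, x$discordance, x$verdict))
  invisible(x)
}

#' Attribution table for several populations
#'
#' Runs [count_fold()], [marker_fold()] and [attribute()] for each entry of
#' a population map and returns one row per population.
#'
#' @param fpkm An `expr_matrix` with unit `FPKM`.
#' @param cellcounts Cell-count table.
#' @param populations Named list: each element a list with `count_column`
#'   and `markers` (transcript ids).
#' @param group_a,group_b Contrast (default acute vs control).
#' @param tau,pseudocount See [attribute()] and [marker_fold()].
#' @return `data.frame(population, count_fold, expression_fold, fold_min,
#'   fold_max, discordance, verdict)`.
#' @export
attribution_table <- function(fpkm, cellcounts, populations,
                              group_a = "RAA", group_b = "C",
                              tau = 0.5, pseudocount = 0.1) {
  do.call(rbind, lapply(names(populations), function(pop) {
    spec <- populations[[pop]]
    cf <- count_fold(cellcounts, spec$count_column, group_a, group_b)
    mf <- marker_fold(fpkm, spec$markers, group_a, group_b, pseudocount)
    v <- attribute(cf, mf, tau = tau, population = pop)
    data.frame(population = pop, count_fold = cf,
               expression_fold = mf$geomean,
               fold_min = mf$range[1], fold_max = mf$range[2],
               discordance = v$discordance, verdict = v$verdict,
               stringsAsFactors = FALSE)
  }))
}
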