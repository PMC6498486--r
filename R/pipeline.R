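#' Default pipeline configuration
#'
#' All tunables of the end-to-end run in one list: simulation size and
#' seed, detection/FDR/fold thresholds, time-course thresholds, gene-set
#' pseudocounts and the attribution discordance threshold. Values can be
#' overridden via a YAML file ([load_run_config()]) or by name.
#'
#' @param seed Global seed; every stochastic stage derives its stream from
#'   it.
#' @param outdir Output directory.
#' @param ... Named overrides of any default entry.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, outdir = tempfile("bloodshift_"),
                               ...) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    n_transcripts = 2000L,
    detection_threshold = 0.1,
    basal_threshold = 0.5,
    fdr_threshold = 1e-5,
    fold_threshold = 2,
    fold_pseudocount = 0.1,
    R_threshold = 0.7,
    p_threshold = 0.01,
    ei_pseudocount = 1,
    tau = 0.5,
    write_gtf = FALSE,
    stages = c("simulate", "quantify", "de", "lmn", "structure", "attribute")
  )
  override <- list(...)
  cfg <- modifyList(cfg, override)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$detection_threshold >= 0,
            cfg$fdr_threshold > 0, cfg$fdr_threshold < 1,
            cfg$fold_threshold >= 1,
            cfg$R_threshold > 0, cfg$R_threshold <= 1,
            cfg$p_threshold > 0, cfg$p_threshold <= 1,
            cfg$ei_pseudocount > 0, cfg$tau >= 0,
            cfg$n_transcripts >= 100)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_run_config()]
#'   entries.
#' @param ... Further named overrides (e.g. from CLI flags), taking
#'   precedence over the file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  do.call(default_run_config,
          modifyList(cfg, list(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, quantify, de
#' (ANOVA + folds + patterns), lmn, structure (biotypes + exon/intron),
#' attribute — writing each stage's tables under `cfg$outdir` and a JSON
#' run manifest (seed, thresholds, per-file MD5 checksums). Stages that
#' depend on a disabled stage fail fast with a dependency error. The run is
#' deterministic for a fixed config and seed.
#'
#' @param cfg A `run_config` (see [default_run_config()]).
#' @return The manifest, invisibly (list; also at
#'   `<outdir>/manifest.json`).
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  outputs <- character()
  state <- new.env(parent = emptyenv())

  need <- function(what, stage, from) {
    if (!exists(what, state)) {
      stop("stage '", stage, "' requires output of disabled stage '", from,
           "'", call. = FALSE)
    }
    get(what, state)
  }
  emit <- function(name) outputs <<- c(outputs, name)

  if ("simulate" %in% stages) {
    scen <- simulate_scenario(cfg$seed, cfg$n_transcripts)
    assign("scen", scen, state)
    write_expr_matrix(scen$cohort$exonic,
                      file.path(cfg$outdir, "exonic_counts.tsv"))
    write_expr_matrix(scen$cohort$intronic,
                      file.path(cfg$outdir, "intronic_counts.tsv"))
    write_cellcounts(scen$cohort$cellcounts,
                     file.path(cfg$outdir, "cellcounts.tsv"))
    write_genesets(scen$genesets, file.path(cfg$outdir, "genesets.tsv"))
    write.table(scen$cohort$exonic$samples,
                file.path(cfg$outdir, "samples.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(expected_folds = scen$cohort$truth$expected_folds,
           up_set = scen$up_set, down_set = scen$down_set),
      file.path(cfg$outdir, "truth.json"), digits = NA)
    if (isTRUE(cfg$write_gtf)) {
      write_annotation_gtf(scen$annotation,
                           file.path(cfg$outdir, "annotation.gtf"))
      emit("annotation.gtf")
    }
    emit("exonic_counts.tsv"); emit("intronic_counts.tsv")
    emit("cellcounts.tsv"); emit("genesets.tsv"); emit("samples.tsv")
    emit("truth.json")
  }

  if ("quantify" %in% stages) {
    scen <- need("scen", "quantify", "simulate")
    fpkm <- compute_fpkm(scen$cohort$exonic, scen$annotation)
    detected <- detection_filter(fpkm, cfg$detection_threshold, ">=")
    basal <- detection_filter(fpkm, cfg$basal_threshold, ">")
    assign("fpkm", fpkm, state)
    assign("detected", detected, state)
    assign("basal", basal, state)
    write_expr_matrix(fpkm, file.path(cfg$outdir, "fpkm.tsv"))
    emit("fpkm.tsv")
  }

  if ("de" %in% stages) {
    scen <- need("scen", "de", "simulate")
    need("fpkm", "de", "quantify")
    de <- diffexpr_table(scen$cohort$exonic, scen$annotation,
                         q_threshold = cfg$fdr_threshold,
                         pseudocount = cfg$fold_pseudocount)
    assign("de", de, state)
    write.table(de, file.path(cfg$outdir, "diffexpr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    pat <- attr(de, "patterns")
    if (!is.null(pat)) {
      writeLines(pat$leaf_order, file.path(cfg$outdir, "leaf_order.txt"))
      emit("leaf_order.txt")
    }
    tc <- timecourse_screen(get("fpkm", state),
                            R_threshold = cfg$R_threshold,
                            p_threshold = cfg$p_threshold)
    write.table(tc[tc$hit, , drop = FALSE],
                file.path(cfg$outdir, "timecourse_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("diffexpr.tsv"); emit("timecourse_hits.tsv")
  }

  if ("lmn" %in% stages) {
    scen <- need("scen", "lmn", "simulate")
    fpkm <- need("fpkm", "lmn", "quantify")
    lmn <- lmn_index(fpkm, scen$genesets)
    assign("lmn", lmn, state)
    write.table(data.frame(sample_id = names(lmn$values),
                           lmn = lmn$values, row.names = NULL),
                file.path(cfg$outdir, "lmn_values.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(group_summary = lmn$group_summary,
                              comparisons = lmn$comparisons),
                         file.path(cfg$outdir, "lmn_summary.json"),
                         digits = NA)
    emit("lmn_values.tsv"); emit("lmn_summary.json")
  }

  if ("structure" %in% stages) {
    scen <- need("scen", "structure", "simulate")
    de <- need("de", "structure", "de")
    basal <- need("basal", "structure", "quantify")
    sig <- de$transcript_id[de$significant]
    profiles <- list(basal = biotype_profile(basal, scen$annotation))
    if (length(sig)) {
      profiles$regulated <- biotype_profile(sig, scen$annotation)
    }
    up <- de$transcript_id[!is.na(de$pattern) & de$pattern == "B"]
    down <- de$transcript_id[!is.na(de$pattern) & de$pattern == "A"]
    ei <- NULL
    if (length(up) && length(down)) {
      raa <- scen$cohort$exonic$samples$group == "RAA"
      ei <- exon_intron_score(scen$cohort$exonic, scen$cohort$intronic,
                              up, down, pseudocount = cfg$ei_pseudocount,
                              samples = which(raa))
      write.table(ei$scores, file.path(cfg$outdir, "exon_intron_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      emit("exon_intron_scores.tsv")
    }
    assign("structure", list(profiles = profiles, ei = ei), state)
    jsonlite::write_json(
      list(profiles = profiles,
           exon_intron = if (!is.null(ei))
             list(median_up = ei$median_up, median_down = ei$median_down,
                  p = ei$p)),
      file.path(cfg$outdir, "structure_summary.json"), digits = NA)
    emit("structure_summary.json")
  }

  if ("attribute" %in% stages) {
    scen <- need("scen", "attribute", "simulate")
    fpkm <- need("fpkm", "attribute", "quantify")
    pops <- list(
      CD4 = list(count_column = "cd4", markers = scen$marker_sets$CD4),
      MONOCYTES = list(count_column = "monocytes",
                       markers = scen$marker_sets$MN)
    )
    att <- attribution_table(fpkm, scen$cohort$cellcounts, pops,
                             tau = cfg$tau,
                             pseudocount = cfg$fold_pseudocount)
    assign("attribution", att, state)
    write.table(att, file.path(cfg$outdir, "attribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("attribution.tsv")
  }

  files <- file.path(cfg$outdir, outputs)
  manifest <- list(
    package = "bloodshift",
    version = as.character(utils::packageVersion("bloodshift")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("outdir", "stages"))],
    stages = stages,
    checksums = as.list(setNames(unname(tools::md5sum(files)), outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
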