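# Workflow orchestration: wires the module stages into the two end-to-end
# analyses (split-site screening; rearrangement calling) with config
# validation and a reproducibility manifest.

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a config file path")
  config
}

.check_config_keys <- function(config, allowed) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

.write_manifest <- function(outdir, workflow, config) {
  manifest <- list(workflow = workflow,
                   package = "magtaq",
                   version = as.character(utils::packageVersion("magtaq")),
                   config = config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Run the split-site screening workflow
#'
#' Collects metrics for every variant model in a directory (files named
#' `<variant_id>.pdb` or `.cif`), joins the external free-energy table,
#' computes the buried-area vs free-energy Pearson correlation, and ranks
#' variants against the baseline. Writes `screen_table.tsv`,
#' `correlation.json`, `winner.txt` and `manifest.json` into the output
#' directory. Config keys: `model_dir`, `dg_table`, `chains_protein`,
#' `chains_dna`, `baseline_id`, `outdir`, and optional `split_positions`
#' (named list), `probe_radius`, `n_sphere_points`.
#'
#' @param config list or path to a JSON/YAML config file.
#' @return list with `table`, `correlation`, `ranking` (invisibly).
#' @export
run_split_screen <- function(config) {
  config <- .read_config(config)
  .check_config_keys(config, c("model_dir", "dg_table", "chains_protein",
                               "chains_dna", "baseline_id", "outdir",
                               "split_positions", "probe_radius",
                               "n_sphere_points"))
  for (key in c("model_dir", "dg_table", "chains_protein", "chains_dna",
                "baseline_id", "outdir")) {
    if (is.null(config[[key]])) stop("config key '", key, "' is required")
  }
  if (!dir.exists(config$model_dir)) {
    stop("model directory not found: ", config$model_dir)
  }
  files <- list.files(config$model_dir, pattern = "\\.(pdb|cif)$",
                      full.names = TRUE)
  if (!length(files)) stop("no model files in ", config$model_dir)
  ids <- sub("\\.(pdb|cif)$", "", basename(files))
  model_paths <- setNames(files, ids)
  params <- sasa_params(
    probe_radius = if (is.null(config$probe_radius)) 1.4 else config$probe_radius,
    n_sphere_points = if (is.null(config$n_sphere_points)) 960
    else config$n_sphere_points)
  sp <- if (!is.null(config$split_positions)) {
    unlist(config$split_positions)
  } else {
    NULL
  }
  tab <- .stage("collect_metrics", collect_metrics(
    model_paths, config$dg_table,
    chains_protein = unlist(config$chains_protein),
    chains_dna = unlist(config$chains_dna),
    baseline_id = config$baseline_id, split_positions = sp, params = params))
  corr <- .stage("pearson", pearson(tab$buried_area, tab$delta_g))
  ranking <- .stage("rank_variants", rank_variants(tab))

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- tab[tab$variant_id == config$baseline_id, ]
  tab_out <- tab
  tab_out$dominates_baseline <- tab$buried_area > base$buried_area &
    tab$delta_g < base$delta_g & tab$variant_id != config$baseline_id
  write.table(tab_out, file.path(outdir, "screen_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(r = corr$r, p_two_sided = corr$p_two_sided,
                            n = corr$n),
                       file.path(outdir, "correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(if (ranking$no_improvement) "no improvement" else ranking$winner,
             file.path(outdir, "winner.txt"))
  .write_manifest(outdir, "split-screen", config)
  message("winner: ",
          if (ranking$no_improvement) "no improvement" else ranking$winner)
  invisible(list(table = tab_out, correlation = corr, ranking = ranking))
}

#' Run the rearrangement-calling workflow for one isolate
#'
#' Genotypes the marker track, calls LOH (SGC/BIR) and aneuploidy,
#' classifies junctions (NAHR/NMTL) with recognition-motif annotation,
#' subtracts control events if given, and writes the per-isolate report.
#' Outputs in `outdir`: `loh_segments.tsv`, `loh.bed`, `cnv.bed`,
#' `junctions.bedpe`, `report.json`, `manifest.json`.
#'
#' Config keys: `isolate_id`, `markers` (path or data.frame),
#' `chrom_sizes` (path or named vector), `outdir`; optional `junctions`,
#' `repeats`, `control_loh`, `control_junctions`, `motif`, and the
#' thresholds `min_depth`, `het_band`, `hom_band`, `min_run`,
#' `max_discordant_frac`, `end_margin`, `gain_ratio`, `loss_ratio`.
#'
#' @param config list or path to a JSON/YAML config file.
#' @return the `isolate_report` (invisibly).
#' @export
run_rearrangement_analysis <- function(config) {
  config <- .read_config(config)
  .check_config_keys(config, c("isolate_id", "markers", "junctions",
                               "chrom_sizes", "repeats", "control_loh",
                               "control_junctions", "motif", "outdir",
                               "min_depth", "het_band", "hom_band",
                               "min_run", "max_discordant_frac",
                               "end_margin", "gain_ratio", "loss_ratio"))
  for (key in c("isolate_id", "markers", "chrom_sizes", "outdir")) {
    if (is.null(config[[key]])) stop("config key '", key, "' is required")
  }
  p <- function(key, default) {
    if (is.null(config[[key]])) default else config[[key]]
  }
  track <- .stage("read_markers", {
    if (is.character(config$markers)) read_marker_table(config$markers)
    else .validate_marker_track(config$markers)
  })
  chrom_sizes <- if (is.character(config$chrom_sizes)) {
    read_chrom_sizes(config$chrom_sizes)
  } else {
    unlist(config$chrom_sizes)
  }
  junctions <- if (!is.null(config$junctions)) {
    if (is.character(config$junctions)) read_junction_table(config$junctions)
    else config$junctions
  } else {
    NULL
  }
  repeats <- if (!is.null(config$repeats)) {
    if (is.character(config$repeats)) read_repeats_bed(config$repeats)
    else config$repeats
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  motif <- p("motif", "GATC")

  track <- .stage("genotype_markers", genotype_markers(
    track, min_depth = p("min_depth", 10),
    het_band = unlist(p("het_band", c(0.25, 0.75))),
    hom_band = p("hom_band", 0.10)))
  loh <- .stage("call_loh", call_loh(
    track, chrom_sizes, min_run = p("min_run", 5),
    max_discordant_frac = p("max_discordant_frac", 0.1),
    end_margin = p("end_margin", 20000)))
  cnv <- .stage("call_aneuploidy", call_aneuploidy(
    track, chrom_sizes, gain_ratio = p("gain_ratio", 1.25),
    loss_ratio = p("loss_ratio", 0.75)))
  jcls <- if (!is.null(junctions) && nrow(junctions)) {
    j <- .stage("classify_translocations",
                classify_translocations(junctions, repeats))
    .stage("annotate_junction_motifs", annotate_junction_motifs(j, motif))
  } else {
    NULL
  }
  if (!is.null(config$control_loh)) {
    loh <- .stage("subtract_control", subtract_control(loh, config$control_loh))
  }
  if (!is.null(jcls) && !is.null(config$control_junctions)) {
    jcls <- .stage("subtract_control",
                   subtract_control(jcls, config$control_junctions))
  }
  report <- .stage("build_isolate_report", build_isolate_report(
    config$isolate_id, loh, cnv, jcls, chrom_sizes, track = track))

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(loh, file.path(outdir, "loh_segments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_segments_bed(loh, file.path(outdir, "loh.bed"))
  write_segments_bed(cnv, file.path(outdir, "cnv.bed"))
  write_junctions_bedpe(if (is.null(jcls)) data.frame(
    chrom_a = character(), pos_a = numeric(), strand_a = character(),
    chrom_b = character(), pos_b = numeric(), strand_b = character())
    else jcls,
    file.path(outdir, "junctions.bedpe"))
  write_isolate_report_json(report, file.path(outdir, "report.json"))
  .write_manifest(outdir, "call-rearrangements",
                  config[!vapply(config, is.data.frame, logical(1))])
  invisible(report)
}
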