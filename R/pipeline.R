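#' Pipeline run configuration
#'
#' Defaults reproduce the standard operating point: 500-kb windows, mapping
#' quality 20, secondary/supplementary reads dropped. Accepts either an
#' alignment file (sorted/indexed BAM, or SAM) or a fixed-step WIG of
#' precomputed bin counts.
#'
#' @param input Path to the input file.
#' @param input_type `"alignment"` or `"wig"` (guessed from the extension by
#'   default).
#' @param build Build name (`"hg38"`/`"hg19"`) or a `genome_build`.
#' @param bin_size Bin width in bp (default 500 000).
#' @param min_mapq Mapping-quality floor for alignment input (default 20).
#' @param panel Character vector of WIG paths for the panel of normals
#'   (optional).
#' @param baseline_path Deletion-baseline JSON (default: the packaged
#'   synthetic baseline).
#' @param gc_track,map_track Optional per-bin GC / mappability track paths;
#'   WIG input without a GC track cannot be GC-corrected, so one of the two
#'   sources must provide GC.
#' @param tf_min,tf_max,tf_step Tumor-fraction scan bounds.
#' @param arm_call_threshold,mappability_threshold,amplification_state
#'   Calling thresholds (see [marker_config()], [correction_config()]).
#' @param centromere_padding Exclusion padding in bins (default 1).
#' @param context_path Optional clinical-context YAML/JSON.
#' @param out_dir Output directory.
#' @param sample_id Sample label (default: input file name).
#' @param seed Seed recorded in the config (the pipeline itself is
#'   deterministic).
#' @param timestamp Embed a timestamp in the report footer (default `FALSE`
#'   for reproducible output).
#' @param resume Reuse cached intermediates in `out_dir` when their config
#'   digest matches (default `TRUE`).
#' @return Named list of class `run_config` with the config digest in
#'   `$digest`.
#' @export
run_config <- function(input, input_type = NULL, build = "hg38",
                       bin_size = 5e5, min_mapq = 20, panel = character(),
                       baseline_path = NULL, gc_track = NULL, map_track = NULL,
                       tf_min = 0.05, tf_max = 1, tf_step = 0.01,
                       arm_call_threshold = 0.8, mappability_threshold = 0.75,
                       amplification_state = 5, centromere_padding = 1,
                       context_path = NULL, out_dir = "gliomacnv_out",
                       sample_id = NULL, seed = 1L, timestamp = FALSE,
                       resume = TRUE) {
  input_type <- input_type %||%
    (if (grepl("\\.(bam|sam)$", input, ignore.case = TRUE)) "alignment" else "wig")
  stopifnot(input_type %in% c("alignment", "wig"))
  cfg <- list(input = input, input_type = input_type,
              build = if (inherits(build, "genome_build")) build$name else build,
              bin_size = bin_size, min_mapq = min_mapq, panel = panel,
              baseline_path = baseline_path, gc_track = gc_track,
              map_track = map_track, tf_min = tf_min, tf_max = tf_max,
              tf_step = tf_step, arm_call_threshold = arm_call_threshold,
              mappability_threshold = mappability_threshold,
              amplification_state = amplification_state,
              centromere_padding = centromere_padding,
              context_path = context_path, out_dir = out_dir,
              sample_id = sample_id %||% basename(input), seed = as.integer(seed),
              timestamp = timestamp, resume = resume)
  if (inherits(build, "genome_build")) attr(cfg, "build_object") <- build
  cfg$digest <- config_digest(cfg)
  structure(cfg, class = "run_config")
}

config_digest <- function(cfg) {
  cfg$digest <- NULL
  cfg$out_dir <- NULL
  cfg$resume <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a run configuration from YAML/JSON with flag overrides
#'
#' @param path YAML (or JSON) file whose keys match [run_config()]
#'   arguments.
#' @param overrides Named list of values that win over the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, overrides)
  do.call(run_config, vals)
}

stage_log <- function(stage, ...) {
  message(sprintf("[gliomacnv] %-18s %s", stage, paste0(...)))
}

#' Run the full copy-number marker pipeline
#'
#' Executes count/read -> GC annotation -> bias correction -> optional
#' panel normalization -> HMM segmentation with tumor-fraction estimation ->
#' marker calls (with the deletion baseline) -> classification -> report,
#' writing every export into `config$out_dir`: `counts.wig`,
#' `corrected.tsv`, `segments.seg`, `segments.bed`, `markers.tsv`,
#' `markers.json`, `classification.json`, `plot.svg`, `plot.png`,
#' `report.html`, plus `run_config.json` and `run_digest.txt`. A directory
#' already holding outputs from a different configuration is refused. Stage
#' failures leave a `FAILED` marker file naming the stage.
#'
#' @param config A [run_config()].
#' @return A [report_bundle()], invisibly, with the segmentation in
#'   `attr(, "segmentation")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  digest_file <- file.path(out, "run_digest.txt")
  if (file.exists(digest_file)) {
    prev <- readLines(digest_file, n = 1)
    if (!identical(prev, config$digest)) {
      stop("output directory ", out, " holds results for a different ",
           "configuration (digest ", prev, " != ", config$digest,
           "); use a fresh directory")
    }
  }
  failed_file <- file.path(out, "FAILED")
  if (file.exists(failed_file)) unlink(failed_file)
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste("stage:", stage, "-", conditionMessage(e)), failed_file)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }

  bundle <- tryCatch({
    build <- attr(config, "build_object", exact = TRUE) %||% genome_build(config$build)
    grid <- bin_grid(build, config$bin_size)
    mask <- exclusion_mask(grid, config$centromere_padding)
    writeLines(config$digest, digest_file)
    jsonlite::write_json(unclass(config), file.path(out, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)

    stage <- "read counting"
    counts_wig <- file.path(out, "counts.wig")
    if (config$resume && file.exists(counts_wig)) {
      stage_log(stage, "reusing cached ", counts_wig)
      counts <- read_wig(counts_wig, grid, sample_id = config$sample_id)
    } else if (config$input_type == "alignment") {
      counts <- count_reads_in_bins(config$input, grid,
                                    min_mapq = config$min_mapq,
                                    sample_id = config$sample_id)
      fs <- attr(counts, "filter_stats")
      stage_log(stage, sprintf("%d records scanned, %d retained (%d unmapped, %d secondary/supplementary, %d low MAPQ, %d off-grid)",
                               fs$scanned, fs$retained, fs$unmapped,
                               fs$secondary_supplementary, fs$low_mapq,
                               fs$off_grid_contig))
      write_wig(counts, counts_wig)
    } else {
      counts <- read_wig(config$input, grid, sample_id = config$sample_id)
      stage_log(stage, sprintf("WIG input: %d bins populated",
                               sum(!is.na(counts$count))))
      write_wig(counts, counts_wig)
    }

    stage <- "annotation"
    counts <- annotate_gc_mappability(counts, gc_track = config$gc_track,
                                      map_track = config$map_track)
    stage_log(stage, sprintf("GC present for %d bins", sum(!is.na(counts$gc))))

    stage <- "bias correction"
    ccfg <- correction_config(mappability_threshold = config$mappability_threshold)
    profile <- correct_bias(counts, mask = mask, config = ccfg)
    md <- attr(profile, "correction_metadata")
    stage_log(stage, sprintf("%d valid bins; dropped: %s", sum(profile$valid),
                             paste(names(md$bins_dropped_by_reason),
                                   md$bins_dropped_by_reason,
                                   sep = "=", collapse = " ")))

    stage <- "panel normalization"
    if (length(config$panel) > 0) {
      panel <- lapply(config$panel, function(p) {
        correct_bias(annotate_gc_mappability(read_wig(p, grid),
                                             gc_track = config$gc_track,
                                             map_track = config$map_track),
                     mask = mask, config = ccfg)
      })
      profile <- normalize_against_panel(profile, panel)
      stage_log(stage, length(panel), " normals applied")
    } else {
      stage_log(stage, "no panel supplied; skipped")
    }
    write_profile_tsv(profile, file.path(out, "corrected.tsv"))

    stage <- "segmentation"
    hcfg <- hmm_config(tf_grid = seq(config$tf_min, config$tf_max,
                                     by = config$tf_step),
                       seed = config$seed)
    seg <- estimate_tumor_fraction(profile, hcfg)
    stage_log(stage, sprintf("tumor fraction %.2f%s, %d segments",
                             seg$tumor_fraction,
                             if (seg$non_informative) " (non-informative)" else "",
                             nrow(seg$segments)))
    write_seg(seg, file.path(out, "segments.seg"))
    write_segments_bed(seg, file.path(out, "segments.bed"))

    stage <- "marker calls"
    baseline <- if (is.null(config$baseline_path)) default_baseline()
      else read_baseline(config$baseline_path)
    mcfg <- marker_config(arm_call_threshold = config$arm_call_threshold,
                          amplification_state = config$amplification_state)
    table <- call_markers(seg, baseline = baseline, config = mcfg)
    write_marker_table(table, file.path(out, "markers.tsv"), "tsv")
    write_marker_table(table, file.path(out, "markers.json"), "json")
    stage_log(stage, paste(table$marker_id, table$status, sep = ":",
                           collapse = " "))

    stage <- "classification"
    context <- if (is.null(config$context_path)) clinical_context()
      else read_clinical_context(config$context_path)
    cls <- classify_glioma(table, context)
    write_classification(cls, file.path(out, "classification.json"))
    stage_log(stage, cls$suggestion, " / ", cls$grade_hint)

    stage <- "report"
    render_genome_plot(seg, table, svg_path = file.path(out, "plot.svg"),
                       png_path = file.path(out, "plot.png"))
    header <- c(list(sample = config$sample_id, build = build$name,
                     bin_size = format(config$bin_size, scientific = FALSE),
                     tumor_fraction = sprintf("%.2f%s", seg$tumor_fraction,
                       if (seg$non_informative) " (non-informative)" else ""),
                     idh_status = context$idh_status),
                attr(context, "extra") %||% list())
    bundle <- report_bundle(
      sample_header = header, plot_png = file.path(out, "plot.png"),
      marker_table = table, classification = cls,
      run_config_digest = config$digest,
      timestamp = if (isTRUE(config$timestamp))
        format(Sys.time(), "%Y-%m-%d %H:%M:%S") else FALSE)
    render_html_report(bundle, file.path(out, "report.html"))
    stage_log(stage, "written to ", file.path(out, "report.html"))
    attr(bundle, "segmentation") <- seg
    bundle
  }, error = on_fail)

  invisible(bundle)
}
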