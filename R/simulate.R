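#' Specify a synthetic low-pass CNV sample
#'
#' Describes a bin-count sample with known truth: sequencing depth per bin,
#' negative-binomial overdispersion, tumor fraction, planted copy-number
#' events and a smooth GC bias. Per-bin expected counts are
#' `depth_lambda * gc_bias(gc) * (t*c + 2*(1-t)) / 2`.
#'
#' @param build A `genome_build` (default hg38).
#' @param bin_size Bin width in bp.
#' @param depth_lambda Mean reads per neutral diploid bin (default 100,
#'   typical of low-pass long-read runs at 500-kb windows).
#' @param dispersion Negative-binomial size parameter (default 20; low-pass
#'   nanopore depth is overdispersed relative to Poisson). `Inf` gives
#'   Poisson noise.
#' @param tumor_fraction Tumor fraction in (0, 1].
#' @param events List of planted alterations, each either
#'   `list(marker = "<catalog id>", copy = <int>)` or
#'   `list(chrom =, start =, end =, copy =)` (tumor-cell copy number).
#' @param gc_bias Numeric polynomial coefficients `c(a0, a1, a2, ...)`
#'   evaluated at `(gc - 0.45)` and normalized to mean 1, or `"none"`.
#' @param noise `"nb"` (default) or `"none"` for noiseless expected counts.
#' @param seed Mandatory integer seed.
#' @return Named list of class `simulation_spec`.
#' @export
simulation_spec <- function(build = genome_build("hg38"), bin_size = 5e5,
                            depth_lambda = 100, dispersion = 20,
                            tumor_fraction = 1, events = list(),
                            gc_bias = "none", noise = c("nb", "none"),
                            seed) {
  if (missing(seed)) stop("simulation seed is mandatory")
  noise <- match.arg(noise)
  stopifnot(depth_lambda > 0, tumor_fraction > 0, tumor_fraction <= 1)
  for (ev in events) stopifnot(ev$copy >= 0)
  structure(list(build = build, bin_size = bin_size,
                 depth_lambda = depth_lambda, dispersion = dispersion,
                 tumor_fraction = tumor_fraction, events = events,
                 gc_bias = gc_bias, noise = noise, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Smooth deterministic GC landscape over bins: a slow genome-wide wave plus
# bin-level ripple, in [~0.35, 0.55]. GC is a property of the reference, so
# the landscape is a fixed function of the grid, identical across samples.
simulated_gc <- function(n, seed = NULL) {
  base <- 0.45 + 0.08 * sin(2 * pi * seq_len(n) / 600) +
    0.02 * sin(2 * pi * seq_len(n) / 47)
  set.seed(104729L)
  ripple <- if (n >= 5) {
    as.numeric(stats::filter(rnorm(n, 0, 0.02), rep(1 / 5, 5), circular = TRUE))
  } else {
    rnorm(n, 0, 0.01)
  }
  pmin(0.75, pmax(0.25, base + ripple))
}

true_copy_vector <- function(grid, events) {
  copy <- rep(2L, nrow(grid))
  catalog <- marker_catalog(grid_build(grid))
  for (ev in events) {
    if (!is.null(ev$marker)) {
      bins <- locate_marker_bins(grid, ev$marker, catalog = catalog)
    } else {
      sel <- grid$chrom == ev$chrom & grid$start < ev$end & grid$end > ev$start
      if (!any(sel)) stop("event region off the grid: ", ev$chrom)
      bins <- grid$bin[sel]
    }
    copy[bins] <- as.integer(ev$copy)
  }
  copy
}

status_from_copy <- function(copy) {
  if (copy >= 5) "amplification"
  else if (copy > 2) "gain"
  else if (copy == 2) "neutral"
  else if (copy == 1) "hemizygous_loss"
  else "homozygous_loss"
}

#' Simulate per-bin read counts with known truth
#'
#' @param spec A [simulation_spec()].
#' @param grid Optional precomputed [bin_grid()] for the spec's build
#'   (avoids re-tiling in tight loops).
#' @return Object of class `simulated_sample`: list with `counts` (a
#'   [bin_counts()] profile annotated with GC and unit mappability) and
#'   `truth` (list: `tumor_fraction`, `copy` per bin, `marker_status` named
#'   by catalog marker).
#' @export
simulate_bin_counts <- function(spec, grid = NULL) {
  grid <- grid %||% bin_grid(spec$build, spec$bin_size)
  n <- nrow(grid)
  gc <- simulated_gc(n, spec$seed)
  copy <- true_copy_vector(grid, spec$events)
  t <- spec$tumor_fraction

  bias <- if (identical(spec$gc_bias, "none")) rep(1, n) else {
    b <- vapply(gc - 0.45, function(x) sum(spec$gc_bias * x^(seq_along(spec$gc_bias) - 1)), 0)
    if (any(b <= 0)) stop("gc_bias polynomial must stay positive over the GC range")
    b / mean(b)
  }

  mu <- spec$depth_lambda * bias * (t * copy + 2 * (1 - t)) / 2
  if (spec$noise == "none") {
    counts <- mu
  } else {
    set.seed(spec$seed)
    counts <- if (is.finite(spec$dispersion)) {
      rnbinom(n, mu = mu, size = spec$dispersion)
    } else {
      stats::rpois(n, mu)
    }
  }

  catalog <- marker_catalog(grid_build(grid))
  marker_status <- vapply(unique(catalog$marker_id), function(id) {
    mb <- locate_marker_bins(grid, id, catalog = catalog)
    status_from_copy(round(mean(copy[mb])))
  }, "")

  structure(
    list(counts = annotate_gc_mappability(
           bin_counts(grid, counts, sample_id = sprintf("sim_seed%d", spec$seed)),
           gc_track = gc, map_track = rep(1, n)),
         truth = list(tumor_fraction = t, copy = copy,
                      marker_status = marker_status),
         spec = spec),
    class = "simulated_sample")
}

#' Simulate a corrected profile directly (log2-ratio level)
#'
#' Bypasses count-level noise: per-bin log2 ratios are the admixture
#' expectation for the planted copy states plus Gaussian noise of the given
#' standard deviation. This is the regime the segmentation emission model
#' assumes and is used to characterize tumor-fraction recovery in isolation
#' from count-level correction.
#'
#' @param grid A [bin_grid()].
#' @param tumor_fraction Tumor fraction in (0, 1].
#' @param events As in [simulation_spec()].
#' @param sd Gaussian log2-ratio noise (0 = noiseless).
#' @param seed Integer seed.
#' @param mask Optional exclusion mask; masked bins become invalid.
#' @return List with `profile` (a `cnv_profile`) and `truth`.
#' @export
simulate_profile <- function(grid, tumor_fraction, events = list(), sd = 0.1,
                             seed = 1L, mask = NULL) {
  n <- nrow(grid)
  copy <- true_copy_vector(grid, events)
  mu <- pmax(expected_log2_ratio(copy, tumor_fraction), MU_CLAMP)
  set.seed(seed)
  ratio <- mu + if (sd > 0) rnorm(n, 0, sd) else 0
  valid <- rep(TRUE, n)
  if (!is.null(mask)) valid <- valid & !mask
  list(profile = cnv_profile(grid, ifelse(valid, ratio, NA_real_), valid = valid,
                             sample_id = sprintf("simprof_seed%d", seed)),
       truth = list(tumor_fraction = tumor_fraction, copy = copy))
}

#' Simulate a matched normal/tumor pair and build an admixture series
#'
#' Generates a diploid normal and a homozygous-CDKN2A/B-deletion tumor
#' (pure, `t = 1`) from the same GC landscape and delegates to
#' [make_admixture()]; the in-silico analogue of diluting a deletion cell
#' line into a normal background.
#'
#' @param fractions Tumor fractions of the series.
#' @param seed Integer seed (normal and tumor use offset seeds).
#' @param build,bin_size,depth_lambda,dispersion,gc_bias,noise Passed to
#'   [simulation_spec()]; `noise = "none"` gives the noiseless series.
#' @param tumor_events Planted tumor events (default: homozygous CDKN2A/B
#'   deletion).
#' @param round_counts Passed to [make_admixture()].
#' @return An `admixture_set`; per-mixture truths are in
#'   `attr(, "truth")`.
#' @export
simulate_admixture_series <- function(fractions = seq(0.1, 0.9, by = 0.1),
                                      seed = 1L,
                                      build = genome_build("hg38"),
                                      bin_size = 5e5, depth_lambda = 100,
                                      dispersion = 20, gc_bias = "none",
                                      noise = c("nb", "none"),
                                      tumor_events = list(list(marker = "CDKN2AB", copy = 0)),
                                      round_counts = TRUE) {
  noise <- match.arg(noise)
  grid <- bin_grid(build, bin_size)
  normal <- simulate_bin_counts(simulation_spec(
    build = build, bin_size = bin_size, depth_lambda = depth_lambda,
    dispersion = dispersion, tumor_fraction = 1, events = list(),
    gc_bias = gc_bias, noise = noise, seed = seed), grid = grid)
  tumor <- simulate_bin_counts(simulation_spec(
    build = build, bin_size = bin_size, depth_lambda = depth_lambda,
    dispersion = dispersion, tumor_fraction = 1, events = tumor_events,
    gc_bias = gc_bias, noise = noise, seed = seed + 1L), grid = grid)

  adm <- make_admixture(normal$counts, tumor$counts, fractions = fractions,
                        seed = seed, round_counts = round_counts)
  attr(adm, "truth") <- list(fractions = fractions,
                             tumor_copy = tumor$truth$copy,
                             tumor_marker_status = tumor$truth$marker_status)
  adm
}

#' Named simulation presets for the canonical glioma scenarios
#'
#' Four genome-level scenarios at a chosen tumor fraction, with stable names
#' for CI: `neutral` (no events), `oligodendroglioma-like` (1p and 19q
#' single-copy loss), `gbm-like` (+7, -10, EGFR at 8 copies) and
#' `astro-grade4-like` (CDKN2A/B homozygous deletion over a background of
#' chr13/chr18 single-copy losses, reflecting the aneuploidy of high-grade
#' astrocytomas and anchoring tumor-fraction estimation). Presets use depth
#' 400 reads/bin and dispersion 600, i.e. per-bin log2 noise near 0.09,
#' inside the noise regime (<= 0.1) in which deletion typing is designed to
#' operate.
#'
#' @param tumor_fraction Tumor fraction of the presets (default 0.6; the
#'   scenarios are defined at 0.3 and 0.6).
#' @param seed Integer seed.
#' @param build A `genome_build`.
#' @return Named list of [simulation_spec()] objects.
#' @export
scenario_library <- function(tumor_fraction = 0.6, seed = 1L,
                             build = genome_build("hg38")) {
  base <- function(events) simulation_spec(
    build = build, depth_lambda = 400, dispersion = 600,
    tumor_fraction = tumor_fraction, events = events,
    gc_bias = c(1, 0.5, -2), seed = seed)
  list(
    "neutral" = base(list()),
    "oligodendroglioma-like" = base(list(
      list(marker = "ARM_1P", copy = 1),
      list(marker = "ARM_19Q", copy = 1))),
    "gbm-like" = base(list(
      list(marker = "CHR7", copy = 3),
      list(marker = "CHR10", copy = 1),
      list(marker = "EGFR", copy = 8))),
    "astro-grade4-like" = base(list(
      list(marker = "CDKN2AB", copy = 0),
      list(chrom = "chr13", start = 0, end = build$chrom_lengths[["chr13"]], copy = 1),
      list(chrom = "chr18", start = 0, end = build$chrom_lengths[["chr18"]], copy = 1)))
  )
}

#' Write a small synthetic SAM file
#'
#' Emits a coordinate-sorted SAM (header + primary records) for exercising
#' the bin counter; at most a few hundred records.
#'
#' @param path Output `.sam` path.
#' @param grid A [bin_grid()] supplying the reference dictionary.
#' @param reads Tibble with columns `chrom`, `pos` (1-based leftmost),
#'   `mapq`, and optional `flag` (default 0).
#' @return `path`, invisibly.
#' @export
simulate_sam <- function(path, grid, reads) {
  build <- grid_build(grid)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(build$chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       as.integer(build$chrom_lengths[[chrom]])), con)
  }
  if (!"flag" %in% names(reads)) reads$flag <- 0L
  ord <- order(match(reads$chrom, names(build$chrom_lengths)), reads$pos)
  reads <- reads[ord, ]
  for (i in seq_len(nrow(reads))) {
    writeLines(paste(sprintf("read%04d", i), reads$flag[i], reads$chrom[i],
                     as.integer(reads$pos[i]), reads$mapq[i], "50M", "*", 0, 0,
                     strrep("A", 50), "*", sep = "\t"), con)
  }
  invisible(path)
}
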