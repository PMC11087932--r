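#' Mix normal and tumor count profiles at chosen tumor fractions
#'
#' Builds an artificial admixture series: both sources are first
#' depth-normalized to a common diploid (median) bin depth — mixing must
#' operate on cell fractions, and a diploid bin receives reads in
#' proportion to per-cell depth, so equalizing the median bin count makes
#' the per-bin mixture `t * tumor + (1 - t) * normal` follow the admixture
#' copy algebra exactly (a total-count normalization would let the tumor's
#' deleted mass inflate its per-cell depth). Deterministic; the seed is
#' reserved for an optional resampling mode.
#'
#' @param normal,tumor [bin_counts()] profiles on the same grid with
#'   positive totals.
#' @param fractions Tumor fractions in (0, 1], strictly increasing.
#' @param seed Seed (unused by the default deterministic rounding).
#' @param round_counts Round mixture counts to integers (default `TRUE`;
#'   disable for noiseless algebra at arbitrary precision).
#' @return Object of class `admixture_set`: list with `mixtures` (list of
#'   `{tumor_fraction_true, counts}`), `source_normal_id`,
#'   `source_tumor_id`.
#' @export
make_admixture <- function(normal, tumor, fractions = seq(0.1, 0.9, by = 0.1),
                           seed = 1L, round_counts = TRUE) {
  assert_same_grid(normal, tumor)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must lie in (0, 1]")
  if (is.unsorted(fractions, strictly = TRUE)) {
    stop("fractions must be strictly increasing")
  }
  if (sum(normal$count, na.rm = TRUE) <= 0 || sum(tumor$count, na.rm = TRUE) <= 0) {
    stop("both inputs need positive total counts")
  }
  med_n <- median(normal$count[normal$count > 0], na.rm = TRUE)
  med_t <- median(tumor$count[tumor$count > 0], na.rm = TRUE)
  target <- (med_n + med_t) / 2
  norm_n <- normal$count * target / med_n
  norm_t <- tumor$count * target / med_t

  grid <- counts_grid(normal)
  mixtures <- lapply(fractions, function(t) {
    mixed <- t * norm_t + (1 - t) * norm_n
    if (round_counts) mixed <- round(mixed)
    list(tumor_fraction_true = t,
         counts = bin_counts(grid, mixed, gc = normal$gc,
                             mappability = normal$mappability,
                             sample_id = sprintf("admix_t%.2f", t)))
  })
  structure(list(mixtures = mixtures,
                 source_normal_id = attr(normal, "sample_id", exact = TRUE),
                 source_tumor_id = attr(tumor, "sample_id", exact = TRUE)),
            class = "admixture_set")
}

marker_copy_value <- function(profile, marker_bins) {
  vals <- profile$log2_ratio[marker_bins]
  vals <- vals[profile$valid[marker_bins] & is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  mean(2 * 2^vals)
}

#' Fit the homozygous-deletion baseline at CDKN2A/B
#'
#' Runs the correction (and optional panel-normalization) pipeline on each
#' admixture mixture, extracts the copy value at the CDKN2A/B bins (mean
#' over marker bins of `2 * 2^log2_ratio`) and fits ordinary least squares
#' of copy value on true tumor fraction. Under a true homozygous deletion
#' the copy value follows `2 - 2t`, so a usable baseline has slope near -2.
#'
#' @param admixtures An [make_admixture()] series built from a tumor with
#'   homozygous CDKN2A/B deletion; at least 3 mixtures spanning a fraction
#'   range of at least 0.3.
#' @param mask Exclusion mask passed to [correct_bias()].
#' @param panel Optional panel of normals (list of `cnv_profile`).
#' @param config Correction configuration.
#' @return Object of class `deletion_baseline`: list with `slope`,
#'   `intercept`, `residual_sd`, `n_points`, `t_range`, `points` (tibble of
#'   fitted observations) and `provenance`.
#' @export
fit_baseline <- function(admixtures, mask = NULL, panel = list(),
                         config = correction_config()) {
  stopifnot(inherits(admixtures, "admixture_set"))
  mixtures <- admixtures$mixtures
  if (length(mixtures) < 3) {
    stop("insufficient data: need >= 3 admixture points, got ", length(mixtures))
  }
  ts <- vapply(mixtures, function(m) m$tumor_fraction_true, 0)
  if (diff(range(ts)) < 0.3) {
    stop("admixture fractions must span a range of at least 0.3")
  }

  grid <- counts_grid(mixtures[[1]]$counts)
  mb <- locate_marker_bins(grid, "CDKN2AB")
  copy_vals <- vapply(seq_along(mixtures), function(i) {
    prof <- correct_bias(mixtures[[i]]$counts, mask = mask, config = config)
    if (length(panel) > 0) prof <- normalize_against_panel(prof, panel)
    cv <- marker_copy_value(prof, mb)
    if (is.na(cv)) {
      stop("marker-coverage error: CDKN2A/B bins all invalid in mixture t = ",
           ts[i])
    }
    cv
  }, 0)

  fit <- lm(copy_vals ~ ts)
  res <- fit$residuals
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         residual_sd = if (length(res) > 2) sqrt(sum(res^2) / (length(res) - 2)) else 0,
         n_points = length(ts), t_range = range(ts),
         points = tibble::tibble(tumor_fraction = ts, copy_value = copy_vals),
         provenance = list(source_normal = admixtures$source_normal_id,
                           source_tumor = admixtures$source_tumor_id)),
    class = "deletion_baseline")
}

#' Evaluate a deletion baseline
#'
#' @param baseline A `deletion_baseline`.
#' @param tumor_fraction Tumor fraction(s).
#' @return Expected copy value at CDKN2A/B under true homozygous deletion.
#' @export
predict_baseline <- function(baseline, tumor_fraction) {
  baseline$intercept + baseline$slope * tumor_fraction
}

# a usable homozygous baseline must slope materially downward; near-zero
# slope means the admixture carried no deletion signal
baseline_usable <- function(baseline) {
  is.finite(baseline$slope) && baseline$slope < -0.1 && baseline$n_points >= 3
}

#' Classify an observed CDKN2A/B deletion as homozygous or hemizygous
#'
#' Compares the observed copy value against three expectations at the
#' sample's tumor fraction: the fitted homozygous baseline
#' `predict_baseline(baseline, t)`, the analytic hemizygous expectation
#' `2 - t` (one copy lost in tumor cells), and the neutral value 2. The call
#' is the nearest expectation, with cuts at the midpoints; the
#' homozygous/hemizygous margin therefore widens with tumor fraction.
#'
#' @param observed_copy Observed copy value (mean of `2 * 2^log2_ratio` over
#'   the marker bins).
#' @param tumor_fraction Tumor fraction in (0, 1].
#' @param baseline A usable `deletion_baseline` (negative slope).
#' @return `"homozygous"`, `"hemizygous"` or `"none"`.
#' @export
classify_deletion <- function(observed_copy, tumor_fraction, baseline) {
  stopifnot(tumor_fraction > 0, tumor_fraction <= 1)
  if (!baseline_usable(baseline)) {
    stop("baseline error: unusable deletion baseline (slope must be negative, ",
         "n_points >= 3)")
  }
  homo_expect <- predict_baseline(baseline, tumor_fraction)
  hemi_expect <- 2 - tumor_fraction
  cut_homo_hemi <- (homo_expect + hemi_expect) / 2
  cut_hemi_none <- (hemi_expect + 2) / 2
  if (observed_copy < cut_homo_hemi) "homozygous"
  else if (observed_copy < cut_hemi_none) "hemizygous"
  else "none"
}

#' @export
print.deletion_baseline <- function(x, ...) {
  cat("<deletion_baseline> copy(t) =", format(round(x$intercept, 4)), "+",
      format(round(x$slope, 4)), "* t\n")
  cat("  residual sd:", format(round(x$residual_sd, 4)), "| n =", x$n_points,
      "| t range:", paste(format(x$t_range), collapse = "-"), "\n")
  invisible(x)
}

#' @describeIn fit_baseline Fitted admixture points as a tibble.
#' @param x A `deletion_baseline`.
#' @param ... Unused.
#' @export
tidy.deletion_baseline <- function(x, ...) x$points

#' @describeIn fit_baseline One-row fit summary.
#' @export
glance.deletion_baseline <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 residual_sd = x$residual_sd, n_points = x$n_points,
                 t_min = x$t_range[1], t_max = x$t_range[2])
}

#' Serialize / load a deletion baseline
#'
#' The baseline is stored as JSON with coefficients and provenance, so a
#' fitted calibration can be reused across runs. A default baseline fitted
#' on a noiseless synthetic admixture series ships with the package
#' (`system.file("extdata", "default_baseline.json", package = "gliomacnv")`).
#'
#' @param baseline A `deletion_baseline`.
#' @param path JSON path.
#' @return `write_baseline`: `path` invisibly; `read_baseline`: a
#'   `deletion_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  jsonlite::write_json(
    list(slope = baseline$slope, intercept = baseline$intercept,
         residual_sd = baseline$residual_sd, n_points = baseline$n_points,
         t_range = baseline$t_range, provenance = baseline$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(slope = x$slope, intercept = x$intercept, residual_sd = x$residual_sd,
         n_points = x$n_points, t_range = x$t_range,
         points = NULL, provenance = x$provenance),
    class = "deletion_baseline")
}

#' The packaged default deletion baseline
#'
#' Fitted on a noiseless synthetic admixture series (slope ~ -2,
#' intercept ~ 2); regenerable with [simulate_admixture_series()] and
#' [fit_baseline()].
#'
#' @return A `deletion_baseline`.
#' @export
default_baseline <- function() {
  read_baseline(system.file("extdata", "default_baseline.json",
                            package = "gliomacnv", mustWork = TRUE))
}
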