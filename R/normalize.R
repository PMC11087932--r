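#' Default bias-correction configuration
#'
#' @param mappability_threshold Bins with mappability below this fraction are
#'   invalidated (default 0.75).
#' @param gc_span Width of the moving smoothing window for the GC fit, as a
#'   fraction of the observed GC range (default 0.3).
#' @param n_gc_bins Number of equal-width GC strata used for the binned
#'   medians (default 50).
#' @param min_valid_bins Fewer valid bins than this aborts correction
#'   (default 50).
#' @return Named list of correction parameters.
#' @export
correction_config <- function(mappability_threshold = 0.75, gc_span = 0.3,
                              n_gc_bins = 50, min_valid_bins = 50) {
  list(mappability_threshold = mappability_threshold, gc_span = gc_span,
       n_gc_bins = n_gc_bins, min_valid_bins = min_valid_bins)
}

# Binned-median GC fit: median count per GC stratum (robust to altered
# segments and outlier bins), then a tricube-weighted local quadratic fit
# through the stratum medians with a moving window spanning `gc_span` of
# the GC range, linearly interpolated at each bin's GC. Local regression
# behavior without assuming a global parametric curve.
gc_fit <- function(count, gc, config) {
  rng <- range(gc)
  # keep ~10+ bins per stratum so a real CNV cannot dominate its stratum
  # median and be absorbed into the bias curve
  n_strata <- max(5, min(config$n_gc_bins, floor(length(count) / 10)))
  breaks <- seq(rng[1], rng[2], length.out = n_strata + 1)
  stratum <- cut(gc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  med <- tapply(count, stratum, median)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  present <- sort(unique(stratum))
  x <- centers[present]
  y <- as.numeric(med[as.character(present)])
  half <- max(config$gc_span * diff(rng) / 2, 1.5 * diff(rng) / config$n_gc_bins)
  smooth <- vapply(seq_along(x), function(i) {
    d <- abs(x - x[i])
    w <- (1 - pmin(d / half, 1)^3)^3
    use <- w > 0
    deg <- min(2, sum(use) - 1)
    if (deg < 1) return(y[i])
    df <- data.frame(xx = x[use], yy = y[use])
    fit <- lm(yy ~ poly(xx, deg, raw = TRUE), data = df, weights = w[use])
    unname(predict(fit, newdata = data.frame(xx = x[i]))[1])
  }, 0)
  approx(x, smooth, xout = gc, rule = 2)$y
}

#' Correct bin counts for GC and mappability bias
#'
#' Two-stage correction: (1) a smooth curve of count versus GC is fitted over
#' valid bins (binned medians with moving-window smoothing) and each count is
#' divided by its fitted value; (2) counts are divided by mappability where
#' available, and bins below the mappability threshold are dropped. The
#' corrected values are then log2-transformed relative to their median over
#' valid autosomal bins (sex chromosomes are excluded from centering so they
#' cannot bias the diploid baseline). Bins that are excluded by the mask,
#' have zero raw count, or lack a GC value are invalid.
#'
#' @param counts A [bin_counts()] profile with GC annotations for at least
#'   80\% of non-excluded bins.
#' @param mask Logical exclusion mask from [exclusion_mask()] (`NULL` = no
#'   exclusion).
#' @param config See [correction_config()].
#' @return A tibble of class `cnv_profile` with columns of `counts` plus
#'   `log2_ratio` (NA where invalid) and `valid`; correction metadata (GC fit
#'   summary, bins dropped by reason) in `attr(, "correction_metadata")`.
#' @export
correct_bias <- function(counts, mask = NULL, config = correction_config()) {
  grid <- counts_grid(counts)
  n <- nrow(counts)
  mask <- mask %||% rep(FALSE, n)
  stopifnot(length(mask) == n)

  gc_cover <- mean(!is.na(counts$gc[!mask]))
  if (is.nan(gc_cover) || gc_cover < 0.8) {
    stop("insufficient GC annotation: ", round(100 * gc_cover),
         "% of non-excluded bins have GC (>= 80% required); ",
         "run annotate_gc_mappability() first")
  }

  excluded <- mask
  zero_count <- !excluded & (is.na(counts$count) | counts$count <= 0)
  no_gc <- !excluded & !zero_count & is.na(counts$gc)
  low_map <- !excluded & !zero_count & !no_gc &
    !is.na(counts$mappability) &
    counts$mappability < config$mappability_threshold
  valid <- !excluded & !zero_count & !no_gc & !low_map

  if (sum(valid) < config$min_valid_bins) {
    stop("insufficient data: only ", sum(valid), " valid bins (need >= ",
         config$min_valid_bins, ")")
  }

  corrected <- rep(NA_real_, n)
  gc_rng <- range(counts$gc[valid])
  gc_skipped <- diff(gc_rng) < 1e-9
  if (gc_skipped) {
    warning("degenerate GC range; GC correction stage skipped")
    corrected[valid] <- counts$count[valid]
    fit_summary <- list(skipped = TRUE)
  } else {
    fitted <- gc_fit(counts$count[valid], counts$gc[valid], config)
    corrected[valid] <- counts$count[valid] / fitted
    fit_summary <- list(skipped = FALSE, gc_range = gc_rng,
                        fitted_range = range(fitted))
  }
  has_map <- valid & !is.na(counts$mappability)
  corrected[has_map] <- corrected[has_map] / counts$mappability[has_map]

  autosomal <- valid & !(counts$chrom %in% c("chrX", "chrY", "X", "Y"))
  center <- median(corrected[if (any(autosomal)) autosomal else valid])
  log2_ratio <- rep(NA_real_, n)
  log2_ratio[valid] <- log2(corrected[valid] / center)

  out <- counts
  out$log2_ratio <- log2_ratio
  out$valid <- valid
  attr(out, "correction_metadata") <- list(
    gc_fit_summary = fit_summary,
    mappability_threshold = config$mappability_threshold,
    bins_dropped_by_reason = c(
      excluded = sum(excluded), zero_count = sum(zero_count),
      missing_gc = sum(no_gc), low_mappability = sum(low_map))
  )
  class(out) <- c("cnv_profile", setdiff(class(counts), c("cnv_profile", "bin_counts")))
  out
}

#' Construct a corrected profile directly from log2 ratios
#'
#' Used by the simulator and tests to build a `cnv_profile` without going
#' through count-level correction.
#'
#' @param grid A [bin_grid()].
#' @param log2_ratio Numeric vector over grid bins.
#' @param valid Logical validity mask (default: finite `log2_ratio`).
#' @param sample_id Sample label.
#' @return A `cnv_profile` tibble.
#' @export
cnv_profile <- function(grid, log2_ratio, valid = is.finite(log2_ratio),
                        sample_id = "sample") {
  stopifnot(inherits(grid, "bin_grid"), length(log2_ratio) == nrow(grid),
            length(valid) == nrow(grid))
  out <- tibble::tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                        bin = grid$bin,
                        count = NA_real_, gc = NA_real_, mappability = NA_real_,
                        log2_ratio = ifelse(valid, log2_ratio, NA_real_),
                        valid = valid)
  structure(out, grid = grid, sample_id = sample_id,
            class = c("cnv_profile", class(tibble::tibble())))
}

#' Normalize a corrected profile against a panel of normals
#'
#' Subtracts, per bin, the median log2 ratio across the panel (robust to one
#' aberrant normal), then re-centers on the autosomal median. Bins invalid in
#' at least half of the panel members become invalid; invalid bins never
#' regain validity.
#'
#' @param profile A `cnv_profile`.
#' @param panel List of `cnv_profile`s on the same grid (an empty list falls
#'   back to the identity with a warning).
#' @return A `cnv_profile`.
#' @export
normalize_against_panel <- function(profile, panel) {
  if (length(panel) == 0) {
    warning("empty panel of normals; profile returned unchanged")
    return(profile)
  }
  for (p in panel) assert_same_grid(profile, p)
  ratio_mat <- vapply(panel, function(p) p$log2_ratio, numeric(nrow(profile)))
  ratio_mat <- matrix(ratio_mat, nrow = nrow(profile))
  panel_median <- apply(ratio_mat, 1, median, na.rm = TRUE)
  invalid_frac <- rowMeans(vapply(panel, function(p) !p$valid, logical(nrow(profile))))

  valid <- profile$valid & invalid_frac < 0.5 & !is.na(panel_median)
  adj <- profile$log2_ratio - panel_median
  autosomal <- valid & !(profile$chrom %in% c("chrX", "chrY", "X", "Y"))
  center <- median(adj[if (any(autosomal)) autosomal else valid])
  out <- profile
  out$log2_ratio <- ifelse(valid, adj - center, NA_real_)
  out$valid <- valid
  attr(out, "panel_size") <- length(panel)
  out
}

#' Export a corrected profile as TSV
#'
#' Writes `chrom`, `start`, `end`, `log2_ratio`, `valid` for inspection or
#' external plotting.
#'
#' @param profile A `cnv_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  readr::write_tsv(
    tibble::tibble(chrom = profile$chrom, start = profile$start,
                   end = profile$end, log2_ratio = profile$log2_ratio,
                   valid = profile$valid),
    path)
  invisible(path)
}

#' Read a corrected profile from TSV
#'
#' Inverse of [write_profile_tsv()] onto a known grid.
#'
#' @param path TSV written by [write_profile_tsv()].
#' @param grid The matching [bin_grid()].
#' @param sample_id Sample label.
#' @return A `cnv_profile`.
#' @export
read_profile_tsv <- function(path, grid, sample_id = basename(path)) {
  tbl <- readr::read_tsv(path, col_types = "cdddl", progress = FALSE)
  if (nrow(tbl) != nrow(grid) || !identical(tbl$chrom, grid$chrom)) {
    stop("profile TSV does not match the grid")
  }
  cnv_profile(grid, tbl$log2_ratio, valid = tbl$valid, sample_id = sample_id)
}
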