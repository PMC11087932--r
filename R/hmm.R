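#' HMM configuration for copy-number segmentation
#'
#' The segmentation model assigns each valid bin an integer copy state
#' `0..max(copy_states)` (the top state also absorbs higher amplifications).
#' Emissions are Gaussian around the tumor-admixture expectation
#' [expected_log2_ratio()]; transitions are homogeneous with a small
#' probability of changing state between adjacent bins; a soft per-bin state
#' prior concentrated on the diploid state resolves the tumor-fraction
#' scaling degeneracy (see the package vignette).
#'
#' @param copy_states Ordered integer states (default `0:5`; state 5 means
#'   ">= 5 copies" and is emitted at the 5-copy center).
#' @param normal_copy The diploid state (2).
#' @param switch_prob Probability of a state change between adjacent bins,
#'   in (0, 0.5) (default 1e-4).
#' @param emission_sd Gaussian emission standard deviation; `NULL` (default)
#'   estimates it from the data as `mad(diff(log2_ratio)) / sqrt(2)`, a
#'   robust noise estimate independent of segment structure.
#' @param tf_grid Tumor fractions scanned during estimation (default 0.05 to
#'   1.00 in steps of 0.01).
#' @param state_prior_alpha Strength of the per-bin state prior
#'   `propto exp(-alpha * |c - 2|)` (default 0.3); 0 disables it.
#' @param min_valid_bins Minimum valid bins required by
#'   [estimate_tumor_fraction()] (default 100).
#' @param seed Seed reserved for stochastic restarts (the default decoder is
#'   fully deterministic).
#' @return Named list of class `hmm_config`.
#' @export
hmm_config <- function(copy_states = 0:5, normal_copy = 2, switch_prob = 1e-4,
                       emission_sd = NULL, tf_grid = seq(0.05, 1, by = 0.01),
                       state_prior_alpha = 0.3, min_valid_bins = 100,
                       seed = 1L) {
  stopifnot(switch_prob > 0, switch_prob < 0.5,
            all(tf_grid > 0), all(tf_grid <= 1),
            normal_copy %in% copy_states)
  structure(list(copy_states = as.integer(copy_states), normal_copy = normal_copy,
                 switch_prob = switch_prob, emission_sd = emission_sd,
                 tf_grid = tf_grid, state_prior_alpha = state_prior_alpha,
                 min_valid_bins = min_valid_bins, seed = seed),
            class = "hmm_config")
}

#' Expected log2 copy ratio under tumor admixture
#'
#' A sample with tumor fraction `t` whose tumor cells carry `c` copies of a
#' locus (against a diploid normal background) has expected ratio
#' `log2((t*c + 2*(1-t)) / 2)`: 0 at `c = 2` for any `t`, strictly
#' increasing in `c`, and attenuated toward 0 as `t` decreases. `c = 0` with
#' `t = 1` yields `-Inf`; the decoder clamps emission centers.
#'
#' @param copy_state Integer copy number in tumor cells (>= 0).
#' @param tumor_fraction Tumor fraction in (0, 1].
#' @return Expected log2 ratio (possibly `-Inf`).
#' @examples
#' expected_log2_ratio(4, 1)    # 1
#' expected_log2_ratio(0, 0.5)  # -1
#' @export
expected_log2_ratio <- function(copy_state, tumor_fraction) {
  stopifnot(all(copy_state >= 0), all(tumor_fraction > 0), all(tumor_fraction <= 1))
  log2((tumor_fraction * copy_state + 2 * (1 - tumor_fraction)) / 2)
}

# floor applied to emission centers so c=0 at t=1 stays finite
MU_CLAMP <- -8

estimate_emission_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) return(0.1)
  s <- mad(diff(x)) / sqrt(2)
  if (!is.finite(s) || s < 1e-4) 1e-4 else s
}

state_log_prior <- function(config) {
  lp <- -config$state_prior_alpha * abs(config$copy_states - config$normal_copy)
  lp - log(sum(exp(lp)))
}

#' Viterbi copy-state segmentation at a fixed tumor fraction
#'
#' Decodes the maximum-probability copy-state path per chromosome (no
#' transitions across chromosome boundaries) under a uniform initial
#' distribution, homogeneous transitions (self-probability
#' `1 - switch_prob`, off-diagonal `switch_prob / (K - 1)`), the per-bin
#' state prior, and Gaussian emissions centered at [expected_log2_ratio()].
#' Invalid bins carry no emission; the chain bridges them with a single
#' transition between neighboring valid bins.
#'
#' @param profile A `cnv_profile`.
#' @param tumor_fraction Tumor fraction in (0, 1].
#' @param config An [hmm_config()].
#' @return List with `states` (integer copy state per bin, `NA` at invalid
#'   bins), `log_likelihood` (joint log probability of the decoded path and
#'   data) and `emission_sd` used.
#' @export
viterbi_segment <- function(profile, tumor_fraction, config = hmm_config()) {
  valid <- which(profile$valid & is.finite(profile$log2_ratio))
  if (length(valid) == 0) stop("insufficient data: no valid bins")
  sd <- config$emission_sd %||% estimate_emission_sd(profile$log2_ratio)
  stopifnot(sd > 0)

  K <- length(config$copy_states)
  mu <- pmax(expected_log2_ratio(config$copy_states, tumor_fraction), MU_CLAMP)
  lp <- state_log_prior(config)
  x <- profile$log2_ratio[valid]
  # n_valid x K log emission densities (state prior folded in)
  emis <- outer(x, mu, function(xx, mm) dnorm(xx, mm, sd, log = TRUE)) +
    matrix(lp, nrow = length(x), ncol = K, byrow = TRUE)

  log_self <- log(1 - config$switch_prob)
  log_switch <- log(config$switch_prob / (K - 1))

  states <- rep(NA_integer_, nrow(profile))
  ll <- 0
  chroms <- unique(profile$chrom[valid])
  for (chrom in chroms) {
    sel <- profile$chrom[valid] == chrom
    dec <- viterbi_decode(emis[sel, , drop = FALSE], log_self, log_switch)
    states[valid[sel]] <- config$copy_states[dec$path]
    ll <- ll + dec$log_likelihood
  }
  list(states = states, log_likelihood = ll, emission_sd = sd)
}

#' Segment a profile and estimate tumor fraction
#'
#' Runs [viterbi_segment()] at every tumor fraction in `config$tf_grid` and
#' keeps the decoding with maximal joint log likelihood (ties broken toward
#' the smaller fraction). When the winning path is entirely diploid the
#' estimate carries no information and is flagged `non_informative`.
#'
#' @param profile A `cnv_profile` with at least `config$min_valid_bins`
#'   valid bins.
#' @param config An [hmm_config()].
#' @return Object of class `cnv_segmentation`: list with `bins` (profile
#'   tibble plus `copy_state` and `expected_log2`), `segments` (tibble
#'   `chrom`, `start`, `end`, `copy_state`, `mean_log2`, `n_bins`),
#'   `tumor_fraction`, `log_likelihood`, `non_informative`, `emission_sd`,
#'   `tf_profile` (log likelihood per scanned fraction) and `config`.
#' @export
estimate_tumor_fraction <- function(profile, config = hmm_config()) {
  n_valid <- sum(profile$valid & is.finite(profile$log2_ratio))
  if (n_valid == 0) stop("insufficient data: profile has no valid bins")
  if (n_valid < config$min_valid_bins) {
    stop("insufficient data: ", n_valid, " valid bins (need >= ",
         config$min_valid_bins, ")")
  }
  sd <- config$emission_sd %||% estimate_emission_sd(profile$log2_ratio)
  cfg <- config
  cfg$emission_sd <- sd

  best <- NULL
  lls <- numeric(length(cfg$tf_grid))
  for (i in seq_along(cfg$tf_grid)) {
    t <- cfg$tf_grid[i]
    fit <- viterbi_segment(profile, t, cfg)
    lls[i] <- fit$log_likelihood
    if (is.null(best) || fit$log_likelihood > best$log_likelihood + 1e-9) {
      best <- fit
      best$tumor_fraction <- t
    }
  }

  states <- best$states
  expected <- rep(NA_real_, length(states))
  ok <- !is.na(states)
  expected[ok] <- pmax(expected_log2_ratio(states[ok], best$tumor_fraction), MU_CLAMP)

  bins <- profile
  bins$copy_state <- states
  bins$expected_log2 <- expected

  structure(
    list(bins = bins,
         segments = merge_segments(states, counts_grid(profile) %||% attr(profile, "grid"), profile),
         tumor_fraction = best$tumor_fraction,
         log_likelihood = best$log_likelihood,
         non_informative = all(states[ok] == cfg$normal_copy),
         emission_sd = sd,
         tf_profile = tibble::tibble(tumor_fraction = cfg$tf_grid, log_likelihood = lls),
         sample_id = attr(profile, "sample_id", exact = TRUE) %||% "sample",
         config = cfg),
    class = "cnv_segmentation"
  )
}

#' Merge a copy-state path into segments
#'
#' Maximal runs of identical copy state per chromosome; `mean_log2` is the
#' mean ratio over the valid bins of the run, and segment bounds span from
#' the first to the last valid bin of the run.
#'
#' @param states Integer state per grid bin (`NA` at invalid bins).
#' @param grid The [bin_grid()] the path is aligned to.
#' @param profile The `cnv_profile` supplying `log2_ratio`.
#' @return Tibble with `chrom`, `start`, `end`, `copy_state`, `mean_log2`,
#'   `n_bins`.
#' @export
merge_segments <- function(states, grid, profile) {
  stopifnot(length(states) == nrow(grid))
  out <- list()
  for (chrom in unique(grid$chrom)) {
    idx <- which(grid$chrom == chrom & !is.na(states))
    if (length(idx) == 0) next
    s <- states[idx]
    run_id <- cumsum(c(1L, as.integer(s[-1] != s[-length(s)])))
    for (r in unique(run_id)) {
      b <- idx[run_id == r]
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chrom,
        start = grid$start[b[1]],
        end = grid$end[b[length(b)]],
        copy_state = s[run_id == r][1],
        mean_log2 = mean(profile$log2_ratio[b], na.rm = TRUE),
        n_bins = length(b))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = double(), end = double(),
                          copy_state = integer(), mean_log2 = double(),
                          n_bins = integer()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.cnv_segmentation <- function(x, ...) {
  cat("<cnv_segmentation>", x$sample_id, "\n")
  cat("  tumor fraction:", format(x$tumor_fraction),
      if (x$non_informative) "(non-informative: all-diploid path)" else "", "\n")
  cat("  log likelihood:", format(x$log_likelihood), "| emission sd:",
      format(round(x$emission_sd, 4)), "\n")
  cat("  segments:", nrow(x$segments), "over",
      sum(x$segments$n_bins), "valid bins\n")
  invisible(x)
}

#' @describeIn estimate_tumor_fraction Segments as a tibble (one row per
#'   segment).
#' @param x A `cnv_segmentation`.
#' @param ... Unused.
#' @export
tidy.cnv_segmentation <- function(x, ...) x$segments

#' @describeIn estimate_tumor_fraction One-row model summary (tumor
#'   fraction, log likelihood, segment and bin counts, emission sd).
#' @export
glance.cnv_segmentation <- function(x, ...) {
  tibble::tibble(tumor_fraction = x$tumor_fraction,
                 log_likelihood = x$log_likelihood,
                 non_informative = x$non_informative,
                 emission_sd = x$emission_sd,
                 n_segments = nrow(x$segments),
                 n_bins = sum(x$segments$n_bins))
}

#' Export segments as SEG-like TSV
#'
#' @param seg A `cnv_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(seg, path) {
  readr::write_tsv(
    dplyr::mutate(seg$segments, sample = seg$sample_id, .before = 1),
    path)
  invisible(path)
}

#' Export segments as BED
#'
#' @param seg A `cnv_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(seg, path) {
  readr::write_tsv(
    tibble::tibble(chrom = seg$segments$chrom,
                   start = as.integer(seg$segments$start),
                   end = as.integer(seg$segments$end),
                   name = paste0("cn", seg$segments$copy_state),
                   score = round(1000 * pmin(1, abs(seg$segments$mean_log2)))),
    path, col_names = FALSE)
  invisible(path)
}
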