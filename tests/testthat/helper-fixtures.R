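# Shared fixtures: toy builds/grids and an exhaustive Viterbi oracle.

tiny_build <- function(lenA = 2e6, lenB = 1e6, gaps = NULL) {
  toy_build(c(chrA = lenA, chrB = lenB), gaps = gaps)
}

# two-chromosome grid with 4 + 2 bins at 500 kb
tiny_grid <- function(...) bin_grid(tiny_build(...), 5e5)

flat_counts <- function(grid, value = 100, gc = 0.45) {
  annotate_gc_mappability(bin_counts(grid, rep(value, nrow(grid))),
                          gc_track = rep(gc, nrow(grid)),
                          map_track = rep(1, nrow(grid)))
}

# Exhaustive max-probability path search, independent of the C++ decoder:
# enumerates every state path per chromosome and scores it with directly
# composed Gaussian density / transition / prior terms.
oracle_viterbi <- function(profile, tumor_fraction, config) {
  sd <- config$emission_sd
  K <- length(config$copy_states)
  mu <- pmax(expected_log2_ratio(config$copy_states, tumor_fraction), -8)
  lp <- -config$state_prior_alpha * abs(config$copy_states - config$normal_copy)
  lp <- lp - log(sum(exp(lp)))
  l_self <- log(1 - config$switch_prob)
  l_switch <- log(config$switch_prob / (K - 1))

  states <- rep(NA_integer_, nrow(profile))
  total_ll <- 0
  for (chrom in unique(profile$chrom)) {
    idx <- which(profile$chrom == chrom & profile$valid &
                   is.finite(profile$log2_ratio))
    if (length(idx) == 0) next
    x <- profile$log2_ratio[idx]
    n <- length(x)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
    # per-bin emission + prior scored via direct density composition
    escore <- matrix(0, nrow(paths), n)
    for (i in seq_len(n)) {
      escore[, i] <- dnorm(x[i], mu[paths[, i]], sd, log = TRUE) + lp[paths[, i]]
    }
    score <- -log(K) + rowSums(escore)
    if (n > 1) {
      same <- paths[, -1, drop = FALSE] == paths[, -n, drop = FALSE]
      score <- score + rowSums(same) * l_self + rowSums(!same) * l_switch
    }
    best <- which.max(score)
    states[idx] <- config$copy_states[paths[best, ]]
    total_ll <- total_ll + score[best]
  }
  list(states = states, log_likelihood = total_ll)
}

# Background arm losses used by deletion-typing simulations: anchor the
# tumor-fraction estimate without touching any catalog marker.
background_losses <- function(build) {
  list(list(chrom = "chr13", start = 0, end = build$chrom_lengths[["chr13"]], copy = 1),
       list(chrom = "chr18", start = 0, end = build$chrom_lengths[["chr18"]], copy = 1))
}

hg38_build <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- genome_build("hg38")
    cache
  }
})

hg38_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- bin_grid(hg38_build(), 5e5)
    cache
  }
})

ideal_baseline <- function() {
  structure(list(slope = -2, intercept = 2, residual_sd = 0, n_points = 9,
                 t_range = c(0.1, 0.9), points = NULL,
                 provenance = list(note = "ideal analytic baseline")),
            class = "deletion_baseline")
}

# Marker-call tibble shorthand for classification tests
fake_calls <- function(cdkn2ab = "neutral", egfr = "neutral",
                       arm_1p = "neutral", arm_19q = "neutral",
                       chr7 = "neutral", chr10 = "neutral") {
  tibble::tibble(
    marker_id = c("CDKN2AB", "EGFR", "ARM_1P", "ARM_19Q", "CHR7", "CHR10"),
    status = c(cdkn2ab, egfr, arm_1p, arm_19q, chr7, chr10),
    mean_copy = NA_real_, fraction_of_bins_altered = NA_real_,
    bins_used = 10L, evidence_note = "")
}
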