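test_that("expected log2 ratio follows the admixture closed form", {
  for (t in c(0.1, 0.5, 1)) expect_equal(expected_log2_ratio(2, t), 0)
  expect_equal(expected_log2_ratio(4, 1), 1)
  expect_equal(expected_log2_ratio(0, 0.5), -1)
  expect_equal(expected_log2_ratio(3, 0.6), log2((0.6 * 3 + 0.8) / 2))
  expect_equal(expected_log2_ratio(0, 1), -Inf)
  # strictly increasing in copy state
  for (t in c(0.2, 0.7)) {
    expect_true(all(diff(expected_log2_ratio(0:6, t)) > 0))
  }
})

test_that("a flat profile decodes as all-diploid on every chromosome", {
  g <- tiny_grid()
  set.seed(1)
  prof <- cnv_profile(g, rnorm(6, 0, 0.05))
  fit <- viterbi_segment(prof, 0.5, hmm_config(emission_sd = 0.05))
  expect_equal(fit$states, rep(2L, 6))
})

test_that("an exact emission match decodes the planted arm loss", {
  g <- bin_grid(toy_build(c(chrA = 5e6, chrB = 5e6)), 5e5)
  ratio <- rep(0, 20)
  ratio[1:10] <- -1  # chrA exactly at expected_log2(0, 0.5)
  prof <- cnv_profile(g, ratio)
  fit <- viterbi_segment(prof, 0.5, hmm_config(emission_sd = 0.1))
  expect_equal(fit$states[1:10], rep(0L, 10))
  expect_equal(fit$states[11:20], rep(2L, 10))
})

test_that("viterbi matches exhaustive path enumeration on small instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    K <- sample(2:4, 1)
    states <- sort(unique(c(2L, seq_len(K) - 1L)))
    cfg <- hmm_config(copy_states = states,
                      emission_sd = runif(1, 0.05, 0.3),
                      switch_prob = runif(1, 1e-4, 0.2))
    K <- length(states)
    g <- bin_grid(toy_build(c(chrA = n * 5e5)), 5e5)
    t <- runif(1, 0.2, 1)
    prof <- cnv_profile(g, rnorm(n, sample(c(-1, 0, 0.6), n, TRUE) * t, 0.3))
    fit <- viterbi_segment(prof, t, cfg)
    oracle <- oracle_viterbi(prof, t, cfg)
    expect_equal(fit$log_likelihood, oracle$log_likelihood, tolerance = 1e-9)
    expect_equal(fit$states, oracle$states)
  }
})

test_that("invalid bins are bridged without emission and chromosomes decode independently", {
  g <- bin_grid(toy_build(c(chrA = 3e6, chrB = 2e6)), 5e5)
  ratio <- c(-1, NA, -1, 0, 0, 0, 0.585, 0.585, NA, 0.585)
  valid <- !is.na(ratio)
  prof <- cnv_profile(g, ratio, valid = valid)
  cfg <- hmm_config(emission_sd = 0.1)
  fit <- viterbi_segment(prof, 0.5, cfg)
  expect_true(is.na(fit$states[2]))
  expect_true(is.na(fit$states[9]))
  oracle <- oracle_viterbi(prof, 0.5, cfg)
  expect_equal(fit$log_likelihood, oracle$log_likelihood, tolerance = 1e-9)
  expect_equal(fit$states, oracle$states)
})

test_that("a noiseless profile built at a grid fraction is recovered exactly", {
  g <- hg38_grid()
  events <- list(list(marker = "CHR10", copy = 1),
                 list(chrom = "chr4", start = 0, end = 5e7, copy = 4))
  sim <- simulate_profile(g, 0.40, events, sd = 0, seed = 1)
  cfg <- hmm_config(emission_sd = 0.05, min_valid_bins = 100)
  seg <- estimate_tumor_fraction(sim$profile, cfg)
  expect_equal(seg$tumor_fraction, 0.40)
  expect_false(seg$non_informative)
  expect_equal(seg$bins$copy_state, sim$truth$copy, ignore_attr = TRUE)
})

test_that("a pure normal profile is flagged non-informative at the grid floor", {
  g <- hg38_grid()
  sim <- simulate_profile(g, 0.5, list(), sd = 0.08, seed = 2)
  seg <- estimate_tumor_fraction(sim$profile)
  expect_true(seg$non_informative)
  expect_equal(seg$tumor_fraction, min(seg$config$tf_grid))
  expect_true(all(seg$bins$copy_state[!is.na(seg$bins$copy_state)] == 2))
})

test_that("tumor fraction and states are recovered from noisy simulations", {
  g <- hg38_grid()
  events <- list(list(marker = "CHR10", copy = 1),
                 list(marker = "CHR7", copy = 3))
  for (t in c(0.4, 0.7)) {
    sim <- simulate_profile(g, t, events, sd = 0.1, seed = 7)
    seg <- estimate_tumor_fraction(sim$profile)
    expect_lt(abs(seg$tumor_fraction - t), 0.05)
    acc <- mean(seg$bins$copy_state == sim$truth$copy, na.rm = TRUE)
    expect_gt(acc, 0.95)
  }
})

test_that("the reported log likelihood matches an independent path scoring", {
  g <- bin_grid(toy_build(c(chrA = 4e6)), 5e5)
  set.seed(5)
  prof <- cnv_profile(g, rnorm(8, c(rep(-0.5, 4), rep(0, 4)), 0.1))
  cfg <- hmm_config(emission_sd = 0.1)
  fit <- viterbi_segment(prof, 0.6, cfg)
  # rescore the reported path by direct composition
  K <- length(cfg$copy_states)
  mu <- pmax(expected_log2_ratio(cfg$copy_states, 0.6), -8)
  lp <- -cfg$state_prior_alpha * abs(cfg$copy_states - 2)
  lp <- lp - log(sum(exp(lp)))
  s_idx <- match(fit$states, cfg$copy_states)
  ll <- -log(K) + sum(dnorm(prof$log2_ratio, mu[s_idx], 0.1, log = TRUE) + lp[s_idx]) +
    sum(ifelse(diff(s_idx) == 0, log(1 - cfg$switch_prob),
               log(cfg$switch_prob / (K - 1))))
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-9)
})

test_that("segments merge maximal runs and conserve valid-bin counts", {
  g <- bin_grid(toy_build(c(chrA = 2.5e6, chrB = 1e6)), 5e5)
  prof <- cnv_profile(g, rep(0, 7))

  segs <- merge_segments(rep(2L, 7), g, prof)
  expect_equal(nrow(segs), 2)  # one per chromosome

  segs2 <- merge_segments(c(2L, 2L, 0L, 0L, 2L, 2L, 2L), g, prof)
  expect_equal(segs2$n_bins[segs2$chrom == "chrA"], c(2, 2, 1))
  expect_equal(segs2$copy_state[segs2$chrom == "chrA"], c(2, 0, 2))
  # adjacent segments always differ in state
  for (ch in unique(segs2$chrom)) {
    s <- segs2$copy_state[segs2$chrom == ch]
    if (length(s) > 1) expect_true(all(diff(s) != 0))
  }

  # fuzz: n_bins always sums to the number of decoded bins
  set.seed(10)
  for (i in 1:50) {
    states <- sample(c(NA, 0:3), 7, TRUE)
    segs3 <- merge_segments(as.integer(states), g, prof)
    expect_equal(sum(segs3$n_bins), sum(!is.na(states)))
  }
})

test_that("segmentation results are deterministic and tidy/glance behave", {
  g <- hg38_grid()
  sim <- simulate_profile(g, 0.6, list(list(marker = "ARM_1P", copy = 1)),
                          sd = 0.1, seed = 12)
  s1 <- estimate_tumor_fraction(sim$profile)
  s2 <- estimate_tumor_fraction(sim$profile)
  expect_identical(s1$tumor_fraction, s2$tumor_fraction)
  expect_identical(s1$bins$copy_state, s2$bins$copy_state)
  expect_identical(s1$log_likelihood, s2$log_likelihood)

  td <- tidy(s1)
  expect_true(all(c("chrom", "start", "end", "copy_state", "mean_log2",
                    "n_bins") %in% names(td)))
  gl <- glance(s1)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$tumor_fraction, s1$tumor_fraction)

  # likelihood ties break toward the smaller tumor fraction
  tfp <- s1$tf_profile
  best <- tfp$tumor_fraction[tfp$log_likelihood >=
                               max(tfp$log_likelihood) - 1e-9]
  expect_equal(s1$tumor_fraction, min(best))
})

test_that("degenerate inputs raise informative errors", {
  g <- tiny_grid()
  prof <- cnv_profile(g, rep(NA_real_, 6), valid = rep(FALSE, 6))
  expect_error(viterbi_segment(prof, 0.5, hmm_config(emission_sd = 0.1)),
               "no valid bins")
  prof2 <- cnv_profile(g, rep(0, 6))
  expect_error(estimate_tumor_fraction(prof2, hmm_config(min_valid_bins = 100)),
               "insufficient data")
  expect_error(hmm_config(switch_prob = 0.7), "switch_prob")
  expect_error(hmm_config(tf_grid = c(0, 0.5)))
})
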