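# Smaller toy genome carrying a CDKN2AB marker for fast admixture tests
baseline_build <- function() {
  toy_build(c(chr1 = 3e7, chr9 = 3e7, chr13 = 3e7),
            markers = tibble::tibble(chrom = "chr9", start = 1.02e7,
                                     end = 1.06e7, marker_id = "CDKN2AB"))
}

noiseless_pair <- function(depth = 1e4) {
  b <- baseline_build()
  g <- bin_grid(b, 5e5)
  normal <- simulate_bin_counts(simulation_spec(
    build = b, depth_lambda = depth, tumor_fraction = 1, events = list(),
    noise = "none", seed = 1), grid = g)
  tumor <- simulate_bin_counts(simulation_spec(
    build = b, depth_lambda = depth, tumor_fraction = 1,
    events = list(list(marker = "CDKN2AB", copy = 0)),
    noise = "none", seed = 2), grid = g)
  list(normal = normal$counts, tumor = tumor$counts, grid = g)
}

test_that("admixture endpoints and midpoints follow mixing arithmetic", {
  p <- noiseless_pair()
  adm <- make_admixture(p$normal, p$tumor, fractions = c(0.5, 1),
                        round_counts = FALSE)
  # t = 1 -> depth-normalized tumor counts exactly (median-depth scaling)
  med_t <- median(p$tumor$count[p$tumor$count > 0])
  med_n <- median(p$normal$count[p$normal$count > 0])
  target <- (med_t + med_n) / 2
  expect_equal(adm$mixtures[[2]]$counts$count, p$tumor$count * target / med_t)

  # t = 0.5 with normal bin 100, tumor bin 0 at equal diploid depth -> 50
  g <- tiny_grid()
  n <- bin_counts(g, rep(100, 6))
  tm <- bin_counts(g, c(0, rep(100, 5)))
  adm2 <- make_admixture(n, tm, fractions = 0.5, round_counts = FALSE)
  mixed <- adm2$mixtures[[1]]$counts$count
  expect_equal(mixed[1], 0.5 * 0 + 0.5 * 100)
  expect_equal(mixed[2], 100)

  expect_error(make_admixture(n, tm, fractions = c(0.5, 0.2)), "increasing")
  expect_error(make_admixture(n, tm, fractions = 1.2), "\\(0, 1\\]")
})

test_that("a noiseless homozygous-deletion series fits copy(t) = 2 - 2t", {
  p <- noiseless_pair()
  adm <- make_admixture(p$normal, p$tumor, fractions = c(0.2, 0.5, 0.8),
                        round_counts = FALSE)
  bl <- fit_baseline(adm)
  expect_lt(abs(bl$slope + 2), 1e-3)
  expect_lt(abs(bl$intercept - 2), 1e-3)
  expect_lt(bl$residual_sd, 1e-3)
  expect_true(nrow(tidy(bl)) == 3)
  expect_equal(glance(bl)$slope, bl$slope)
})

test_that("mixture copy values follow 2-2t (homozygous) and 2-t (hemizygous)", {
  b <- baseline_build()
  g <- bin_grid(b, 5e5)
  mb <- locate_marker_bins(g, "CDKN2AB")
  for (src_copy in c(0, 1)) {
    tumor <- simulate_bin_counts(simulation_spec(
      build = b, depth_lambda = 1e4, tumor_fraction = 1,
      events = list(list(marker = "CDKN2AB", copy = src_copy)),
      noise = "none", seed = 3), grid = g)
    normal <- simulate_bin_counts(simulation_spec(
      build = b, depth_lambda = 1e4, tumor_fraction = 1, events = list(),
      noise = "none", seed = 4), grid = g)
    adm <- make_admixture(normal$counts, tumor$counts,
                          fractions = c(0.3, 0.6), round_counts = FALSE)
    for (m in adm$mixtures) {
      prof <- correct_bias(m$counts)
      cv <- mean(2 * 2^prof$log2_ratio[mb])
      t <- m$tumor_fraction_true
      expected <- if (src_copy == 0) 2 - 2 * t else 2 - t
      expect_lt(abs(cv - expected), 1e-6)
    }
  }
})

test_that("a degenerate flat series yields slope 0 flagged unusable", {
  p <- noiseless_pair()
  adm <- make_admixture(p$normal, p$normal, fractions = c(0.2, 0.5, 0.8),
                        round_counts = FALSE)
  bl <- fit_baseline(adm)
  expect_lt(abs(bl$slope), 1e-6)
  expect_error(classify_deletion(1.0, 0.5, bl), "unusable")
})

test_that("noisy admixture series recover the homozygous slope", {
  b <- baseline_build()
  g <- bin_grid(b, 5e5)
  slopes <- vapply(1:5, function(seed) {
    adm <- simulate_admixture_series(
      fractions = seq(0.2, 0.9, length.out = 6), seed = seed * 10,
      build = b, depth_lambda = 400, dispersion = 600)
    fit_baseline(adm)$slope
  }, 0)
  expect_true(all(abs(slopes + 2) < 0.3))
})

test_that("deletion classification uses midpoint cuts against the baseline", {
  bl <- ideal_baseline()
  # t = 0.5: homo expectation 1.0, hemi 1.5; cuts at 1.25 and 1.75
  expect_equal(classify_deletion(1.1, 0.5, bl), "homozygous")
  expect_equal(classify_deletion(1.4, 0.5, bl), "hemizygous")
  expect_equal(classify_deletion(1.8, 0.5, bl), "none")
  expect_equal(classify_deletion(2.0, 0.2, bl), "none")
  expect_equal(classify_deletion(2.0, 0.9, bl), "none")
  # boundary: exactly at the cut goes to the less severe class
  expect_equal(classify_deletion(1.25, 0.5, bl), "hemizygous")
})

test_that("fit_baseline enforces its preconditions", {
  p <- noiseless_pair()
  adm <- make_admixture(p$normal, p$tumor, fractions = c(0.4, 0.6))
  expect_error(fit_baseline(adm), "3 admixture points")
  adm2 <- make_admixture(p$normal, p$tumor, fractions = c(0.4, 0.5, 0.6))
  expect_error(fit_baseline(adm2), "range")
})

test_that("baselines serialize and reload through JSON", {
  p <- noiseless_pair()
  adm <- make_admixture(p$normal, p$tumor, fractions = c(0.2, 0.5, 0.8),
                        round_counts = FALSE)
  bl <- fit_baseline(adm)
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline(bl, path)
  back <- read_baseline(path)
  expect_equal(back$slope, bl$slope)
  expect_equal(back$intercept, bl$intercept)
  expect_s3_class(back, "deletion_baseline")

  dflt <- default_baseline()
  expect_lt(abs(dflt$slope + 2), 0.05)
  expect_lt(abs(dflt$intercept - 2), 0.05)
})
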