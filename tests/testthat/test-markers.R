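# Build a segmentation-like object directly from planted states/ratios so
# marker-call logic is tested in isolation from the HMM.
fake_seg <- function(grid, states, ratios = NULL, tumor_fraction = 0.5,
                     non_informative = FALSE) {
  ratios <- ratios %||% vapply(states, function(s) {
    if (is.na(s)) NA_real_ else expected_log2_ratio(s, tumor_fraction)
  }, 0)
  prof <- cnv_profile(grid, ratios, valid = !is.na(states))
  bins <- prof
  bins$copy_state <- as.integer(states)
  bins$expected_log2 <- ratios
  structure(list(bins = bins,
                 segments = merge_segments(as.integer(states), grid, prof),
                 tumor_fraction = tumor_fraction,
                 log_likelihood = 0, non_informative = non_informative,
                 emission_sd = 0.1, sample_id = "fake", config = hmm_config()),
            class = "cnv_segmentation")
}

mk_grid <- function() {
  b <- toy_build(c(chr7 = 5e6, chr9 = 5e6),
                 markers = tibble::tibble(
                   chrom = c("chr9", "chr7"), start = c(1.1e6, 2.6e6),
                   end = c(1.3e6, 2.8e6), marker_id = c("CDKN2AB", "EGFR")))
  bin_grid(b, 5e5)
}

test_that("focal marker calls map decoded states through the baseline", {
  g <- mk_grid()
  cd_bins <- locate_marker_bins(g, "CDKN2AB")
  eg_bins <- locate_marker_bins(g, "EGFR")
  bl <- ideal_baseline()

  neutral <- fake_seg(g, rep(2, 20))
  call <- call_focal_marker(neutral, cd_bins, "CDKN2AB", baseline = bl)
  expect_equal(call$status, "neutral")
  expect_equal(call$mean_copy, 2, tolerance = 1e-9)

  # homozygous deletion at t = 0.5: observed copy 1.0
  homo <- fake_seg(g, replace(rep(2, 20), cd_bins, 0))
  expect_equal(call_focal_marker(homo, cd_bins, "CDKN2AB", baseline = bl)$status,
               "homozygous_loss")

  hemi <- fake_seg(g, replace(rep(2, 20), cd_bins, 1))
  expect_equal(call_focal_marker(hemi, cd_bins, "CDKN2AB", baseline = bl)$status,
               "hemizygous_loss")

  # non-informative tumor fraction suppresses baseline typing
  ni <- fake_seg(g, replace(rep(2, 20), cd_bins, 1), non_informative = TRUE)
  expect_equal(call_focal_marker(ni, cd_bins, "CDKN2AB", baseline = bl)$status,
               "neutral")

  # EGFR by modal state
  amp <- fake_seg(g, replace(rep(2, 20), eg_bins, 5))
  expect_equal(call_focal_marker(amp, eg_bins, "EGFR")$status, "amplification")
  gain <- fake_seg(g, replace(rep(2, 20), eg_bins, 3))
  expect_equal(call_focal_marker(gain, eg_bins, "EGFR")$status, "gain")

  # no valid coverage -> indeterminate
  nocov <- fake_seg(g, replace(rep(2, 20), cd_bins, NA))
  expect_equal(call_focal_marker(nocov, cd_bins, "CDKN2AB", baseline = bl)$status,
               "indeterminate")
})

test_that("arm calls follow the 80% completeness threshold", {
  g <- mk_grid()
  bins_7 <- locate_marker_bins(g, "CHR7")  # 10 bins

  total <- fake_seg(g, c(rep(1, 10), rep(2, 10)))
  call <- call_arm_marker(total, bins_7, "CHR7")
  expect_equal(call$status, "hemizygous_loss")
  expect_equal(call$fraction_of_bins_altered, 1)

  half <- fake_seg(g, c(rep(1, 5), rep(2, 15)))
  call2 <- call_arm_marker(half, bins_7, "CHR7")
  expect_equal(call2$status, "neutral")
  expect_match(call2$evidence_note, "partial loss: 50%")

  # exactly at threshold calls
  eight <- fake_seg(g, c(rep(1, 8), rep(2, 12)))
  expect_equal(call_arm_marker(eight, bins_7, "CHR7")$status, "hemizygous_loss")

  gains <- fake_seg(g, c(rep(3, 9), 2, rep(2, 10)))
  expect_equal(call_arm_marker(gains, bins_7, "CHR7")$status, "gain")

  sparse <- fake_seg(g, c(rep(NA, 7), rep(1, 3), rep(2, 10)))
  expect_equal(call_arm_marker(sparse, bins_7, "CHR7")$status, "indeterminate")
})

test_that("deepening a planted deletion never flips a loss call to neutral", {
  g <- mk_grid()
  bins_7 <- locate_marker_bins(g, "CHR7")
  statuses <- vapply(c(1, 0), function(cp) {
    seg <- fake_seg(g, c(rep(cp, 10), rep(2, 10)))
    call_arm_marker(seg, bins_7, "CHR7")$status
  }, "")
  expect_true(all(statuses == "hemizygous_loss"))
  # and fraction altered is monotone in the number of lost bins
  fr <- vapply(5:10, function(k) {
    seg <- fake_seg(g, c(rep(1, k), rep(2, 20 - k)))
    call_arm_marker(seg, bins_7, "CHR7")$fraction_of_bins_altered
  }, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("composite logic enumerates its full truth table", {
  arm_states <- c("hemizygous_loss", "neutral", "indeterminate")
  for (s1 in arm_states) for (s19 in arm_states) {
    tab <- assemble_marker_table(fake_calls(arm_1p = s1, arm_19q = s19))
    comp <- attr(tab, "composites")$codeletion_1p19q
    if (s1 == "indeterminate" || s19 == "indeterminate") {
      expect_true(is.na(comp))
    } else {
      expect_equal(comp, s1 == "hemizygous_loss" && s19 == "hemizygous_loss")
    }
  }
  chr7_states <- c("gain", "amplification", "neutral", "indeterminate")
  chr10_states <- c("hemizygous_loss", "homozygous_loss", "neutral", "indeterminate")
  for (s7 in chr7_states) for (s10 in chr10_states) {
    tab <- assemble_marker_table(fake_calls(chr7 = s7, chr10 = s10))
    comp <- attr(tab, "composites")$plus7_minus10
    if (s7 == "indeterminate" || s10 == "indeterminate") {
      expect_true(is.na(comp))
    } else {
      expect_equal(comp, s7 %in% c("gain", "amplification") &&
                     s10 %in% c("hemizygous_loss", "homozygous_loss"))
    }
  }
  expect_error(assemble_marker_table(fake_calls()[-1, ]), "missing marker")
})

test_that("marker table exports are value-identical between TSV and JSON", {
  tab <- assemble_marker_table(fake_calls(arm_1p = "hemizygous_loss",
                                          arm_19q = "hemizygous_loss"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_marker_table(tab, tsv, "tsv")
  write_marker_table(tab, js, "json")
  back_tsv <- readr::read_tsv(tsv, show_col_types = FALSE)
  back_js <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back_tsv$status, tab$status)
  expect_equal(back_js$markers$status, tab$status)
  expect_true(back_js$composites$codeletion_1p19q)
  expect_false(back_js$composites$plus7_minus10)
})

test_that("planted scenarios recover the right marker statuses end to end", {
  b <- hg38_build()
  g <- hg38_grid()
  mask <- exclusion_mask(g)
  specs <- scenario_library(0.6, seed = 5, build = b)
  sim <- simulate_bin_counts(specs[["gbm-like"]], grid = g)
  prof <- correct_bias(sim$counts, mask = mask)
  seg <- estimate_tumor_fraction(prof)
  tab <- call_markers(seg)
  expect_equal(tab$status[tab$marker_id == "CHR7"], "gain")
  expect_equal(tab$status[tab$marker_id == "CHR10"], "hemizygous_loss")
  expect_equal(tab$status[tab$marker_id == "EGFR"], "amplification")
  expect_true(attr(tab, "composites")$plus7_minus10)
  expect_false(attr(tab, "composites")$codeletion_1p19q)
})
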