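ctx <- function(idh) clinical_context(idh_status = idh)

test_that("the three canonical rule mappings hold", {
  # complete 1p/19q codeletion -> oligodendroglioma
  tab <- assemble_marker_table(fake_calls(arm_1p = "hemizygous_loss",
                                          arm_19q = "hemizygous_loss"))
  res <- classify_glioma(tab)
  expect_equal(res$suggestion, "oligodendroglioma")
  expect_equal(res$grade_hint, "no_grade4_cnv_evidence")
  expect_true("R1_codeletion_oligodendroglioma" %in% res$rules_fired$rule)

  # no codeletion + CDKN2A/B homozygous loss + IDH mutant -> astrocytoma grade 4
  tab2 <- assemble_marker_table(fake_calls(cdkn2ab = "homozygous_loss"))
  res2 <- classify_glioma(tab2, ctx("mutant"))
  expect_equal(res2$suggestion, "astrocytoma")
  expect_equal(res2$grade_hint, "grade_4_supported")
  expect_true("R4_cdkn2ab_homdel_grade4" %in% res2$rules_fired$rule)

  # +7/-10 + EGFR amplification + IDH wildtype -> molecular glioblastoma
  tab3 <- assemble_marker_table(fake_calls(egfr = "amplification",
                                           chr7 = "gain",
                                           chr10 = "hemizygous_loss"))
  res3 <- classify_glioma(tab3, ctx("wildtype"))
  expect_equal(res3$suggestion, "glioblastoma_molecular")
  expect_match(res3$rules_fired$evidence[res3$rules_fired$rule ==
                 "R3_plus7_minus10_egfr_gbm"], "EGFR amplification")

  # all neutral -> unclassified
  res4 <- classify_glioma(assemble_marker_table(fake_calls()))
  expect_equal(res4$suggestion, "unclassified_by_cnv")
})

test_that("the GBM rule takes precedence over astrocytoma when IDH is unknown", {
  tab <- assemble_marker_table(fake_calls(chr7 = "gain",
                                          chr10 = "hemizygous_loss"))
  res <- classify_glioma(tab, ctx("unknown"))
  expect_equal(res$suggestion, "glioblastoma_molecular")
  # but IDH mutant blocks it and falls back to astrocytoma
  res2 <- classify_glioma(tab, ctx("mutant"))
  expect_equal(res2$suggestion, "astrocytoma")
})

test_that("the engine is total and self-justifying over the status product", {
  arm <- c("hemizygous_loss", "neutral", "indeterminate")
  chr7s <- c("gain", "neutral", "indeterminate")
  chr10s <- c("hemizygous_loss", "neutral", "indeterminate")
  cdk <- c("homozygous_loss", "hemizygous_loss", "neutral", "indeterminate")
  egfr <- c("amplification", "neutral")
  idh <- c("mutant", "wildtype", "unknown")
  n_checked <- 0
  for (a1 in arm) for (a19 in arm) for (c7 in chr7s) for (c10 in chr10s)
    for (cd in cdk) for (eg in egfr) for (ii in idh) {
      tab <- assemble_marker_table(fake_calls(cdkn2ab = cd, egfr = eg,
                                              arm_1p = a1, arm_19q = a19,
                                              chr7 = c7, chr10 = c10))
      res <- classify_glioma(tab, ctx(ii))
      expect_true(res$suggestion %in% c("oligodendroglioma", "astrocytoma",
                                        "glioblastoma_molecular",
                                        "unclassified_by_cnv"))
      expect_true(res$grade_hint %in% c("grade_4_supported",
                                        "no_grade4_cnv_evidence",
                                        "indeterminate"))
      # every output justified by at least one fired rule
      expect_gte(nrow(res$rules_fired), 1)
      # consistency: grade-4 support iff CDKN2A/B homozygous loss, with evidence
      if (res$grade_hint == "grade_4_supported") {
        expect_equal(cd, "homozygous_loss")
        expect_true(any(grepl("CDKN2A/B homozygous_loss",
                              res$rules_fired$evidence)))
      }
      if (cd == "indeterminate") expect_equal(res$grade_hint, "indeterminate")
      # determinism
      res_b <- classify_glioma(tab, ctx(ii))
      expect_identical(res$rules_fired, res_b$rules_fired)
      n_checked <- n_checked + 1
    }
  expect_equal(n_checked, 3 * 3 * 3 * 3 * 4 * 2 * 3)
})

test_that("indeterminate composites never produce a definite codeletion call", {
  tab <- assemble_marker_table(fake_calls(arm_1p = "hemizygous_loss",
                                          arm_19q = "indeterminate"))
  res <- classify_glioma(tab)
  expect_false(res$suggestion == "oligodendroglioma")
})

test_that("classification serializes with disclaimer and stable rule ids", {
  tab <- assemble_marker_table(fake_calls(arm_1p = "hemizygous_loss",
                                          arm_19q = "hemizygous_loss"))
  res <- classify_glioma(tab)
  path <- withr::local_tempfile(fileext = ".json")
  write_classification(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$suggestion, "oligodendroglioma")
  expect_match(back$disclaimer, "not a diagnosis")
  expect_equal(back$rules_fired$rule[1], "R1_codeletion_oligodendroglioma")

  expect_equal(glance(res)$suggestion, "oligodendroglioma")
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("clinical context files parse with graceful fallback", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("idh_status: mutant", "sample_id: S1", "age: 54"), path)
  cc <- read_clinical_context(path)
  expect_equal(cc$idh_status, "mutant")
  expect_equal(attr(cc, "extra")$age, 54)

  writeLines(c("idh_status: bogus"), path)
  expect_equal(read_clinical_context(path)$idh_status, "unknown")
})
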