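#' Clinical context for classification
#'
#' Optional record accompanying a sample. IDH status cannot be determined
#' from copy number and is advisory only: rules degrade gracefully to
#' `"unknown"`.
#'
#' @param idh_status `"mutant"`, `"wildtype"` or `"unknown"`.
#' @param histology_note Free-text note carried into the report.
#' @param sample_id,patient Optional identifiers.
#' @return Named list of class `clinical_context`.
#' @export
clinical_context <- function(idh_status = c("unknown", "mutant", "wildtype"),
                             histology_note = "", sample_id = NULL,
                             patient = NULL) {
  idh_status <- match.arg(idh_status)
  structure(list(idh_status = idh_status, histology_note = histology_note,
                 sample_id = sample_id, patient = patient),
            class = "clinical_context")
}

#' Read a clinical-context key-value file
#'
#' Accepts a small YAML/JSON file or `key: value` lines; recognized keys are
#' `idh_status`, `histology_note`, `sample_id`, `patient`; everything else
#' is carried into the report header verbatim.
#'
#' @param path File path.
#' @return A `clinical_context` with extra keys in `attr(, "extra")`.
#' @export
read_clinical_context <- function(path) {
  vals <- yaml::read_yaml(path)
  ctx <- clinical_context(
    idh_status = if (!is.null(vals$idh_status) &&
                     vals$idh_status %in% c("mutant", "wildtype", "unknown"))
      vals$idh_status else "unknown",
    histology_note = vals$histology_note %||% "",
    sample_id = vals$sample_id, patient = vals$patient)
  attr(ctx, "extra") <- vals[setdiff(names(vals),
    c("idh_status", "histology_note", "sample_id", "patient"))]
  ctx
}

CLASSIFICATION_DISCLAIMER <- paste(
  "This is automated decision support based on copy-number evidence only;",
  "it is not a diagnosis. Integrate with histology, IDH/ATRX/TERT status",
  "and clinical findings per current WHO CNS guidance.")

#' Classify a glioma CNV profile
#'
#' Deterministic rule engine over the marker-table composites, encoding the
#' WHO-CNS5-style mapping from CNV markers to diffuse-glioma entities:
#' complete 1p/19q codeletion is the defining alteration of
#' oligodendroglioma; its absence with IDH-mutant (or unknown) status and
#' any CNV evidence suggests astrocytoma; the +7/-10 signature or EGFR
#' amplification with IDH-wildtype (or unknown) status suggests molecular
#' glioblastoma and takes precedence over the astrocytoma rule; homozygous
#' CDKN2A/B deletion supports WHO grade 4 regardless of entity.
#' Indeterminate composites propagate: no definite rule can fire on them.
#'
#' Rule ids (stable for audit): `R1_codeletion_oligodendroglioma`,
#' `R2_no_codeletion_astrocytoma`, `R3_plus7_minus10_egfr_gbm`,
#' `R4_cdkn2ab_homdel_grade4`.
#'
#' @param table A `marker_table` from [assemble_marker_table()].
#' @param context A [clinical_context()] (defaults to all-unknown).
#' @return Object of class `glioma_classification`: list with `suggestion`
#'   (`oligodendroglioma`, `astrocytoma`, `glioblastoma_molecular` or
#'   `unclassified_by_cnv`), `grade_hint` (`grade_4_supported`,
#'   `no_grade4_cnv_evidence` or `indeterminate`), `rules_fired` (tibble of
#'   rule id + evidence), `idh_status` and `disclaimer`.
#' @export
classify_glioma <- function(table, context = clinical_context()) {
  stopifnot(inherits(table, "marker_table"))
  comp <- marker_composites(table)
  status_of <- function(id) table$status[table$marker_id == id]
  idh <- context$idh_status

  rules <- list()
  fire <- function(id, evidence) {
    rules[[length(rules) + 1]] <<- tibble::tibble(rule = id, evidence = evidence)
  }

  cdkn2ab <- status_of("CDKN2AB")
  egfr <- status_of("EGFR")
  egfr_amp <- identical(egfr, "amplification")
  codel <- comp$codeletion_1p19q
  p7m10 <- comp$plus7_minus10

  any_evidence <- any(!(table$status %in% c("neutral", "indeterminate")))
  any_indeterminate <- any(table$status == "indeterminate") ||
    is.na(codel) || is.na(p7m10)

  suggestion <- "unclassified_by_cnv"
  if (isTRUE(codel)) {
    suggestion <- "oligodendroglioma"
    fire("R1_codeletion_oligodendroglioma",
         "complete 1p/19q codeletion (both arms lost)")
  } else {
    gbm_signal <- isTRUE(p7m10) || egfr_amp
    if (gbm_signal && idh %in% c("wildtype", "unknown")) {
      suggestion <- "glioblastoma_molecular"
      ev <- c(if (isTRUE(p7m10)) "+7/-10 signature",
              if (egfr_amp) "EGFR amplification")
      fire("R3_plus7_minus10_egfr_gbm",
           paste0(paste(ev, collapse = " and "), "; IDH ", idh,
                  if (idh == "unknown") " (takes precedence over astrocytoma rule)" else ""))
    } else if (isFALSE(codel) && idh %in% c("mutant", "unknown") && any_evidence) {
      suggestion <- "astrocytoma"
      fire("R2_no_codeletion_astrocytoma",
           paste0("CNV alterations without 1p/19q codeletion; IDH ", idh))
    }
  }
  if (suggestion == "unclassified_by_cnv") {
    fire("R0_no_rule",
         if (any_indeterminate && !any_evidence)
           "indeterminate marker input; no definite CNV evidence"
         else "no diagnostic CNV evidence")
  }

  if (identical(cdkn2ab, "homozygous_loss")) {
    grade_hint <- "grade_4_supported"
    fire("R4_cdkn2ab_homdel_grade4", "CDKN2A/B homozygous_loss")
  } else if (identical(cdkn2ab, "indeterminate")) {
    grade_hint <- "indeterminate"
  } else {
    grade_hint <- "no_grade4_cnv_evidence"
  }

  structure(
    list(suggestion = suggestion, grade_hint = grade_hint,
         rules_fired = dplyr::bind_rows(rules),
         idh_status = idh,
         disclaimer = CLASSIFICATION_DISCLAIMER),
    class = "glioma_classification")
}

#' @export
print.glioma_classification <- function(x, ...) {
  cat("<glioma_classification>\n")
  cat("  CNV-consistent-with:", x$suggestion, "\n")
  cat("  grade hint:", x$grade_hint, "\n")
  for (i in seq_len(nrow(x$rules_fired))) {
    cat("  -", x$rules_fired$rule[i], "::", x$rules_fired$evidence[i], "\n")
  }
  invisible(x)
}

#' @describeIn classify_glioma Fired rules as a tibble.
#' @param x A `glioma_classification`.
#' @param ... Unused.
#' @export
tidy.glioma_classification <- function(x, ...) x$rules_fired

#' @describeIn classify_glioma One-row summary.
#' @export
glance.glioma_classification <- function(x, ...) {
  tibble::tibble(suggestion = x$suggestion, grade_hint = x$grade_hint,
                 idh_status = x$idh_status, n_rules = nrow(x$rules_fired))
}

#' Serialize a classification result to JSON
#'
#' @param classification A `glioma_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  jsonlite::write_json(
    list(suggestion = classification$suggestion,
         grade_hint = classification$grade_hint,
         idh_status = classification$idh_status,
         rules_fired = classification$rules_fired,
         disclaimer = classification$disclaimer),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
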