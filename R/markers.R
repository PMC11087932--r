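#' Marker-calling configuration
#'
#' @param arm_call_threshold Fraction of valid arm/chromosome bins that must
#'   share a loss (or gain) state for the arm call (default 0.8); partial
#'   alterations in \[0.2, threshold) are surfaced in the evidence note
#'   instead of called.
#' @param amplification_state Minimum modal copy state for an EGFR
#'   amplification call (default 5, the capped top state) as opposed to a
#'   single-copy gain.
#' @param min_arm_bins Minimum valid bins for an arm/chromosome call
#'   (default 5); below it the call is indeterminate.
#' @return Named list.
#' @export
marker_config <- function(arm_call_threshold = 0.8, amplification_state = 5,
                          min_arm_bins = 5) {
  list(arm_call_threshold = arm_call_threshold,
       amplification_state = amplification_state,
       min_arm_bins = min_arm_bins)
}

marker_call_row <- function(marker_id, status, mean_copy = NA_real_,
                            fraction_altered = NA_real_, bins_used = 0L,
                            note = "") {
  tibble::tibble(marker_id = marker_id, status = status,
                 mean_copy = mean_copy,
                 fraction_of_bins_altered = fraction_altered,
                 bins_used = as.integer(bins_used), evidence_note = note)
}

#' Call a focal marker (CDKN2A/B or EGFR)
#'
#' The mean copy value over valid marker bins is `mean(2 * 2^log2_ratio)`.
#' CDKN2A/B status comes from [classify_deletion()] against the deletion
#' baseline at the sample's estimated tumor fraction (mapped to
#' `homozygous_loss` / `hemizygous_loss` / `neutral`). EGFR status follows
#' the modal copy state over marker bins: amplification at the capped top
#' state, gain at 3-4, neutral at 2, losses below.
#'
#' @param seg A `cnv_segmentation`.
#' @param marker_bins Bin ordinals from [locate_marker_bins()].
#' @param marker_id `"CDKN2AB"` or `"EGFR"`.
#' @param baseline A `deletion_baseline` (required for CDKN2A/B).
#' @param config A [marker_config()].
#' @return One-row marker-call tibble.
#' @export
call_focal_marker <- function(seg, marker_bins, marker_id, baseline = NULL,
                              config = marker_config()) {
  bins <- seg$bins
  ok <- marker_bins[bins$valid[marker_bins] & !is.na(bins$copy_state[marker_bins])]
  if (length(ok) == 0) {
    return(marker_call_row(marker_id, "indeterminate",
                           note = "no valid bins cover the marker"))
  }
  mean_copy <- mean(2 * 2^bins$log2_ratio[ok])
  states <- bins$copy_state[ok]
  modal <- as.integer(names(sort(table(states), decreasing = TRUE))[1])

  if (marker_id == "CDKN2AB") {
    if (is.null(baseline)) stop("CDKN2A/B calling requires a deletion baseline")
    # With a non-informative tumor fraction (all-diploid decode, estimate at
    # the grid floor) the homozygous/hemizygous/neutral expectations collapse
    # to within per-bin noise, so no baseline call is attempted. Otherwise
    # the admixture baseline types the locus even when the 2-bin focal event
    # is too short to overcome the Viterbi transition penalty.
    if (seg$non_informative) {
      status <- "neutral"
      note <- sprintf("tumor fraction non-informative; no deletion typing (copy %.2f)",
                      mean_copy)
    } else {
      del <- classify_deletion(mean_copy, seg$tumor_fraction, baseline)
      status <- switch(del, homozygous = "homozygous_loss",
                       hemizygous = "hemizygous_loss", none = "neutral")
      note <- sprintf("copy %.2f vs homozygous expectation %.2f at t=%.2f",
                      mean_copy, predict_baseline(baseline, seg$tumor_fraction),
                      seg$tumor_fraction)
    }
  } else {
    status <- if (modal >= config$amplification_state) "amplification"
      else if (modal %in% c(3, 4)) "gain"
      else if (modal == 2) "neutral"
      else if (modal == 1) "hemizygous_loss"
      else "homozygous_loss"
    note <- sprintf("modal copy state %d, copy %.2f", modal, mean_copy)
  }
  marker_call_row(marker_id, status, mean_copy = mean_copy,
                  fraction_altered = mean(states != 2),
                  bins_used = length(ok), note = note)
}

#' Call an arm-level or whole-chromosome marker
#'
#' Counts the fraction of valid marker bins in a loss (`copy_state < 2`) or
#' gain (`> 2`) state. A call requires the fraction to reach
#' `arm_call_threshold` (complete arm events, as diagnostically required for
#' 1p/19q); partial alterations between 0.2 and the threshold are recorded
#' in the evidence note but left neutral.
#'
#' @inheritParams call_focal_marker
#' @param marker_id `"ARM_1P"`, `"ARM_19Q"`, `"CHR7"` or `"CHR10"`.
#' @return One-row marker-call tibble.
#' @export
call_arm_marker <- function(seg, marker_bins, marker_id,
                            config = marker_config()) {
  bins <- seg$bins
  ok <- marker_bins[bins$valid[marker_bins] & !is.na(bins$copy_state[marker_bins])]
  if (length(ok) < config$min_arm_bins) {
    return(marker_call_row(marker_id, "indeterminate",
                           note = sprintf("only %d valid bins (need >= %d)",
                                          length(ok), config$min_arm_bins)))
  }
  states <- bins$copy_state[ok]
  loss_frac <- mean(states < 2)
  gain_frac <- mean(states > 2)
  mean_copy <- mean(2 * 2^bins$log2_ratio[ok])
  thr <- config$arm_call_threshold

  note <- ""
  if (loss_frac >= thr) {
    status <- "hemizygous_loss"
    frac <- loss_frac
  } else if (gain_frac >= thr) {
    status <- if (median(states[states > 2]) >= config$amplification_state)
      "amplification" else "gain"
    frac <- gain_frac
  } else {
    status <- "neutral"
    frac <- max(loss_frac, gain_frac)
    if (loss_frac >= 0.2) {
      note <- sprintf("partial loss: %.0f%% of bins below diploid (threshold %.0f%%)",
                      100 * loss_frac, 100 * thr)
    } else if (gain_frac >= 0.2) {
      note <- sprintf("partial gain: %.0f%% of bins above diploid (threshold %.0f%%)",
                      100 * gain_frac, 100 * thr)
    }
  }
  marker_call_row(marker_id, status, mean_copy = mean_copy,
                  fraction_altered = frac, bins_used = length(ok), note = note)
}

loss_statuses <- c("hemizygous_loss", "homozygous_loss")
gain_statuses <- c("gain", "amplification")

#' Assemble per-marker calls into a marker table
#'
#' Adds the two diagnostic composites: `codeletion_1p19q` is `TRUE` only
#' when both 1p and 19q are called losses, and `plus7_minus10` only when
#' chromosome 7 is gained/amplified and chromosome 10 lost. Any
#' indeterminate input propagates to an indeterminate (`NA`) composite.
#'
#' @param calls Tibble with exactly one row per catalog marker
#'   (`CDKN2AB`, `EGFR`, `ARM_1P`, `ARM_19Q`, `CHR7`, `CHR10`).
#' @return Object of class `marker_table`: the calls tibble with composites
#'   in `attr(, "composites")`.
#' @export
assemble_marker_table <- function(calls) {
  required <- c("CDKN2AB", "EGFR", "ARM_1P", "ARM_19Q", "CHR7", "CHR10")
  missing <- setdiff(required, calls$marker_id)
  if (length(missing)) {
    stop("missing marker call(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(calls$marker_id)) stop("duplicate marker calls")

  status_of <- function(id) calls$status[calls$marker_id == id]
  comp <- function(a, b, ok_a, ok_b) {
    if (a == "indeterminate" || b == "indeterminate") return(NA)
    (a %in% ok_a) && (b %in% ok_b)
  }
  codeletion <- comp(status_of("ARM_1P"), status_of("ARM_19Q"),
                     loss_statuses, loss_statuses)
  plus7_minus10 <- comp(status_of("CHR7"), status_of("CHR10"),
                        gain_statuses, loss_statuses)
  structure(calls,
            composites = list(codeletion_1p19q = codeletion,
                              plus7_minus10 = plus7_minus10),
            class = c("marker_table", class(tibble::tibble())))
}

marker_composites <- function(table) attr(table, "composites", exact = TRUE)

#' Call all catalog markers from a segmentation
#'
#' Convenience wrapper running [call_focal_marker()] and [call_arm_marker()]
#' for every catalog entry and assembling the [assemble_marker_table()].
#'
#' @param seg A `cnv_segmentation`.
#' @param baseline A `deletion_baseline` for CDKN2A/B typing.
#' @param config A [marker_config()].
#' @return A `marker_table`.
#' @export
call_markers <- function(seg, baseline = default_baseline(),
                         config = marker_config()) {
  grid <- attr(seg$bins, "grid", exact = TRUE)
  catalog <- marker_catalog(grid_build(grid))
  calls <- purrr::map_dfr(unique(catalog$marker_id), function(id) {
    mb <- locate_marker_bins(grid, id, catalog = catalog)
    kind <- catalog$kind[catalog$marker_id == id][1]
    if (kind == "focal") {
      call_focal_marker(seg, mb, id, baseline = baseline, config = config)
    } else {
      call_arm_marker(seg, mb, id, config = config)
    }
  })
  assemble_marker_table(calls)
}

#' Export a marker table
#'
#' @param table A `marker_table`.
#' @param path Output path (`.tsv` or `.json` chosen by `format`).
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tibble::as_tibble(table), path)
  } else {
    comp <- marker_composites(table)
    jsonlite::write_json(
      list(markers = tibble::as_tibble(table),
           composites = list(
             codeletion_1p19q = if (is.na(comp$codeletion_1p19q)) "indeterminate"
               else comp$codeletion_1p19q,
             plus7_minus10 = if (is.na(comp$plus7_minus10)) "indeterminate"
               else comp$plus7_minus10)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
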