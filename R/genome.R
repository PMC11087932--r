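#' Reference genome builds
#'
#' A genome build bundles the chromosome lengths, chromosome-arm boundaries
#' (the centromere midpoint) and centromeric gap intervals needed to tile the
#' genome into fixed-width bins and to exclude unreliable pericentromeric
#' windows. Tables for hg19 and hg38 (chr1-chr22, chrX, chrY) ship with the
#' package; all three tables can be overridden with user-supplied files in
#' the same plain-text formats (UCSC `chrom.sizes`, BED).
#'
#' @param name Build name, `"hg19"` or `"hg38"`, or an arbitrary label when
#'   all three tables are supplied explicitly.
#' @param chrom_sizes Optional path to a two-column `chrom.sizes` file
#'   (chromosome, length) overriding the packaged table.
#' @param gaps Optional path to a BED file of centromere/gap intervals
#'   (0-based half-open) overriding the packaged table.
#' @param markers Optional path to a 4-column BED (chrom, start, end, name)
#'   with focal marker coordinates overriding the packaged table.
#'
#' @return An object of class `genome_build`: a list with `name`,
#'   `chrom_lengths` (named numeric), `arm_boundaries` (named numeric,
#'   centromere midpoints), `gaps` (tibble chrom/start/end) and `markers`
#'   (tibble chrom/start/end/marker_id).
#' @examples
#' b <- genome_build("hg38")
#' head(b$chrom_lengths)
#' @export
genome_build <- function(name = c("hg38", "hg19"),
                         chrom_sizes = NULL, gaps = NULL, markers = NULL) {
  if (is.null(chrom_sizes) || is.null(gaps) || is.null(markers)) {
    name <- match.arg(name)
  }
  pkg_file <- function(f) system.file("extdata", f, package = "gliomacnv", mustWork = TRUE)
  chrom_sizes <- chrom_sizes %||% pkg_file(paste0(name, ".chrom.sizes"))
  gaps <- gaps %||% pkg_file(paste0(name, ".gaps.bed"))
  markers <- markers %||% pkg_file(paste0(name, ".markers.bed"))

  sizes <- readr::read_tsv(chrom_sizes, col_names = c("chrom", "length"),
                           col_types = "cd", progress = FALSE)
  gap_tbl <- readr::read_tsv(gaps, col_names = c("chrom", "start", "end", "name"),
                             col_types = "cddc", progress = FALSE)
  mk_tbl <- readr::read_tsv(markers, col_names = c("chrom", "start", "end", "marker_id"),
                            col_types = "cddc", progress = FALSE)

  if (nrow(sizes) == 0) stop("invalid build: no chromosomes in ", chrom_sizes)
  lens <- setNames(sizes$length, sizes$chrom)

  cen <- gap_tbl[gap_tbl$name == "centromere", , drop = FALSE]
  arms <- setNames((cen$start + cen$end) / 2, cen$chrom)
  bad <- names(arms)[arms <= 0 | arms >= lens[names(arms)]]
  if (length(bad)) stop("arm boundary outside chromosome for: ", paste(bad, collapse = ", "))
  if (any(gap_tbl$start < 0 | gap_tbl$end > lens[gap_tbl$chrom] | gap_tbl$end < gap_tbl$start)) {
    stop("gap interval outside chromosome bounds")
  }

  structure(
    list(name = name, chrom_lengths = lens, arm_boundaries = arms,
         gaps = tibble::as_tibble(gap_tbl[, c("chrom", "start", "end")]),
         markers = tibble::as_tibble(mk_tbl)),
    class = "genome_build"
  )
}

#' @export
print.genome_build <- function(x, ...) {
  cat("<genome_build>", x$name, "-", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  invisible(x)
}

#' Construct a small in-memory genome build
#'
#' Convenience constructor for toy builds used in examples and simulations.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param arm_boundaries Named numeric vector of centromere midpoints;
#'   defaults to the chromosome midpoint for each chromosome.
#' @param gaps Tibble/data frame with `chrom`, `start`, `end` (0-based
#'   half-open); defaults to no gaps.
#' @param markers Tibble/data frame with `chrom`, `start`, `end`,
#'   `marker_id`; defaults to none.
#' @param name Label for the build.
#' @return A `genome_build`.
#' @examples
#' toy_build(c(chrA = 2e6, chrB = 1e6))
#' @export
toy_build <- function(chrom_lengths, arm_boundaries = NULL, gaps = NULL,
                      markers = NULL, name = "toy") {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  arm_boundaries <- arm_boundaries %||% (chrom_lengths / 2)
  gaps <- tibble::as_tibble(gaps %||%
    tibble::tibble(chrom = character(), start = double(), end = double()))
  markers <- tibble::as_tibble(markers %||%
    tibble::tibble(chrom = character(), start = double(), end = double(),
                   marker_id = character()))
  structure(
    list(name = name, chrom_lengths = chrom_lengths,
         arm_boundaries = arm_boundaries, gaps = gaps, markers = markers),
    class = "genome_build"
  )
}

#' Tile a genome build into fixed-width bins
#'
#' Each chromosome is tiled left to right with `bin_size`-bp windows
#' (0-based half-open); the last bin of a chromosome is truncated at the
#' chromosome end, so per-chromosome bin widths always sum exactly to the
#' chromosome length.
#'
#' @param build A [genome_build()] or [toy_build()].
#' @param bin_size Window width in bp (default 500 kb).
#' @return A tibble of class `bin_grid` with columns `chrom`, `start`, `end`
#'   and `bin` (1-based genome-wide ordinal), plus the build stored in
#'   attributes (`build`, `bin_size`).
#' @examples
#' g <- bin_grid(toy_build(c(chrA = 1234567)), 5e5)
#' g
#' @export
bin_grid <- function(build, bin_size = 5e5) {
  if (!inherits(build, "genome_build")) stop("`build` must be a genome_build")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1e4) {
    stop("invalid bin_size: must be a single number >= 10000")
  }
  if (length(build$chrom_lengths) < 1) stop("invalid build: no chromosomes")

  grid <- purrr::map2_dfr(names(build$chrom_lengths), build$chrom_lengths, function(chrom, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(chrom = chrom, start = starts, end = pmin(starts + bin_size, len))
  })
  grid$bin <- seq_len(nrow(grid))
  structure(grid, build = build, bin_size = bin_size,
            class = c("bin_grid", class(tibble::tibble())))
}

grid_build <- function(grid) attr(grid, "build", exact = TRUE)
grid_bin_size <- function(grid) attr(grid, "bin_size", exact = TRUE)

assert_same_grid <- function(a, b) {
  ga <- if (inherits(a, "bin_grid")) a else attr(a, "grid", exact = TRUE)
  gb <- if (inherits(b, "bin_grid")) b else attr(b, "grid", exact = TRUE)
  if (nrow(ga) != nrow(gb) || !identical(ga$chrom, gb$chrom) ||
      !identical(ga$start, gb$start)) {
    stop("bin grids do not match (different build or bin size)")
  }
  invisible(TRUE)
}

#' The glioma CNV marker catalog
#'
#' Resolves the six diagnostic markers to genomic regions on a build: the
#' focal markers CDKN2A/B (9p21.3) and EGFR (7p11.2) come from the build's
#' marker table; 1p and 19q are the regions from the chromosome start (or
#' centromere) to the arm boundary (or chromosome end); chromosomes 7 and 10
#' span whole chromosomes.
#'
#' @param build A `genome_build`.
#' @return Tibble with `marker_id`, `kind` (focal/arm/whole_chromosome),
#'   `chrom`, `start`, `end`.
#' @examples
#' marker_catalog(genome_build("hg38"))
#' @export
marker_catalog <- function(build) {
  chr_name <- function(base) {
    if (base %in% names(build$chrom_lengths)) return(base)
    alt <- sub("^chr", "", base)
    if (alt %in% names(build$chrom_lengths)) return(alt)
    NA_character_
  }
  focal <- build$markers
  rows <- list()
  for (i in seq_len(nrow(focal))) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker_id = focal$marker_id[i], kind = "focal",
      chrom = focal$chrom[i], start = focal$start[i], end = focal$end[i])
  }
  c1 <- chr_name("chr1"); c19 <- chr_name("chr19")
  c7 <- chr_name("chr7"); c10 <- chr_name("chr10")
  if (!is.na(c1)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker_id = "ARM_1P", kind = "arm", chrom = c1,
      start = 0, end = build$arm_boundaries[[c1]])
  }
  if (!is.na(c19)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker_id = "ARM_19Q", kind = "arm", chrom = c19,
      start = build$arm_boundaries[[c19]], end = build$chrom_lengths[[c19]])
  }
  if (!is.na(c7)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker_id = "CHR7", kind = "whole_chromosome", chrom = c7,
      start = 0, end = build$chrom_lengths[[c7]])
  }
  if (!is.na(c10)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      marker_id = "CHR10", kind = "whole_chromosome", chrom = c10,
      start = 0, end = build$chrom_lengths[[c10]])
  }
  empty <- tibble::tibble(marker_id = character(), kind = character(),
                          chrom = character(), start = double(), end = double())
  dplyr::bind_rows(c(list(empty), rows))
}

#' Locate the bins overlapping a marker region
#'
#' Returns every bin whose half-open interval overlaps the marker's region
#' on the grid's build, as strictly increasing genome-wide bin ordinals.
#'
#' @param grid A [bin_grid()].
#' @param marker_id One of `"CDKN2AB"`, `"EGFR"`, `"ARM_1P"`, `"ARM_19Q"`,
#'   `"CHR7"`, `"CHR10"` (or any id present in the build's marker table).
#' @param catalog Optional precomputed [marker_catalog()] for the grid's
#'   build.
#' @return Integer vector of bin ordinals (1-based, non-empty).
#' @export
locate_marker_bins <- function(grid, marker_id, catalog = NULL) {
  catalog <- catalog %||% marker_catalog(grid_build(grid))
  hit <- catalog[catalog$marker_id == marker_id, , drop = FALSE]
  if (nrow(hit) == 0) stop("unknown marker id: ", marker_id)
  bins <- integer()
  for (i in seq_len(nrow(hit))) {
    if (!hit$chrom[i] %in% grid$chrom) {
      stop("marker ", marker_id, " lies on ", hit$chrom[i],
           ", which is absent from the grid's build")
    }
    sel <- grid$chrom == hit$chrom[i] & grid$start < hit$end[i] & grid$end > hit$start[i]
    bins <- c(bins, grid$bin[sel])
  }
  bins <- sort(unique(bins))
  if (length(bins) == 0) stop("marker ", marker_id, " overlaps no bins on this grid")
  bins
}

#' Centromere/gap exclusion mask
#'
#' Marks every bin overlapping a gap interval of the build, plus
#' `padding_bins` neighboring bins on each side within the same chromosome.
#' Pericentromeric windows carry unreliable counts and are excluded from
#' correction and segmentation.
#'
#' @param grid A [bin_grid()].
#' @param padding_bins Non-negative number of flanking bins to exclude on
#'   each side of a gap-overlapping bin (default 1).
#' @return Logical vector over the grid's bins; `TRUE` = excluded.
#' @export
exclusion_mask <- function(grid, padding_bins = 1) {
  stopifnot(padding_bins >= 0)
  gaps <- grid_build(grid)$gaps
  mask <- rep(FALSE, nrow(grid))
  if (nrow(gaps) == 0) return(mask)
  for (i in seq_len(nrow(gaps))) {
    sel <- grid$chrom == gaps$chrom[i] & grid$start < gaps$end[i] & grid$end > gaps$start[i]
    mask[sel] <- TRUE
  }
  if (padding_bins > 0) {
    padded <- mask
    for (chrom in unique(grid$chrom[mask])) {
      idx <- which(grid$chrom == chrom)
      hit <- which(mask[idx])
      for (h in hit) {
        lo <- max(1L, h - padding_bins)
        hi <- min(length(idx), h + padding_bins)
        padded[idx[lo:hi]] <- TRUE
      }
    }
    mask <- padded
  }
  mask
}
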