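#' Construct a per-bin read-count profile
#'
#' @param grid A [bin_grid()].
#' @param counts Numeric vector, one non-negative value per grid bin
#'   (`NA` = bin missing from the source).
#' @param gc,mappability Optional per-bin fractions in \[0, 1\] (`NA` where
#'   unknown).
#' @param total_reads Total records scanned in the source
#'   (>= sum of counts; filtered reads are dropped, never re-counted).
#' @param sample_id Sample label carried through to exports.
#' @return A tibble of class `bin_counts` with columns `chrom`, `start`,
#'   `end`, `bin`, `count`, `gc`, `mappability`; grid, sample id and totals
#'   in attributes.
#' @export
bin_counts <- function(grid, counts, gc = NULL, mappability = NULL,
                       total_reads = sum(counts, na.rm = TRUE),
                       sample_id = "sample") {
  stopifnot(inherits(grid, "bin_grid"), length(counts) == nrow(grid))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  gc <- gc %||% rep(NA_real_, nrow(grid))
  mappability <- mappability %||% rep(NA_real_, nrow(grid))
  stopifnot(length(gc) == nrow(grid), length(mappability) == nrow(grid))
  if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc must lie in [0, 1]")
  if (any(mappability < 0 | mappability > 1, na.rm = TRUE)) {
    stop("mappability must lie in [0, 1]")
  }
  out <- tibble::tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                        bin = grid$bin, count = as.numeric(counts),
                        gc = as.numeric(gc), mappability = as.numeric(mappability))
  structure(out, grid = grid, sample_id = sample_id,
            total_reads = total_reads,
            class = c("bin_counts", class(tibble::tibble())))
}

counts_grid <- function(x) attr(x, "grid", exact = TRUE)

#' Write a bin-count profile as fixed-step WIG
#'
#' One `fixedStep` declaration per chromosome with 1-based starts and
#' `step == span == bin_size`. Integer counts round-trip bit-exactly through
#' [read_wig()].
#'
#' @param counts A [bin_counts()] profile.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wig <- function(counts, path) {
  grid <- counts_grid(counts)
  step <- grid_bin_size(grid)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("track type=wiggle_0 name=", attr(counts, "sample_id", exact = TRUE)), con)
  for (chrom in unique(grid$chrom)) {
    sel <- counts$chrom == chrom
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       chrom, as.integer(step), as.integer(step)), con)
    vals <- counts$count[sel]
    writeLines(ifelse(is.na(vals), "NA", format(vals, scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

#' Read a fixed-step WIG file onto a bin grid
#'
#' The file must declare `step == span == bin_size` of the grid. WIG uses
#' 1-based starts; values are mapped onto the 0-based half-open grid bins.
#' Chromosomes absent from the file get `NA` counts.
#'
#' @param path Path to a fixedStep WIG file.
#' @param grid A [bin_grid()].
#' @param sample_id Sample label for the returned profile.
#' @return A [bin_counts()] profile.
#' @export
read_wig <- function(path, grid, sample_id = basename(path)) {
  vals <- parse_fixedstep_wig(path, grid)
  bin_counts(grid, vals, sample_id = sample_id,
             total_reads = sum(vals, na.rm = TRUE))
}

parse_fixedstep_wig <- function(path, grid) {
  lines <- readLines(path)
  step <- grid_bin_size(grid)
  vals <- rep(NA_real_, nrow(grid))
  chrom <- NULL; pos0 <- NA_real_; wstep <- NA_real_
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "track") || startsWith(line, "#")) next
    if (startsWith(line, "fixedStep")) {
      kv <- strsplit(strsplit(line, "\\s+")[[1]][-1], "=")
      if (any(lengths(kv) != 2)) {
        stop("malformed fixedStep header at line ", ln, ": ", line)
      }
      fields <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      if (!all(c("chrom", "start", "step") %in% names(fields))) {
        stop("malformed fixedStep header at line ", ln, ": ", line)
      }
      chrom <- fields[["chrom"]]
      wstep <- as.numeric(fields[["step"]])
      wspan <- as.numeric(fields[["span"]] %||% wstep)
      if (wstep != step || wspan != step) {
        stop("WIG step/span (", format(wstep, scientific = FALSE), "/",
             format(wspan, scientific = FALSE),
             ") do not match grid bin size (",
             format(step, scientific = FALSE), ")")
      }
      pos0 <- as.numeric(fields[["start"]]) - 1  # 1-based WIG -> 0-based grid
      if (is.na(pos0) || pos0 < 0) stop("malformed start at line ", ln)
      next
    }
    if (is.null(chrom)) stop("value before any fixedStep header at line ", ln)
    v <- suppressWarnings(as.numeric(line))
    idx <- which(grid$chrom == chrom & grid$start == pos0)
    if (length(idx) == 1) vals[idx] <- v
    pos0 <- pos0 + wstep
  }
  vals
}

#' Read a per-bin value track (WIG or 4-column TSV)
#'
#' Accepts either a fixedStep WIG aligned to the grid or a headerless
#' 4-column TSV (`chrom`, `start`, `end`, `value`, 0-based half-open) whose
#' intervals match grid bins by (chrom, start).
#'
#' @param path Track file path.
#' @param grid A [bin_grid()].
#' @return Numeric vector over grid bins (`NA` where the track has no value).
#' @export
read_track <- function(path, grid) {
  first <- readLines(path, n = 5)
  if (any(grepl("^fixedStep", first))) return(parse_fixedstep_wig(path, grid))
  tbl <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                         col_types = "cddd", progress = FALSE)
  key <- paste(grid$chrom, grid$start)
  vals <- rep(NA_real_, nrow(grid))
  m <- match(key, paste(tbl$chrom, tbl$start))
  vals[!is.na(m)] <- tbl$value[m[!is.na(m)]]
  vals
}

#' Write a per-bin value track as 4-column TSV
#'
#' Inverse of [read_track()] (TSV flavor): `chrom`, `start`, `end`, `value`
#' with 0-based half-open intervals, one row per grid bin with a value.
#'
#' @param values Numeric vector over grid bins.
#' @param grid A [bin_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(values, grid, path) {
  stopifnot(length(values) == nrow(grid))
  keep <- !is.na(values)
  readr::write_tsv(
    tibble::tibble(chrom = grid$chrom[keep], start = grid$start[keep],
                   end = grid$end[keep], value = values[keep]),
    path, col_names = FALSE)
  invisible(path)
}

#' Annotate a count profile with GC and mappability tracks
#'
#' @param counts A [bin_counts()] profile.
#' @param gc_track,map_track Per-bin value tracks: a file path (WIG or
#'   4-column TSV, see [read_track()]), a numeric vector over grid bins, or
#'   `NULL` to leave the field untouched.
#' @return The profile with `gc` / `mappability` columns populated
#'   (`NA` where a track has no value for a bin).
#' @export
annotate_gc_mappability <- function(counts, gc_track = NULL, map_track = NULL) {
  grid <- counts_grid(counts)
  resolve <- function(track) {
    if (is.null(track)) return(NULL)
    if (is.character(track) && length(track) == 1) return(read_track(track, grid))
    if (is.numeric(track)) {
      if (length(track) != nrow(grid)) {
        stop("track length (", length(track), ") does not match grid (", nrow(grid), " bins)")
      }
      return(as.numeric(track))
    }
    stop("track must be a file path or a numeric vector over grid bins")
  }
  gc <- resolve(gc_track)
  mp <- resolve(map_track)
  if (!is.null(gc)) {
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("gc values must lie in [0, 1]")
    counts$gc <- gc
  }
  if (!is.null(mp)) {
    if (any(mp < 0 | mp > 1, na.rm = TRUE)) stop("mappability values must lie in [0, 1]")
    counts$mappability <- mp
  }
  counts
}
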