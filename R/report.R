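status_colors <- c(
  amplification = "#b2182b",
  gain = "#ef8a62",
  neutral = "#999999",
  hemizygous_loss = "#67a9cf",
  homozygous_loss = "#2166ac",
  indeterminate = "#cccccc"
)

altered_statuses <- c("amplification", "gain", "hemizygous_loss", "homozygous_loss")

genome_coords <- function(bins) {
  chroms <- unique(bins$chrom)
  offsets <- c(0, cumsum(vapply(chroms, function(ch) max(bins$end[bins$chrom == ch]), 0)))
  names(offsets) <- c(chroms, "END")
  list(offset = offsets[seq_along(chroms)], chroms = chroms,
       total = offsets[[length(offsets)]])
}

#' Genome-wide copy-number plot
#'
#' Scatter of per-bin log2 ratios in genome order with chromosome
#' boundaries, decoded segment means overlaid, and catalog marker regions
#' highlighted by call status (neutral and indeterminate markers are not
#' highlighted, so an unaltered genome shows no colored spans).
#'
#' @param object A `cnv_segmentation`.
#' @param table Optional `marker_table` supplying the highlight statuses.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_segmentation <- function(object, table = NULL, ...) {
  bins <- object$bins
  co <- genome_coords(bins)
  bins$gx <- (bins$start + bins$end) / 2 + co$offset[bins$chrom]
  segs <- object$segments
  segs$gx1 <- segs$start + co$offset[segs$chrom]
  segs$gx2 <- segs$end + co$offset[segs$chrom]

  p <- ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = unname(co$offset[-1]),
                        color = "grey85", linewidth = 0.3)

  if (!is.null(table)) {
    grid <- attr(bins, "grid", exact = TRUE)
    catalog <- marker_catalog(grid_build(grid))
    hl <- dplyr::inner_join(tibble::as_tibble(table),
                            catalog[, c("marker_id", "chrom", "start", "end")],
                            by = "marker_id")
    hl <- hl[hl$status %in% altered_statuses, , drop = FALSE]
    if (nrow(hl) > 0) {
      hl$gx1 <- hl$start + co$offset[hl$chrom]
      hl$gx2 <- hl$end + co$offset[hl$chrom]
      p <- p + ggplot2::geom_rect(
        data = hl,
        ggplot2::aes(xmin = .data$gx1, xmax = .data$gx2,
                     ymin = -Inf, ymax = Inf, fill = .data$status),
        alpha = 0.35) +
        ggplot2::geom_text(
          data = hl,
          ggplot2::aes(x = (.data$gx1 + .data$gx2) / 2, y = Inf,
                       label = .data$marker_id),
          vjust = 1.2, size = 2.6)
    }
  }

  p +
    ggplot2::geom_point(data = bins[bins$valid, ],
                        ggplot2::aes(x = .data$gx, y = .data$log2_ratio),
                        size = 0.3, alpha = 0.5, color = "grey40") +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$gx1, xend = .data$gx2,
                                       y = .data$mean_log2, yend = .data$mean_log2),
                          color = "#d7301f", linewidth = 0.9) +
    ggplot2::scale_fill_manual(values = status_colors, guide = "none") +
    ggplot2::scale_x_continuous(
      breaks = unname(co$offset + diff(c(co$offset, co$total)) / 2),
      labels = sub("^chr", "", co$chroms),
      expand = c(0.01, 0)) +
    ggplot2::labs(
      x = "chromosome", y = "log2 copy ratio",
      title = sprintf("%s - tumor fraction %.2f%s", object$sample_id,
                      object$tumor_fraction,
                      if (object$non_informative) " (non-informative)" else "")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid.major.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' Render the genome plot to SVG and PNG
#'
#' @param seg A `cnv_segmentation`.
#' @param table Optional `marker_table` for highlights.
#' @param svg_path,png_path Output paths (`NULL` skips that format).
#' @param width,height Figure size in inches.
#' @return Invisible character vector of the files written.
#' @export
render_genome_plot <- function(seg, table = NULL, svg_path = NULL,
                               png_path = NULL, width = 10, height = 3.5) {
  p <- autoplot(seg, table = table)
  written <- character()
  if (!is.null(svg_path)) {
    grDevices::svg(svg_path, width = width, height = height)
    print(p)
    grDevices::dev.off()
    written <- c(written, svg_path)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = width, height = height, units = "in",
                   res = 150)
    print(p)
    grDevices::dev.off()
    written <- c(written, png_path)
  }
  invisible(written)
}

#' Bundle everything a report needs
#'
#' @param sample_header Named list of sample metadata rendered in the
#'   header section.
#' @param plot_png Path to the rendered genome plot PNG (inlined base64
#'   into the report).
#' @param marker_table A `marker_table`.
#' @param classification A `glioma_classification`.
#' @param tool_version Version string (default: installed package version).
#' @param run_config_digest Digest of the run configuration.
#' @param timestamp Footer timestamp string, or `FALSE` to suppress for
#'   byte-reproducible reports.
#' @return Named list of class `report_bundle`.
#' @export
report_bundle <- function(sample_header, plot_png, marker_table,
                          classification,
                          tool_version = as.character(packageVersion("gliomacnv")),
                          run_config_digest = "unspecified",
                          timestamp = FALSE) {
  structure(list(sample_header = sample_header, plot_png = plot_png,
                 marker_table = marker_table, classification = classification,
                 tool_version = tool_version,
                 run_config_digest = run_config_digest, timestamp = timestamp),
            class = "report_bundle")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the single-file HTML report
#'
#' A self-contained HTML document with four sections, in order: sample
#' information header, visualization (the genome-wide CNV plot, inlined),
#' marker status table (altered markers styled as red alert rows), and the
#' classification/grading summary with fired rules and disclaimer. All
#' assets are inlined, so the single file is portable.
#'
#' @param bundle A [report_bundle()].
#' @param out_path Output HTML path.
#' @return `out_path`, invisibly.
#' @export
render_html_report <- function(bundle, out_path) {
  required <- c("sample_header", "plot_png", "marker_table", "classification",
                "tool_version", "run_config_digest")
  missing <- required[vapply(required, function(f) is.null(bundle[[f]]), TRUE)]
  if (length(missing)) {
    stop("report bundle is missing field(s): ", paste(missing, collapse = ", "))
  }
  if (!file.exists(bundle$plot_png)) stop("plot file not found: ", bundle$plot_png)

  header_rows <- paste(vapply(names(bundle$sample_header), function(k) {
    sprintf("<tr><th>%s</th><td>%s</td></tr>", html_escape(k),
            html_escape(bundle$sample_header[[k]]))
  }, ""), collapse = "\n")

  tbl <- tibble::as_tibble(bundle$marker_table)
  marker_rows <- paste(vapply(seq_len(nrow(tbl)), function(i) {
    alert <- tbl$status[i] %in% altered_statuses
    sprintf(
      '<tr class="%s"><td>%s</td><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>',
      if (alert) "alert" else "normal",
      html_escape(tbl$marker_id[i]), html_escape(tbl$status[i]),
      ifelse(is.na(tbl$mean_copy[i]), "-", sprintf("%.2f", tbl$mean_copy[i])),
      ifelse(is.na(tbl$fraction_of_bins_altered[i]), "-",
             sprintf("%.2f", tbl$fraction_of_bins_altered[i])),
      html_escape(tbl$evidence_note[i]))
  }, ""), collapse = "\n")

  comp <- marker_composites(bundle$marker_table)
  fmt_comp <- function(v) if (is.na(v)) "indeterminate" else if (v) "yes" else "no"
  cls <- bundle$classification
  rule_items <- paste(vapply(seq_len(nrow(cls$rules_fired)), function(i) {
    sprintf("<li><code>%s</code>: %s</li>", html_escape(cls$rules_fired$rule[i]),
            html_escape(cls$rules_fired$evidence[i]))
  }, ""), collapse = "\n")

  img <- jsonlite::base64_enc(readBin(bundle$plot_png, "raw",
                                      file.size(bundle$plot_png)))
  footer <- sprintf("gliomacnv %s | config %s%s",
                    html_escape(bundle$tool_version),
                    html_escape(bundle$run_config_digest),
                    if (isFALSE(bundle$timestamp)) ""
                    else paste0(" | generated ", html_escape(bundle$timestamp)))

  html <- glue::glue('<!DOCTYPE html>
<html lang="en">
<head>
<meta charset="utf-8"/>
<title>CNV marker report</title>
<style>
body {{ font-family: Helvetica, Arial, sans-serif; margin: 2em; color: #222; }}
section {{ margin-bottom: 2em; }}
h2 {{ border-bottom: 2px solid #2166ac; padding-bottom: 0.2em; }}
table {{ border-collapse: collapse; }}
th, td {{ border: 1px solid #ccc; padding: 0.35em 0.7em; text-align: left; }}
tr.alert td {{ background: #fddede; color: #b2182b; font-weight: bold; }}
.disclaimer {{ font-size: 0.85em; color: #666; font-style: italic; }}
footer {{ font-size: 0.8em; color: #999; border-top: 1px solid #eee; }}
img {{ max-width: 100%; }}
</style>
</head>
<body>
<section id="sample-information">
<h2>Sample Information</h2>
<table>{header_rows}</table>
</section>
<section id="visualization">
<h2>Genome-Wide Copy-Number Profile</h2>
<img alt="genome-wide CNV plot" src="data:image/png;base64,{img}"/>
</section>
<section id="marker-status">
<h2>Glioma CNV Marker Status</h2>
<table>
<tr><th>marker</th><th>status</th><th>mean copy</th><th>fraction altered</th><th>note</th></tr>
{marker_rows}
</table>
<p>1p/19q codeletion: <b>{fmt_comp(comp$codeletion_1p19q)}</b> |
+7/-10 signature: <b>{fmt_comp(comp$plus7_minus10)}</b></p>
</section>
<section id="classification">
<h2>Classification and Grading Summary</h2>
<p>CNV-consistent-with: <b>{html_escape(cls$suggestion)}</b></p>
<p>Grading hint: <b>{html_escape(cls$grade_hint)}</b> (IDH status used: {html_escape(cls$idh_status)})</p>
<ul>{rule_items}</ul>
<p class="disclaimer">{html_escape(cls$disclaimer)}</p>
</section>
<footer>{footer}</footer>
</body>
</html>')
  writeLines(html, out_path)
  invisible(out_path)
}
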