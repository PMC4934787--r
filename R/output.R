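#' Write a scan's per-window table as TSV
#'
#' Positions in the TSV report are 1-based inclusive; a comment header
#' names the conventions and the populations behind the sign of `L`.
#'
#' @param scan an `ancestry_scan`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_scan_tsv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# hybridscan window table; positions 1-based inclusive",
    sprintf("# query=%s L=log2(d_min[%s]/d_min[%s]); L<0 => %s, L>0 => %s",
            scan$query, scan$pop_neg, scan$pop_pos,
            scan$pop_neg, scan$pop_pos),
    if (!is.na(scan$alpha)) {
      sprintf("# permutation B=%d alpha=%g threshold_neg=%g threshold_pos=%g",
              scan$B, scan$alpha, scan$threshold_neg, scan$threshold_pos)
    }), con)
  utils::write.table(scan$windows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions a region tibble with `contig`, `start`, `end` (1-based
#'   inclusive, as produced by the region callers).
#' @param path output path.
#' @param name_col optional column used for the BED name field.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, name_col = NULL) {
  bed <- tibble(
    chrom = regions$contig,
    chromStart = regions$start - 1L,   # convert to 0-based half-open
    chromEnd = regions$end,
    name = if (!is.null(name_col)) regions[[name_col]] else "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a generic results tibble as TSV
#' @param x a data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-window table of a scan
#' @param x an `ancestry_scan`.
#' @param ... unused.
#' @return The per-window tibble.
#' @export
tidy.ancestry_scan <- function(x, ...) x$windows

#' One-row summary of a scan
#' @param x an `ancestry_scan`.
#' @param ... unused.
#' @return One-row tibble: query, populations, window counts, thresholds,
#'   breakpoint count and ancestry fractions.
#' @export
glance.ancestry_scan <- function(x, ...) {
  fr <- tryCatch(ancestry_fraction(x), error = function(e) NULL)
  tibble(
    query = x$query, pop_neg = x$pop_neg, pop_pos = x$pop_pos,
    n_windows = nrow(x$windows), n_valid = sum(!x$windows$masked),
    threshold_neg = x$threshold_neg, threshold_pos = x$threshold_pos,
    alpha = x$alpha, B = x$B,
    n_breakpoints = nrow(detect_breakpoints(x)),
    fraction_neg = if (is.null(fr)) NA_real_ else fr$fraction[1],
    fraction_pos = if (is.null(fr)) NA_real_ else fr$fraction[2]
  )
}

#' @rdname tidy.ancestry_scan
#' @export
tidy.snp_pca <- function(x, ...) x$scores

#' @rdname glance.ancestry_scan
#' @export
glance.snp_pca <- function(x, ...) {
  tibble(n_components = length(x$explained),
         pc1_pc2_explained = sum(x$explained[seq_len(min(2, length(x$explained)))]))
}

#' Plot a divergence scan along the genome
#'
#' `L` per window, colored by assignment, with the permutation thresholds
#' as horizontal lines and contigs as facets.
#'
#' @param object an `ancestry_scan`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ancestry_scan <- function(object, ...) {
  w <- object$windows[!object$windows$masked, ]
  p <- ggplot2::ggplot(w, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$L,
    colour = .data$assignment)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$contig),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mbp)",
      y = bquote(log[2] ~ "(" * d[min] ~ .(object$pop_neg) * "/" *
                   d[min] ~ .(object$pop_pos) * ")"),
      colour = "assignment",
      title = sprintf("query %s", object$query)) +
    ggplot2::theme_minimal()
  if (!is.na(object$alpha)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(object$threshold_neg, object$threshold_pos),
      colour = "red", linetype = "dashed")
  }
  p
}

#' Plot ancestry tracks
#'
#' One tile per SNP window, colored by the assigned panel; unassigned
#' windows are blank — the "no call" state.
#'
#' @param object an `ancestry_tracks` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ancestry_tracks <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    xmin = .data$start / 1e6, xmax = .data$end / 1e6,
    ymin = 0, ymax = 1, fill = .data$call)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$contig)) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (Mbp)", y = NULL, fill = "ancestry",
                  title = sprintf("query %s", attr(object, "query"))) +
    ggplot2::theme_minimal()
}

#' Plot a copy-number profile
#'
#' Normalized per-window coverage with the inferred integer copy number
#' per chromosome.
#'
#' @param object a `copy_number_profile`.
#' @param normalized the normalized depth tibble used for the inference.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.copy_number_profile <- function(object, normalized = NULL, ...) {
  ch <- object$chromosomes
  p <- ggplot2::ggplot(ch, ggplot2::aes(x = .data$contig)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_norm), fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$copy), colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = NULL, y = "median-normalized coverage (bars), copy (dots)") +
    ggplot2::theme_minimal()
  p
}
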