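#' Read a per-window read-depth table
#'
#' Depth tables are TSVs with columns `strain`, `contig`, `start`, `end`,
#' `depth` (mean read depth of the window, typically 1 kbp). Producing one
#' from a BAM with standard tooling, e.g.
#' `samtools depth -a aln.bam | <windowed mean>` or
#' `bedtools coverage -mean`, is documented in the vignette.
#'
#' @param path TSV path.
#' @return A depth tibble.
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "contig", "start", "end", "depth") %in% names(df)))
  as_tibble(df)
}

#' Normalize window depths by the genome-wide median
#'
#' Divides each window's depth by the strain's genome-wide median depth, so
#' a single-copy region sits near 1 and copy-number differences appear as
#' integer multiples.
#'
#' @param depth depth tibble (`strain`, `contig`, `start`, `end`, `depth`).
#' @return The tibble with a `norm` column added.
#' @export
normalize_depth <- function(depth) {
  stopifnot(all(c("strain", "contig", "depth") %in% names(depth)))
  if (all(depth$depth == 0)) abort("all depths are zero")
  depth %>%
    group_by(.data$strain) %>%
    mutate(norm = .data$depth / stats::median(.data$depth)) %>%
    ungroup()
}

#' Infer chromosome copy numbers from normalized coverage
#'
#' The chromosome with the lowest mean normalized coverage anchors the
#' profile at one copy (ties broken by chromosome order); every other
#' chromosome's copy number is its mean normalized coverage relative to
#' the anchor, rounded to the nearest integer (exact .5 rounds up).
#' Windows deviating by more than `segment_dev` copies from their
#' chromosome's call are reported, unsmoothed, as candidate
#' sub-chromosomal CNV segments.
#'
#' @param normalized output of [normalize_depth()].
#' @param segment_dev deviation (in copies) flagging a window (default
#'   0.4).
#' @return An object of class `copy_number_profile`: list with
#'   `chromosomes` (per strain and contig: `mean_norm`, `copy`, `anchor`)
#'   and `segments` (deviant windows).
#' @export
infer_copy_number <- function(normalized, segment_dev = 0.4) {
  stopifnot("norm" %in% names(normalized))
  chrom <- normalized %>%
    group_by(.data$strain, .data$contig) %>%
    summarise(mean_norm = mean(.data$norm), .groups = "drop_last") %>%
    mutate(anchor = dplyr::row_number() == which.min(.data$mean_norm)) %>%
    mutate(copy = pmax(1L, as.integer(  # half-copy boundaries round up
      floor(.data$mean_norm / .data$mean_norm[.data$anchor] + 0.5 + 1e-9)))) %>%
    ungroup()
  if (any(table(chrom$strain) < 2)) abort("need >= 2 chromosomes per strain")
  seg <- normalized %>%
    left_join(chrom[, c("strain", "contig", "copy", "anchor")],
              by = c("strain", "contig")) %>%
    left_join(chrom %>% filter(.data$anchor) %>%
                select("strain", anchor_norm = "mean_norm"),
              by = "strain") %>%
    mutate(window_copies = .data$norm / .data$anchor_norm) %>%
    filter(abs(.data$window_copies - .data$copy) > segment_dev) %>%
    select("strain", "contig", "start", "end", "norm", "window_copies",
           chrom_copy = "copy")
  structure(list(chromosomes = chrom, segments = seg),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  for (s in unique(x$chromosomes$strain)) {
    ch <- x$chromosomes[x$chromosomes$strain == s, ]
    cat(sprintf("<copy_number_profile> %s: %s (anchor %s)\n", s,
                paste(sprintf("%s=%d", ch$contig, ch$copy), collapse = " "),
                ch$contig[ch$anchor]))
  }
  cat(sprintf("  %d window(s) deviating from the chromosome call\n",
              nrow(x$segments)))
  invisible(x)
}
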