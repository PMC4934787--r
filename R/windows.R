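#' Tile the genome into fixed-size windows
#'
#' Windows tile each contig without overlap; the last window of a contig may
#' be shorter than the nominal size. Coordinates are 1-based inclusive.
#'
#' @param gm a `genotype_matrix`.
#' @param size_bp nominal window size in bp (default 50 kbp, the scale at
#'   which the divergence scan operates).
#' @return A tibble with `window` (index), `contig`, `start`, `end`, and
#'   `n_valid` (valid sites from the mask falling in the window).
#' @export
make_windows <- function(gm, size_bp = 50000) {
  stopifnot(inherits(gm, "genotype_matrix"), size_bp >= 1000)
  w <- purrr::pmap_dfr(
    list(seq_len(nrow(gm$contigs)), gm$contigs$contig, gm$contigs$length),
    function(ci, cname, clen) {
      starts <- seq(1L, clen, by = size_bp)
      tibble(contig = cname, start = starts,
             end = pmin(starts + size_bp - 1L, clen))
    })
  w <- mutate(w, window = dplyr::row_number(), .before = 1)
  attr(w, "size_bp") <- size_bp
  widx <- site_window_index(gm, w)
  w$n_valid <- tabulate(widx[gm$valid], nbins = nrow(w))
  w
}

# per-site window index (NA outside any window; cannot happen with tiling)
site_window_index <- function(gm, windows) {
  widx <- integer(length(gm$pos))
  size_bp <- attr(windows, "size_bp")
  for (ci in seq_len(nrow(gm$contigs))) {
    sites <- which(gm$contig == ci)
    first <- match(TRUE, windows$contig == gm$contigs$contig[ci])
    widx[sites] <- first + (gm$pos[sites] - 1L) %/% size_bp
  }
  widx
}

#' Windowed pairwise divergence between two strains
#'
#' Divergence `d` is the count of valid columns at which the two strains
#' differ, per valid column — the per-window pairwise number of segregating
#' sites per nucleotide. Windows with zero valid sites are masked (`NA`),
#' never reported as zero.
#'
#' @param gm a gap-masked `genotype_matrix`.
#' @param s1,s2 strain names.
#' @param windows a window tibble from [make_windows()]; when `NULL` a
#'   single genome-wide value is returned.
#' @return A tibble with one row per window (`window`, `contig`, `start`,
#'   `end`, `n_valid`, `n_diff`, `d`), or with a single `genome` row.
#' @export
pairwise_divergence <- function(gm, s1, s2, windows = NULL) {
  i <- strain_index(gm, s1); j <- strain_index(gm, s2)
  diff <- gm$alleles[i, ] != gm$alleles[j, ]
  if (is.null(windows)) {
    nv <- sum(gm$valid)
    nd <- sum(diff & gm$valid)
    return(tibble(window = NA_integer_, contig = "genome",
                  start = NA_integer_, end = NA_integer_,
                  n_valid = nv, n_diff = nd,
                  d = if (nv > 0) nd / nv else NA_real_))
  }
  widx <- site_window_index(gm, windows)
  nd <- tabulate(widx[gm$valid & diff], nbins = nrow(windows))
  out <- windows[, c("window", "contig", "start", "end", "n_valid")]
  out$n_diff <- nd
  out$d <- ifelse(out$n_valid > 0, nd / out$n_valid, NA_real_)
  out
}

#' Windowed divergence profile of a query against a reference population
#'
#' For each window, computes the mean, standard deviation and minimum of
#' the pairwise divergence between the query and every member of the
#' reference population, plus the member attaining the minimum. Windows
#' whose valid-site count falls below `min_valid_frac` of the nominal
#' window size are masked. SD is 0 for single-member populations.
#'
#' @param gm a gap-masked `genotype_matrix`.
#' @param popmap population map tibble (see [read_popmap()]).
#' @param query query strain name (excluded from the population if mapped
#'   to it).
#' @param pop reference population label.
#' @param windows window tibble from [make_windows()].
#' @param min_valid_frac window validity floor as a fraction of nominal
#'   window size (default 0.2).
#' @return A tibble of class `divergence_profile` with per-window `d_mean`,
#'   `d_sd`, `d_min`, `min_strain`, `n_valid`, `masked`; the query and
#'   population labels are carried as attributes.
#' @export
population_profile <- function(gm, popmap, query, pop, windows,
                               min_valid_frac = 0.2) {
  members <- setdiff(intersect(pop_strains(popmap, pop), strain_names(gm)),
                     query)
  if (!length(members)) {
    abort(sprintf("population '%s' has no members besides the query", pop))
  }
  size_bp <- attr(windows, "size_bp")
  dmat <- vapply(members, function(m) {
    pairwise_divergence(gm, query, m, windows)$d
  }, numeric(nrow(windows)))
  dmat <- matrix(dmat, nrow = nrow(windows),
                 dimnames = list(NULL, members))
  d_mean <- rowMeans(dmat)
  d_sd <- if (length(members) > 1) apply(dmat, 1, stats::sd) else
    rep(0, nrow(windows))
  min_idx <- max.col(-dmat, ties.method = "first")
  d_min <- dmat[cbind(seq_len(nrow(dmat)), min_idx)]
  out <- windows[, c("window", "contig", "start", "end", "n_valid")]
  out$d_mean <- d_mean
  out$d_sd <- d_sd
  out$d_min <- d_min
  out$min_strain <- members[min_idx]
  out$masked <- out$n_valid < min_valid_frac * size_bp | is.na(d_min)
  out$d_mean[out$masked] <- NA_real_
  out$d_sd[out$masked] <- NA_real_
  out$d_min[out$masked] <- NA_real_
  out$min_strain[out$masked] <- NA_character_
  attr(out, "query") <- query
  attr(out, "pop") <- pop
  attr(out, "size_bp") <- size_bp
  class(out) <- c("divergence_profile", class(out))
  out
}
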