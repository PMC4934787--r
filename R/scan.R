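# Floor for a zero minimum divergence: half a difference over the window's
# valid sites. Keeps the log2 ratio finite while preserving ordering.
zero_floor <- function(d, n_valid) {
  flag <- !is.na(d) & d == 0
  d[flag] <- 0.5 / n_valid[flag]
  list(d = d, flagged = flag)
}

#' Log2 minimum-divergence ratio scan
#'
#' The scan statistic is `L(w) = log2(d_min_neg(w) / d_min_pos(w))`, the
#' log2 ratio of the query's minimum divergence to each of two candidate
#' source populations in a window. `L < 0` assigns the window to the
#' "negative" population (the query is closer to it) and `L > 0` to the
#' "positive" population; `L == 0` leaves the window unassigned. A minimum
#' divergence of exactly zero is floored at half a difference per valid
#' site and flagged. Windows masked in either profile are masked here.
#'
#' @param profile_neg,profile_pos `divergence_profile`s of the same query
#'   against the negative- and positive-sign populations, on a shared
#'   window set.
#' @return An object of class `ancestry_scan`: a list with `windows` (a
#'   tibble adding `L`, `assignment`, `zero_floored` to the per-window
#'   divergence summaries), `query`, `pop_neg`, `pop_pos`, and empty
#'   significance slots filled in by [permutation_threshold()].
#' @export
log2_ratio_scan <- function(profile_neg, profile_pos) {
  if (!identical(attr(profile_neg, "query"), attr(profile_pos, "query"))) {
    abort("profiles are for different query strains")
  }
  if (!identical(profile_neg$window, profile_pos$window) ||
      !identical(profile_neg$start, profile_pos$start)) {
    abort("profiles computed on different window sets")
  }
  w <- profile_neg[, c("window", "contig", "start", "end", "n_valid")]
  w$d_mean_neg <- profile_neg$d_mean
  w$d_sd_neg <- profile_neg$d_sd
  w$d_min_neg <- profile_neg$d_min
  w$d_mean_pos <- profile_pos$d_mean
  w$d_sd_pos <- profile_pos$d_sd
  w$d_min_pos <- profile_pos$d_min
  masked <- profile_neg$masked | profile_pos$masked
  fn <- zero_floor(w$d_min_neg, w$n_valid)
  fp <- zero_floor(w$d_min_pos, w$n_valid)
  w$zero_floored <- fn$flagged | fp$flagged
  w$L <- ifelse(masked, NA_real_, log2(fn$d / fp$d))
  w$masked <- masked
  pop_neg <- attr(profile_neg, "pop")
  pop_pos <- attr(profile_pos, "pop")
  w$assignment <- dplyr::case_when(
    masked | is.na(w$L) ~ NA_character_,
    w$L < 0 ~ pop_neg,
    w$L > 0 ~ pop_pos,
    TRUE ~ "unassigned"
  )
  structure(
    list(windows = as_tibble(w), query = attr(profile_neg, "query"),
         pop_neg = pop_neg, pop_pos = pop_pos,
         size_bp = attr(profile_neg, "size_bp"),
         threshold_pos = NA_real_, threshold_neg = NA_real_,
         alpha = NA_real_, B = NA_integer_),
    class = "ancestry_scan"
  )
}

#' @export
print.ancestry_scan <- function(x, ...) {
  n_ok <- sum(!x$windows$masked)
  cat(sprintf("<ancestry_scan> query '%s': %s (L<0) vs %s (L>0), %d/%d windows valid\n",
              x$query, x$pop_neg, x$pop_pos, n_ok, nrow(x$windows)))
  if (!is.na(x$alpha)) {
    cat(sprintf("  permutation thresholds (B=%d, alpha=%g): L < %.4g or L > %.4g\n",
                x$B, x$alpha, x$threshold_neg, x$threshold_pos))
  }
  invisible(x)
}

# Null distribution of L: permute per-site difference-indicator columns
# uniformly across valid positions, preserving each window's valid-site
# count, and recompute the windowed statistic. Returns a B x n_windows
# matrix of null L values.
permutation_null_L <- function(gm, widx, valid_idx, query, members_neg,
                               members_pos, n_valid, B, seed) {
  qrow <- gm$alleles[strain_index(gm, query), ]
  members <- c(members_neg, members_pos)
  ind_t <- do.call(rbind, lapply(members, function(m) {
    (qrow != gm$alleles[strain_index(gm, m), ])[valid_idx] * 1L
  }))                                            # strains x valid sites
  g <- widx[valid_idx]
  n_w <- length(n_valid)
  res <- withr::with_seed(seed, {
    perm_null_min_counts(ind_t, g, n_w, B, length(members_neg))
  })
  nv <- matrix(n_valid, nrow = B, ncol = n_w, byrow = TRUE)
  dmin_neg <- res$min_neg / nv
  dmin_pos <- res$min_pos / nv
  dmin_neg[dmin_neg == 0] <- (0.5 / nv)[dmin_neg == 0]
  dmin_pos[dmin_pos == 0] <- (0.5 / nv)[dmin_pos == 0]
  nullL <- log2(dmin_neg / dmin_pos)
  nullL[nv == 0 | is.infinite(nullL)] <- NA_real_
  nullL
}

#' Permutation significance for a log2-ratio scan
#'
#' Builds the null distribution of `L` by `B` genome-wide permutations of
#' the per-site difference-indicator columns across valid positions
#' (preserving each window's valid-site count, destroying local ancestry
#' clustering), then attaches per-window unbiased P-values
#' `P(w) = (b(w) + 1) / (B + 1)` — where `b(w)` counts null `|L|` values at
#' window `w` at least as large as the observed `|L(w)|` — and per-side
#' significance thresholds, the smallest `|L|` whose pooled-null unbiased
#' P-value is below `alpha`.
#'
#' @param scan an `ancestry_scan` from [log2_ratio_scan()].
#' @param gm the gap-masked `genotype_matrix` the profiles came from.
#' @param popmap population map tibble.
#' @param B number of permutations (default 999).
#' @param alpha significance level (default 0.019, the printed bound of the
#'   original analysis).
#' @param seed RNG seed (mandatory: the null is stochastic).
#' @param windows window tibble used for the scan; rebuilt from the scan's
#'   window size when `NULL`.
#' @return The scan with `P` added to `windows` and `threshold_pos`,
#'   `threshold_neg`, `alpha`, `B` filled in. If `1/(B+1) >= alpha` a
#'   warning is raised and the thresholds are unattainable (`Inf`).
#' @export
permutation_threshold <- function(scan, gm, popmap, B = 999, alpha = 0.019,
                                  seed, windows = NULL) {
  stopifnot(inherits(scan, "ancestry_scan"), B >= 1, alpha > 0, alpha < 1)
  if (missing(seed)) abort("`seed` is required for the permutation null")
  if (is.null(windows)) windows <- make_windows(gm, scan$size_bp)
  widx <- site_window_index(gm, windows)
  valid_idx <- which(gm$valid)
  members_neg <- setdiff(intersect(pop_strains(popmap, scan$pop_neg),
                                   strain_names(gm)), scan$query)
  members_pos <- setdiff(intersect(pop_strains(popmap, scan$pop_pos),
                                   strain_names(gm)), scan$query)
  nullL <- permutation_null_L(gm, widx, valid_idx, scan$query,
                              members_neg, members_pos,
                              windows$n_valid, B, seed)
  absL <- abs(scan$windows$L)
  b_cnt <- vapply(seq_len(nrow(scan$windows)), function(w) {
    if (is.na(absL[w])) return(NA_integer_)
    sum(abs(nullL[, w]) >= absL[w], na.rm = TRUE)
  }, integer(1))
  scan$windows$P <- (b_cnt + 1) / (B + 1)
  keep <- !scan$windows$masked
  pooled <- nullL[, keep, drop = FALSE]
  pooled <- pooled[!is.na(pooled)]
  if (1 / (B + 1) >= alpha) {
    warn(sprintf("B = %d too small for alpha = %g: 1/(B+1) >= alpha; thresholds unattainable",
                 B, alpha))
    scan$threshold_pos <- Inf
    scan$threshold_neg <- -Inf
  } else {
    n_pool <- length(pooled)
    # largest count k with (k+1)/(n_pool+1) < alpha
    k <- ceiling(alpha * (n_pool + 1)) - 2L
    k <- max(min(k, n_pool - 1L), 0L)
    srt <- sort(pooled, decreasing = TRUE)
    scan$threshold_pos <- srt[k + 1L]
    srt2 <- sort(pooled)
    scan$threshold_neg <- srt2[k + 1L]
  }
  scan$alpha <- alpha
  scan$B <- as.integer(B)
  scan$seed <- seed
  scan
}

#' Detect ancestry breakpoints from a scan
#'
#' One breakpoint is called at each boundary between consecutive valid
#' windows of opposite `L` sign on the same contig (masked and exactly-zero
#' windows are skipped); the reported position is the midpoint between the
#' flanking window edges.
#'
#' @param scan an `ancestry_scan`.
#' @return A tibble with `contig` and `position` (bp, 1-based).
#' @export
detect_breakpoints <- function(scan) {
  w <- scan$windows
  w <- w[!w$masked & !is.na(w$L) & w$L != 0, ]
  if (nrow(w) < 2) return(tibble(contig = character(), position = numeric()))
  out <- list()
  for (ct in unique(w$contig)) {
    ww <- w[w$contig == ct, ]
    if (nrow(ww) < 2) next
    s <- sign(ww$L)
    flip <- which(s[-1] != s[-length(s)])
    if (length(flip)) {
      out[[ct]] <- tibble(
        contig = ct,
        position = (ww$end[flip] + ww$start[flip + 1]) / 2
      )
    }
  }
  if (!length(out)) return(tibble(contig = character(), position = numeric()))
  dplyr::bind_rows(out)
}

# maximal runs of TRUE within each contig, returned as region tibble
runs_to_regions <- function(windows, hit) {
  hit[is.na(hit)] <- FALSE
  out <- list()
  for (ct in unique(windows$contig)) {
    sel <- windows$contig == ct
    h <- hit[sel]
    if (!any(h)) next
    r <- rle(h)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ww <- windows[sel, ]
    runs <- which(r$values)
    out[[ct]] <- tibble(
      contig = ct,
      start = ww$start[starts[runs]],
      end = ww$end[ends[runs]],
      n_windows = r$lengths[runs],
      window_first = ww$window[starts[runs]],
      window_last = ww$window[ends[runs]]
    )
  }
  if (!length(out)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  n_windows = integer(), window_first = integer(),
                  window_last = integer()))
  }
  dplyr::bind_rows(out)
}

#' Significant regions of a scan, optionally shared between two queries
#'
#' Merges maximal runs of contiguous windows whose `L` lies beyond the
#' requested side's permutation threshold into regions. With a second scan,
#' only regions whose spans overlap by at least one window in both scans
#' are returned (the "shared in both queries" region set).
#'
#' @param scan_a an `ancestry_scan` with thresholds set.
#' @param scan_b optional second scan on the same window set.
#' @param side `"pos"` (L above the positive threshold) or `"neg"`.
#' @return A region tibble (`contig`, `start`, `end`, `n_windows`).
#' @export
significant_regions <- function(scan_a, scan_b = NULL,
                                side = c("pos", "neg")) {
  side <- match.arg(side)
  sig <- function(scan) {
    if (is.na(scan$alpha)) abort("run permutation_threshold() first")
    # the sign gate keeps a skewed null (threshold on the "wrong" side of
    # zero) from calling windows assigned to the other population
    if (side == "pos") scan$windows$L > pmax(scan$threshold_pos, 0)
    else scan$windows$L < pmin(scan$threshold_neg, 0)
  }
  ra <- runs_to_regions(scan_a$windows, sig(scan_a))
  if (is.null(scan_b)) return(ra)
  rb <- runs_to_regions(scan_b$windows, sig(scan_b))
  if (!nrow(ra) || !nrow(rb)) return(ra[0, ])
  keep <- purrr::map_lgl(seq_len(nrow(ra)), function(i) {
    any(rb$contig == ra$contig[i] &
          rb$start <= ra$end[i] & rb$end >= ra$start[i])
  })
  ra[keep, ]
}

#' Regions of discordant ancestry between two queries
#'
#' The strict tier reports maximal runs of valid windows where the two
#' scans disagree in sign and both exceed their own side's permutation
#' threshold — windows where the two queries are confidently assigned to
#' different source populations. The weak tier reports runs where the
#' per-window `L` uncertainty bands of the two scans fail to overlap (bands
#' obtained by propagating each profile's across-strain divergence SD
#' through the ratio), without requiring significance.
#'
#' @param scan_a,scan_b `ancestry_scan`s sharing the window set and
#'   reference populations, with thresholds set.
#' @return A region tibble with a `tier` column (`"strict"` or `"weak"`;
#'   weak runs overlapping a strict run are not repeated).
#' @export
discordant_regions <- function(scan_a, scan_b) {
  stopifnot(identical(scan_a$windows$window, scan_b$windows$window))
  if (!identical(c(scan_a$pop_neg, scan_a$pop_pos),
                 c(scan_b$pop_neg, scan_b$pop_pos))) {
    abort("scans use different reference populations")
  }
  wa <- scan_a$windows; wb <- scan_b$windows
  ok <- !wa$masked & !wb$masked & !is.na(wa$L) & !is.na(wb$L)
  beyond <- function(w, scan) {
    w$L > pmax(scan$threshold_pos, 0) | w$L < pmin(scan$threshold_neg, 0)
  }
  strict <- ok & sign(wa$L) != sign(wb$L) &
    beyond(wa, scan_a) & beyond(wb, scan_b)
  band <- function(w) {
    eps <- 0.5 / pmax(w$n_valid, 1)
    lo <- log2(pmax(w$d_min_neg - w$d_sd_neg, eps) /
                 (w$d_min_pos + w$d_sd_pos))
    hi <- log2((w$d_min_neg + w$d_sd_neg) /
                 pmax(w$d_min_pos - w$d_sd_pos, eps))
    list(lo = lo, hi = hi)
  }
  ba <- band(wa); bb <- band(wb)
  weak <- ok & (ba$hi < bb$lo | bb$hi < ba$lo) & !strict
  rs <- runs_to_regions(wa, strict)
  rw <- runs_to_regions(wa, weak)
  if (nrow(rs)) rs$tier <- "strict"
  if (nrow(rw)) rw$tier <- "weak"
  out <- dplyr::bind_rows(rs, rw)
  if (!nrow(out)) out$tier <- character()
  dplyr::arrange(out, .data$contig, .data$start)
}

#' Genome fraction assigned to each source population
#'
#' Sums assigned-window lengths per side over the total assigned length;
#' masked, unassigned and exactly-tied windows are excluded. Fractions sum
#' to 1.
#'
#' @param scan an `ancestry_scan`.
#' @return A tibble with `population` and `fraction` (negative-side
#'   population first).
#' @export
ancestry_fraction <- function(scan) {
  w <- scan$windows
  assigned <- !w$masked & !is.na(w$L) & w$L != 0
  if (!any(assigned)) abort("no assigned windows")
  len <- (w$end - w$start + 1)[assigned]
  neg <- w$L[assigned] < 0
  tot <- sum(len)
  tibble(population = c(scan$pop_neg, scan$pop_pos),
         fraction = c(sum(len[neg]), sum(len[!neg])) / tot)
}

#' Run the full divergence scan for one query
#'
#' Convenience wrapper: windows, the two population profiles, the log2
#' ratio scan, and (when `B > 0`) the permutation significance step.
#'
#' @inheritParams population_profile
#' @inheritParams permutation_threshold
#' @param pop_neg,pop_pos population labels for the negative/positive sign
#'   conventions (`L < 0` means closer to `pop_neg`).
#' @param window_bp window size in bp.
#' @return An `ancestry_scan`.
#' @export
scan_genome <- function(gm, popmap, query, pop_neg, pop_pos,
                        window_bp = 50000, B = 999, alpha = 0.019,
                        seed = NULL, min_valid_frac = 0.2) {
  windows <- make_windows(gm, window_bp)
  pn <- population_profile(gm, popmap, query, pop_neg, windows, min_valid_frac)
  pp <- population_profile(gm, popmap, query, pop_pos, windows, min_valid_frac)
  scan <- log2_ratio_scan(pn, pp)
  if (B > 0) {
    if (is.null(seed)) abort("`seed` is required when B > 0")
    scan <- permutation_threshold(scan, gm, popmap, B = B, alpha = alpha,
                                  seed = seed, windows = windows)
  }
  scan
}
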