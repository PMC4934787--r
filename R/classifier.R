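#' Fit per-window reference-panel PCA models
#'
#' Partitions the SNP matrix, in genomic order, into consecutive windows of
#' `window_snps` SNPs (a trailing remainder shorter than half the window is
#' dropped) and fits, per window, principal axes on the reference-panel
#' strains only — the query never enters the fit. Per-panel centroids in
#' the retained component space are stored for nearest-centroid assignment.
#' Genotypes are encoded as haploid allele counts in {0, 1}; missing calls
#' are imputed with the window-local panel mean before projection. Windows
#' where the panels' centroids coincide are uninformative and yield no
#' calls; windows where some panel is internally monomorphic are flagged
#' `low_info` (two fully fixed, well-separated panels remain perfectly
#' assignable, so the flag does not suppress calls by itself).
#'
#' @param snps a `snp_matrix`.
#' @param popmap population map tibble.
#' @param panels character vector of >= 2 population labels to use as
#'   reference panels; defaults to all populations with >= 2 mapped strains
#'   present in `snps`.
#' @param window_snps SNPs per window (default 20).
#' @param n_components principal components retained (default 2, capped by
#'   the available rank).
#' @return An object of class `panel_model`.
#' @export
fit_panels <- function(snps, popmap, panels = NULL, window_snps = 20,
                       n_components = 2) {
  stopifnot(inherits(snps, "snp_matrix"))
  validate_popmap(popmap)
  present <- intersect(popmap$strain, rownames(snps$alleles))
  pm <- popmap[popmap$strain %in% present, ]
  if (is.null(panels)) {
    tab <- table(pm$population)
    panels <- names(tab)[tab >= 2]
  }
  if (length(panels) < 2) abort("need >= 2 reference panels")
  panel_members <- lapply(panels, function(p) pop_strains(pm, p))
  names(panel_members) <- panels
  if (any(lengths(panel_members) < 2)) {
    abort("each panel needs >= 2 strains")
  }
  # windows of window_snps consecutive SNPs, restarted at contig
  # boundaries; a trailing remainder < window_snps/2 is dropped
  site_groups <- list()
  for (ci in unique(snps$contig)) {
    sites_c <- which(snps$contig == ci)
    n_c <- length(sites_c)
    n_w <- n_c %/% window_snps
    rem <- n_c - n_w * window_snps
    if (rem >= window_snps / 2) n_w <- n_w + 1
    for (wi in seq_len(n_w)) {
      i0 <- (wi - 1L) * window_snps + 1L
      i1 <- min(wi * window_snps, n_c)
      site_groups[[length(site_groups) + 1L]] <- sites_c[i0:i1]
    }
  }
  if (!length(site_groups)) abort("not enough SNPs for a single window")
  all_members <- unlist(panel_members, use.names = FALSE)
  counts <- snp_counts(snps)    # strains x snps, 0/1/NA

  windows <- vector("list", length(site_groups))
  for (wi in seq_along(site_groups)) {
    sites <- site_groups[[wi]]
    x <- counts[all_members, sites, drop = FALSE] * 1.0
    col_mu <- colMeans(x, na.rm = TRUE)
    col_mu[is.nan(col_mu)] <- 0
    for (j in seq_along(sites)) x[is.na(x[, j]), j] <- col_mu[j]
    mono <- purrr::map_lgl(panel_members, function(m) {
      all(apply(counts[m, sites, drop = FALSE], 2,
                function(col) length(unique(col[!is.na(col)])) <= 1))
    })
    center <- colMeans(x)
    xc <- sweep(x, 2, center)
    r <- min(n_components, nrow(x) - 1L, length(sites))
    sv <- svd(xc, nu = 0, nv = r)
    rot <- sv$v
    scores <- xc %*% rot
    centroids <- do.call(rbind, lapply(panel_members, function(m) {
      colMeans(scores[m, , drop = FALSE])
    }))
    rownames(centroids) <- panels
    # spread of panel members around their own centroid (softmax scale)
    spread <- mean(purrr::map_dbl(seq_along(panels), function(k) {
      m <- panel_members[[k]]
      mean(sqrt(rowSums(sweep(scores[m, , drop = FALSE], 2,
                              centroids[k, ])^2)))
    }))
    cent_sep <- min(stats::dist(centroids))
    windows[[wi]] <- list(
      sites = sites, center = center, rotation = rot, col_mu = col_mu,
      centroids = centroids, spread = spread,
      low_info = any(mono),              # a panel without variation here
      informative = cent_sep > 1e-9      # coincident centroids: no call
    )
  }
  structure(
    list(windows = windows, panels = panels, panel_members = panel_members,
         window_snps = window_snps, n_components = n_components,
         contig = snps$contig, pos = snps$pos, contigs = snps$contigs),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  cat(sprintf("<panel_model> %d windows of %d SNPs, panels: %s (%d informative)\n",
              length(x$windows), x$window_snps,
              paste(x$panels, collapse = ", "),
              sum(purrr::map_lgl(x$windows, "informative"))))
  invisible(x)
}

#' Assign local ancestry to a query strain
#'
#' Projects each 20-SNP window of the query onto the window's panel
#' principal axes and scores each panel by a softmax of the negative
#' distance to its centroid (temperature = the window's mean within-panel
#' spread). A window is assigned to the top panel when its score reaches
#' the confidence floor; otherwise it is left unassigned — the "no call"
#' state. Low-information windows and windows with more than `max_missing`
#' missing query genotypes are never assigned.
#'
#' @param model a `panel_model`.
#' @param snps the `snp_matrix` the model was fitted on (source of the
#'   query genotypes).
#' @param query query strain name; must not be a panel member (leakage).
#' @param min_confidence confidence floor in (0, 1] (default 0.8).
#' @param max_missing maximum tolerated fraction of missing query calls per
#'   window (default 0.25).
#' @return A tibble of class `ancestry_tracks`: per window the span
#'   (contig, start/end from first/last SNP), `call` (panel label or `NA`),
#'   and `confidence`.
#' @export
assign_query <- function(model, snps, query, min_confidence = 0.8,
                         max_missing = 0.25) {
  stopifnot(inherits(model, "panel_model"))
  if (query %in% unlist(model$panel_members)) {
    abort(sprintf("query '%s' is a panel member (leakage)", query))
  }
  qcounts <- snp_counts(snps)[query, ]
  k <- length(model$panels)
  rows <- purrr::map_dfr(seq_along(model$windows), function(wi) {
    w <- model$windows[[wi]]
    q <- qcounts[w$sites] * 1.0
    miss <- mean(is.na(q))
    call <- NA_character_
    conf <- NA_real_
    if (w$informative && miss <= max_missing) {
      q[is.na(q)] <- w$col_mu[is.na(q)]
      z <- drop((q - w$center) %*% w$rotation)
      dist_k <- sqrt(colSums((t(w$centroids) - z)^2))
      tau <- max(w$spread, 1e-9)
      sc <- exp(-dist_k / tau)
      sc <- sc / sum(sc)
      best <- which.max(sc)
      conf <- sc[best]
      if (conf >= min_confidence) call <- model$panels[best]
    }
    tibble(
      window = wi,
      contig = model$contigs$contig[model$contig[w$sites[1]]],
      start = model$pos[w$sites[1]],
      end = model$pos[w$sites[length(w$sites)]],
      n_snps = length(w$sites),
      call = call,
      confidence = unname(conf)
    )
  })
  attr(rows, "query") <- query
  attr(rows, "panels") <- model$panels
  class(rows) <- c("ancestry_tracks", class(rows))
  rows
}

#' Majority-vote smoothing of ancestry tracks
#'
#' Replaces each window's call by the majority call in a sliding
#' neighborhood of `k` windows (same contig). Unassigned windows do not
#' vote and ties keep the original call. Idempotent on homogeneous tracks;
#' stands in for HMM posterior smoothing with one interpretable knob.
#'
#' @param tracks an `ancestry_tracks` tibble.
#' @param k odd neighborhood size (default 3).
#' @return The smoothed `ancestry_tracks`.
#' @export
smooth_tracks <- function(tracks, k = 3) {
  stopifnot(k %% 2 == 1)
  half <- (k - 1) / 2
  out <- tracks
  for (ct in unique(tracks$contig)) {
    idx <- which(tracks$contig == ct)
    calls <- tracks$call[idx]
    new_calls <- calls
    for (i in seq_along(idx)) {
      nb <- calls[max(1, i - half):min(length(idx), i + half)]
      nb <- nb[!is.na(nb)]
      if (!length(nb)) next
      tab <- sort(table(nb), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) next  # tie: keep original
      new_calls[i] <- names(tab)[1]
    }
    out$call[idx] <- new_calls
  }
  out
}

#' Genome fraction contributed by each panel
#'
#' Fraction of assigned windows per panel, weighted by each window's SNP
#' span in bp; fractions sum to 1 over assigned windows.
#'
#' @param tracks an `ancestry_tracks` tibble.
#' @return A tibble with `population` and `fraction`.
#' @export
genome_fractions <- function(tracks) {
  assigned <- tracks[!is.na(tracks$call), ]
  if (!nrow(assigned)) abort("all windows unassigned")
  assigned %>%
    mutate(len = .data$end - .data$start + 1) %>%
    group_by(population = .data$call) %>%
    summarise(fraction = sum(.data$len), .groups = "drop") %>%
    mutate(fraction = .data$fraction / sum(.data$fraction))
}
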