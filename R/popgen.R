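# harmonic-number helpers shared by the neutrality tests
a1_fun <- function(n) sum(1 / seq_len(n - 1))
a2_fun <- function(n) sum(1 / seq_len(n - 1)^2)

#' Nucleotide diversity (pi)
#'
#' Per-site nucleotide diversity: the average over all strain pairs of the
#' pairwise divergence across valid sites, with gaps deleted per pairwise
#' comparison (sites missing in either member of a pair are excluded for
#' that pair only).
#'
#' @param gm a `genotype_matrix`.
#' @param popmap population map tibble; `pop` selects the strains.
#' @param pop population label (ignored when `strains` given).
#' @param strains optional explicit strain set.
#' @return A tibble with `population`, `n`, `n_pairs`, `pi`.
#' @export
nucleotide_diversity <- function(gm, popmap = NULL, pop = NULL,
                                 strains = NULL) {
  if (is.null(strains)) strains <- pop_strains(popmap, pop)
  if (length(strains) < 2) abort("pi needs >= 2 strains")
  idx <- strain_index(gm, strains)
  a <- gm$alleles[idx, gm$valid, drop = FALSE]
  pairs <- utils::combn(length(idx), 2)
  dvals <- apply(pairs, 2, function(pr) {
    x <- a[pr[1], ]; y <- a[pr[2], ]
    ok <- x != 0L & y != 0L
    if (!any(ok)) return(NA_real_)
    sum(x[ok] != y[ok]) / sum(ok)
  })
  tibble(population = pop %||% "custom", n = length(strains),
         n_pairs = ncol(pairs), pi = mean(dvals, na.rm = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-population folded/unfolded counts at each SNP; internal substrate of
# the neutrality tests. Returns list(S, pi_total, xi (unfolded SFS counts
# when polarized), singletons, ...)
pop_site_stats <- function(snps, strains, outgroup_consensus = NULL) {
  x <- snp_counts(snps, strains)          # 0/1/NA, count of allele2
  n <- length(strains)
  cnt2 <- colSums(x == 1L, na.rm = TRUE)
  ncall <- colSums(!is.na(x))
  seg <- ncall == n & cnt2 > 0 & cnt2 < n  # complete data, segregating
  cnt2 <- cnt2[seg]
  list(seg_idx = which(seg), n = n, cnt2 = cnt2,
       minor = pmin(cnt2, n - cnt2))
}

#' Neutrality tests and diversity summary for one population
#'
#' Computes, per their published formulas: S (segregating sites), per-site
#' pi and Watterson's theta, Tajima's D, Fu & Li's D* (or D when an
#' outgroup population is designated, using derived singletons), Fu's Fs
#' (via the Ewens sampling distribution of haplotype counts; the
#' alternative reading "Fu & Li's F" is available via `fs_variant`), and
#' Fay & Wu's H (pi minus theta_H form; outgroup required). The outgroup is
#' the consensus allele of a designated population, and sites where that
#' consensus carries neither sample allele are excluded from the polarized
#' statistics. Statistics are reported `NA` with a reason when n or S is
#' too small.
#'
#' @param snps a `snp_matrix` carrying `n_total_sites` (the per-site
#'   denominators).
#' @param popmap population map tibble.
#' @param pop population label.
#' @param outgroup_pop optional population label whose consensus polarizes
#'   derived alleles.
#' @param fs_variant `"fs"` (Fu's Fs, default) or `"fu_li_F"` (Fu & Li's
#'   F/F* instead).
#' @return A one-row tibble (class `diversity_summary`) with the fields
#'   above.
#' @export
neutrality_tests <- function(snps, popmap, pop, outgroup_pop = NULL,
                             fs_variant = c("fs", "fu_li_F")) {
  fs_variant <- match.arg(fs_variant)
  strains <- pop_strains(popmap, pop)
  n <- length(strains)
  L <- snps$n_total_sites
  x <- snp_counts(snps, strains)
  cnt2 <- colSums(x == 1L, na.rm = TRUE)
  ncall <- colSums(!is.na(x))
  seg <- ncall == n & cnt2 > 0 & cnt2 < n
  S <- sum(seg)
  k2 <- cnt2[seg]

  # derived-allele counts when an outgroup population is given
  derived_cnt <- NULL
  if (!is.null(outgroup_pop)) {
    og <- pop_strains(popmap, outgroup_pop)
    og_x <- snp_counts(snps, og)
    og_freq <- colMeans(og_x, na.rm = TRUE)[seg]
    anc_is_1 <- og_freq < 0.5          # outgroup consensus = allele1
    usable <- !is.na(og_freq) & (og_freq < 0.5 | og_freq > 0.5)
    derived_cnt <- ifelse(anc_is_1, k2, n - k2)[usable]
  }

  pi_total <- sum(2 * k2 * (n - k2) / (n * (n - 1)))
  res <- tibble(
    population = pop, n = n, S = S,
    pi = pi_total / L,
    theta_w = NA_real_, tajima_d = NA_real_, fu_li = NA_real_,
    fu_li_variant = NA_character_, fs = NA_real_, fay_wu_h = NA_real_,
    note = NA_character_
  )
  if (n < 4) {
    res$note <- "n < 4: neutrality tests undefined"
    if (n >= 3 || n >= 2) res$theta_w <- if (n >= 2) S / a1_fun(n) / L else NA
    return(structure(res, class = c("diversity_summary", class(res))))
  }
  a1 <- a1_fun(n); a2 <- a2_fun(n)
  res$theta_w <- S / a1 / L
  if (S == 0) {
    res$note <- "S = 0: tests undefined"
    return(structure(res, class = c("diversity_summary", class(res))))
  }

  # Tajima's D
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  res$tajima_d <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))

  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  if (is.null(outgroup_pop)) {
    # D*: singletons regardless of polarity
    eta_s <- sum(pmin(k2, n - k2) == 1)
    an1 <- a1 + 1 / n
    dn <- cn + (n - 2) / (n - 1)^2 +
      (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
    vDs <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
              2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
    uDs <- (n / (n - 1)) * (a1 - n / (n - 1)) - vDs
    res$fu_li <- ((n / (n - 1)) * S - a1 * eta_s) /
      sqrt(uDs * S + vDs * S^2)
    res$fu_li_variant <- "D*"
  } else {
    eta_e <- sum(derived_cnt == 1)
    Sp <- length(derived_cnt)          # polarizable segregating sites
    vD <- 1 + (a1^2 / (a2 + a1^2)) * (cn - (n + 1) / (n - 1))
    uD <- a1 - 1 - vD
    res$fu_li <- (Sp - a1 * eta_e) / sqrt(uD * Sp + vD * Sp^2)
    res$fu_li_variant <- "D"
    # Fay & Wu's H = pi - theta_H over polarizable sites
    xi <- tabulate(derived_cnt, nbins = n - 1)
    i <- seq_len(n - 1)
    pi_p <- sum(2 * i * (n - i) * xi / (n * (n - 1)))
    theta_h <- sum(2 * xi * i^2 / (n * (n - 1)))
    res$fay_wu_h <- pi_p - theta_h
  }

  if (fs_variant == "fs") {
    res$fs <- fu_fs(snps, strains, theta = pi_total)
  } else {
    res$fs <- fu_li_F(S, k2, n, derived_cnt)
    res$fu_li_variant <- paste0(res$fu_li_variant, "+F")
  }
  structure(res, class = c("diversity_summary", class(res)))
}

# Fu's Fs via the Ewens sampling distribution: S' = P(K >= k_obs | theta),
# Fs = ln(S' / (1 - S')). theta = mean pairwise differences.
fu_fs <- function(snps, strains, theta) {
  x <- snp_counts(snps, strains)
  hap <- apply(x, 1, paste, collapse = ",")
  k_obs <- length(unique(hap))
  n <- length(strains)
  if (theta <= 0) return(NA_real_)
  # unsigned Stirling numbers of the first kind, rows up to n (log scale
  # is unnecessary at the n used here)
  st <- matrix(0, n + 1, n + 1)
  st[1, 1] <- 1
  for (nn in seq_len(n)) {
    for (kk in seq_len(nn)) {
      st[nn + 1, kk + 1] <- st[nn, kk] + (nn - 1) * st[nn, kk + 1]
    }
  }
  pk <- vapply(seq_len(n), function(k) {
    st[n + 1, k + 1] * theta^k
  }, numeric(1))
  pk <- pk / sum(pk)                  # denominator theta^(n) cancels
  sprime <- sum(pk[k_obs:n])
  if (sprime <= 0 || sprime >= 1) return(NA_real_)
  log(sprime / (1 - sprime))
}

# Fu & Li's F (outgroup) / F* (no outgroup); the alternative reading of
# the "Fu's F" label.
fu_li_F <- function(S, k2, n, derived_cnt = NULL) {
  a1 <- a1_fun(n); a2 <- a2_fun(n)
  pi_total <- sum(2 * k2 * (n - k2) / (n * (n - 1)))
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  a2 <- a2_fun(n)
  if (is.null(derived_cnt)) {
    eta_s <- sum(pmin(k2, n - k2) == 1)
    an1 <- a1 + 1 / n
    vFs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
              (2 * (n - 1) * a1) / n^2 - (8 * a2) / n) / (a1^2 + a2)
    uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
              2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - vFs
    (pi_total - ((n - 1) / n) * eta_s) / sqrt(uFs * S + vFs * S^2)
  } else {
    eta_e <- sum(derived_cnt == 1)
    Sp <- length(derived_cnt)
    vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
      (a1^2 + a2)
    uF <- (1 + (n + 1) / (3 * (n - 1)) - 4 * (n + 1) / (n - 1)^2 *
             (a1_fun(n + 1) - 2 * n / (n + 1))) / a1 - vF
    (pi_total - eta_e) / sqrt(uF * Sp + vF * Sp^2)
  }
}

#' Hudson's Fst between two populations
#'
#' Ratio-of-averages Hudson estimator: per segregating site the numerator
#' is `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`; Fst is the summed numerator over the summed
#' denominator, robust to unequal sample sizes. The raw (possibly
#' negative) value is reported alongside a zero-clamped one.
#'
#' @param snps a `snp_matrix`.
#' @param popmap population map tibble.
#' @param pop_p,pop_q population labels.
#' @return A one-row tibble with `fst` (clamped at 0), `fst_raw`, and the
#'   number of sites used; `fst` is `NA` when no site segregates between
#'   the samples.
#' @export
pairwise_fst <- function(snps, popmap, pop_p, pop_q) {
  sp <- pop_strains(popmap, pop_p)
  sq <- pop_strains(popmap, pop_q)
  if (length(sp) < 2 || length(sq) < 2) abort("each population needs >= 2 strains")
  xp <- snp_counts(snps, sp); xq <- snp_counts(snps, sq)
  n1 <- colSums(!is.na(xp)); n2 <- colSums(!is.na(xq))
  p1 <- colMeans(xp, na.rm = TRUE); p2 <- colMeans(xq, na.rm = TRUE)
  use <- n1 >= 2 & n2 >= 2 & (p1 > 0 | p2 > 0) & (p1 < 1 | p2 < 1)
  # drop sites monomorphic for the same allele in both samples
  poly <- use & !(p1 == p2 & (p1 == 0 | p1 == 1))
  if (!any(poly)) {
    return(tibble(pop_p = pop_p, pop_q = pop_q, fst = NA_real_,
                  fst_raw = NA_real_, n_sites = 0L))
  }
  p1 <- p1[poly]; p2 <- p2[poly]; n1 <- n1[poly]; n2 <- n2[poly]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  raw <- sum(num) / sum(den)
  tibble(pop_p = pop_p, pop_q = pop_q, fst = max(raw, 0), fst_raw = raw,
         n_sites = sum(poly))
}

#' Tamura-Nei (TN93) corrected pairwise distance
#'
#' Closed-form TN93 correction with empirical base frequencies estimated
#' from the pair itself (averaged over the two sequences at the shared
#' valid sites); gaps are deleted pairwise. Returns `NA` with a saturation
#' flag when the logarithms are undefined.
#'
#' @param gm a `genotype_matrix`.
#' @param s1,s2 strain names.
#' @return A one-row tibble with `p_distance`, `tn93`, `saturated`,
#'   `n_sites`.
#' @export
tn93_distance <- function(gm, s1, s2) {
  i <- strain_index(gm, s1); j <- strain_index(gm, s2)
  x <- gm$alleles[i, gm$valid]; y <- gm$alleles[j, gm$valid]
  ok <- x != 0L & y != 0L
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 1) abort("no shared valid sites")
  # codes: 1=A, 2=C, 3=G, 4=T; purines {1,3}, pyrimidines {2,4}
  freq <- (tabulate(x, 4) + tabulate(y, 4)) / (2 * n)
  gA <- freq[1]; gC <- freq[2]; gG <- freq[3]; gT <- freq[4]
  gR <- gA + gG; gY <- gC + gT
  diff <- x != y
  ts1 <- sum(diff & ((x == 1 & y == 3) | (x == 3 & y == 1))) / n  # A<->G
  ts2 <- sum(diff & ((x == 2 & y == 4) | (x == 4 & y == 2))) / n  # C<->T
  tv <- sum(diff) / n - ts1 - ts2
  p_dist <- sum(diff) / n
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  t1 <- 1 - ts1 / k1 - tv / (2 * gR)
  t2 <- 1 - ts2 / k2 - tv / (2 * gY)
  t3 <- 1 - tv / (2 * gR * gY)
  saturated <- is.na(t1 * t2 * t3) | t1 <= 0 | t2 <= 0 | t3 <= 0
  d <- if (saturated) NA_real_ else {
    v <- 0
    if (k1 > 0) v <- v - k1 * log(t1)
    if (k2 > 0) v <- v - k2 * log(t2)
    if (k3 > 0) v <- v - k3 * log(t3)
    v
  }
  if (p_dist == 0) { d <- 0; saturated <- FALSE }
  tibble(s1 = s1, s2 = s2, p_distance = p_dist, tn93 = d,
         saturated = saturated, n_sites = n)
}

#' Classify segregating sites between two populations
#'
#' Each site segregating in the combined sample is classed as a fixed
#' difference (both populations monomorphic, for different alleles), a
#' shared polymorphism (both polymorphic), or private to one population
#' (that one polymorphic, the other monomorphic). The four classes
#' partition the sites considered; percentages are normalized by the total
#' number of valid sites.
#'
#' @inheritParams pairwise_fst
#' @return A one-row tibble with counts `fixed`, `shared`, `private_p`,
#'   `private_q`, their `pct_*` per-valid-site percentages, and Hudson's
#'   Fst for the pair.
#' @export
classify_polymorphisms <- function(snps, popmap, pop_p, pop_q) {
  sp <- pop_strains(popmap, pop_p)
  sq <- pop_strains(popmap, pop_q)
  if (length(sp) < 2 || length(sq) < 2) abort("each population needs >= 2 strains")
  p1 <- allele2_freq(snps, sp)
  p2 <- allele2_freq(snps, sq)
  ok <- !is.na(p1) & !is.na(p2)
  poly1 <- ok & p1 > 0 & p1 < 1
  poly2 <- ok & p2 > 0 & p2 < 1
  mono1 <- ok & !poly1
  mono2 <- ok & !poly2
  fixed <- sum(mono1 & mono2 & abs(p1 - p2) == 1)
  shared <- sum(poly1 & poly2)
  private_p <- sum(poly1 & mono2)
  private_q <- sum(poly2 & mono1)
  L <- snps$n_total_sites
  fst <- pairwise_fst(snps, popmap, pop_p, pop_q)$fst
  tibble(pop_p = pop_p, pop_q = pop_q,
         fixed = fixed, shared = shared,
         private_p = private_p, private_q = private_q,
         pct_fixed = 100 * fixed / L, pct_shared = 100 * shared / L,
         pct_private_p = 100 * private_p / L,
         pct_private_q = 100 * private_q / L,
         fst = fst)
}

#' ABBA-BABA D statistic with block-jackknife significance
#'
#' Population-frequency D: with derived-allele frequencies `p1..p3` in
#' (P1, P2, P3) and the outgroup fixing ancestral state,
#' `ABBA = (1-p1) p2 p3` and `BABA = p1 (1-p2) p3` summed over sites;
#' `D = sum(ABBA-BABA) / sum(ABBA+BABA)`. The standard error comes from a
#' delete-one block jackknife over `block_bp` blocks (reported only with
#' >= 20 non-empty blocks). An excess of ABBA (D > 0) indicates gene flow
#' between P2 and P3.
#'
#' @param snps a `snp_matrix`.
#' @param popmap population map tibble.
#' @param p1,p2,p3,outgroup population labels (disjoint); the outgroup
#'   consensus supplies polarity and sites where it is polymorphic at
#'   frequency 0.5 are dropped.
#' @param block_bp jackknife block size in bp (default 50 kbp).
#' @return A one-row tibble (class `introgression_test`) with `d`, `se`,
#'   `z`, `n_blocks`, `n_abba`, `n_baba`.
#' @export
d_statistic <- function(snps, popmap, p1, p2, p3, outgroup,
                        block_bp = 50000) {
  groups <- list(p1, p2, p3, outgroup)
  strains <- lapply(groups, function(p) pop_strains(popmap, p))
  if (anyDuplicated(unlist(strains))) abort("the four groups must be disjoint")
  fr <- lapply(strains, function(s) allele2_freq(snps, s))
  og <- fr[[4]]
  use <- !is.na(og) & og != 0.5 &
    !is.na(fr[[1]]) & !is.na(fr[[2]]) & !is.na(fr[[3]])
  # derived allele = the one the outgroup consensus does not carry
  anc2 <- og[use] > 0.5            # outgroup consensus is allele2
  d1 <- ifelse(anc2, 1 - fr[[1]][use], fr[[1]][use])
  d2 <- ifelse(anc2, 1 - fr[[2]][use], fr[[2]][use])
  d3 <- ifelse(anc2, 1 - fr[[3]][use], fr[[3]][use])
  abba <- (1 - d1) * d2 * d3
  baba <- d1 * (1 - d2) * d3
  denom <- sum(abba + baba)
  if (denom == 0) {
    return(structure(tibble(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                            d = NA_real_, se = NA_real_, z = NA_real_,
                            n_blocks = 0L, n_abba = 0, n_baba = 0),
                     class = c("introgression_test", class(tibble()))))
  }
  D <- sum(abba - baba) / denom
  block <- paste(snps$contig[use], (snps$pos[use] - 1L) %/% block_bp)
  ublk <- unique(block)
  se <- z <- NA_real_
  if (length(ublk) >= 20) {
    dj <- vapply(ublk, function(bl) {
      keep <- block != bl
      sum(abba[keep] - baba[keep]) / sum(abba[keep] + baba[keep])
    }, numeric(1))
    m <- length(ublk)
    se <- sqrt((m - 1) / m * sum((dj - mean(dj))^2))
    z <- D / se
  }
  structure(tibble(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup,
                   d = D, se = se, z = z, n_blocks = length(ublk),
                   n_abba = sum(abba), n_baba = sum(baba)),
            class = c("introgression_test", class(tibble())))
}

#' f4-ratio estimate of an admixture proportion
#'
#' Standard construction: `alpha = f4(a, o; x, c) / f4(a, o; b, c)` where
#' `x` is the admixed group, `b` the reference proxy for the introgressing
#' source and `c` its sister; `f4(W, X; Y, Z)` is the average over sites of
#' `(pW - pX)(pY - pZ)`.
#'
#' @inheritParams d_statistic
#' @param a,b,x,c,o population labels (the quintuple).
#' @return A one-row tibble with `alpha` and the two f4 values.
#' @export
f4_ratio <- function(snps, popmap, a, b, x, c, o) {
  f <- function(w, xx, y, z) {
    fw <- allele2_freq(snps, pop_strains(popmap, w))
    fx <- allele2_freq(snps, pop_strains(popmap, xx))
    fy <- allele2_freq(snps, pop_strains(popmap, y))
    fz <- allele2_freq(snps, pop_strains(popmap, z))
    ok <- !is.na(fw + fx + fy + fz)
    mean(((fw - fx) * (fy - fz))[ok])
  }
  num <- f(a, o, x, c)
  den <- f(a, o, b, c)
  tibble(a = a, b = b, x = x, c = c, o = o,
         f4_num = num, f4_den = den,
         alpha = if (den != 0) num / den else NA_real_)
}

#' Windowed heterozygosity profile
#'
#' Per strain and window, heterozygous sites per valid bp, plus the
#' genome-wide rate; the substrate for comparing regional heterozygosity
#' against the genome as a whole in hybrid subgenomes.
#'
#' @param het_calls tibble of heterozygous site records with columns
#'   `strain`, `contig`, `pos`.
#' @param windows window tibble from [make_windows()] (its `n_valid`
#'   column supplies per-window valid bp).
#' @return A tibble with per-window rates (`het_rate`) per strain; the
#'   genome-wide rate per strain is attached as attribute
#'   `genome_rate` and repeated in column `genome_rate`.
#' @export
heterozygosity_profile <- function(het_calls, windows) {
  stopifnot(all(c("strain", "contig", "pos") %in% names(het_calls)))
  size_bp <- attr(windows, "size_bp")
  strains <- unique(het_calls$strain)
  out <- purrr::map_dfr(strains, function(s) {
    hc <- het_calls[het_calls$strain == s, ]
    w <- windows
    widx <- match(
      paste(hc$contig, (hc$pos - 1L) %/% size_bp),
      paste(w$contig, (w$start - 1L) %/% size_bp))
    counts <- tabulate(widx[!is.na(widx)], nbins = nrow(w))
    w$strain <- s
    w$n_het <- counts
    w$het_rate <- ifelse(w$n_valid > 0, counts / w$n_valid, NA_real_)
    w$genome_rate <- sum(counts) / sum(w$n_valid)
    w
  })
  out
}

#' Principal component analysis of the SNP matrix
#'
#' Centered haploid allele-count PCA via singular value decomposition;
#' deterministic up to component sign. Missing calls are imputed with the
#' site mean. Rank-deficient inputs simply yield fewer components.
#'
#' @param snps a `snp_matrix`.
#' @param strains optional strain subset (default: all).
#' @return An object of class `snp_pca`: list with `scores` (tibble,
#'   strain x PCs) and `explained` (per-component variance fractions,
#'   non-increasing, summing to <= 1).
#' @export
snp_pca <- function(snps, strains = NULL) {
  if (is.null(strains)) strains <- rownames(snps$alleles)
  if (length(strains) < 3) abort("PCA needs >= 3 strains")
  x <- snp_counts(snps, strains) * 1.0
  if (ncol(x) < 2) abort("PCA needs >= 2 SNPs")
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  keep <- ev > 1e-12
  explained <- ev[keep] / sum(ev)
  scores <- as_tibble(pr$x[, keep, drop = FALSE])
  scores <- mutate(scores, strain = strains, .before = 1)
  structure(list(scores = scores, explained = explained),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat(sprintf("<snp_pca> %d strains, %d components; PC1+PC2 explain %.1f%% of variance\n",
              nrow(x$scores), length(x$explained),
              100 * sum(x$explained[seq_len(min(2, length(x$explained)))])))
  invisible(x)
}
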