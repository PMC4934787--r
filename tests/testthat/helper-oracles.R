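# Independent direct-from-definition oracles. These deliberately use naive
# loops and published closed forms, sharing no code with the package.

CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# windowed pairwise divergence by explicit looping over sites
o_window_d <- function(gm, s1, s2, windows) {
  a <- gm$alleles[s1, ]
  b <- gm$alleles[s2, ]
  cn <- gm$contigs$contig[gm$contig]
  vapply(seq_len(nrow(windows)), function(w) {
    nd <- 0L; nv <- 0L
    for (i in seq_along(a)) {
      if (cn[i] == windows$contig[w] && gm$pos[i] >= windows$start[w] &&
          gm$pos[i] <= windows$end[w] && gm$valid[i]) {
        nv <- nv + 1L
        if (a[i] != b[i]) nd <- nd + 1L
      }
    }
    if (nv == 0) NA_real_ else nd / nv
  }, numeric(1))
}

# pi by explicit pair loops with pairwise gap deletion
o_pi_pairwise <- function(gm, strains) {
  tot <- 0; np <- 0
  for (i in seq_along(strains)) {
    for (j in seq_along(strains)) {
      if (j <= i) next
      a <- gm$alleles[strains[i], gm$valid]
      b <- gm$alleles[strains[j], gm$valid]
      ok <- a != 0 & b != 0
      tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
      np <- np + 1
    }
  }
  tot / np
}

# pi from the unfolded SFS: sum 2 i (n-i) xi_i / (n (n-1) L)
o_pi_sfs <- function(gm, strains) {
  a <- gm$alleles[strains, gm$valid, drop = FALSE]
  n <- length(strains)
  L <- ncol(a)
  tot <- 0
  for (s in seq_len(L)) {
    col <- a[, s]
    for (base in 1:4) {
      i <- sum(col == base)
      if (i > 0 && i < n) tot <- tot + i * (n - i)
    }
  }
  # each biallelic site contributes i*(n-i) twice (once per allele)
  tot / (n * (n - 1)) / L
}

o_a1 <- function(n) sum(1 / seq_len(n - 1))
o_a2 <- function(n) sum(1 / seq_len(n - 1)^2)

# Tajima's D from S and mean pairwise differences (total, not per site)
o_tajima_d <- function(n, S, pi_total) {
  a1 <- o_a1(n); a2 <- o_a2(n)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_total - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

o_fuli_d <- function(n, S, eta_e) {
  a1 <- o_a1(n); a2 <- o_a2(n)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  (S - a1 * eta_e) / sqrt(uD * S + vD * S^2)
}

o_fuli_dstar <- function(n, S, eta_s) {
  a1 <- o_a1(n); a2 <- o_a2(n)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  an1 <- a1 + 1 / n
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vDs <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
            2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  uDs <- n / (n - 1) * (a1 - n / (n - 1)) - vDs
  (n / (n - 1) * S - a1 * eta_s) / sqrt(uDs * S + vDs * S^2)
}

# Fay & Wu's H (pi - theta_H) from the unfolded SFS
o_faywu_h <- function(n, xi) {
  i <- seq_len(n - 1)
  sum(2 * i * (n - i) * xi / (n * (n - 1))) -
    sum(2 * xi * i^2 / (n * (n - 1)))
}

# Fu's Fs via the Ewens sampling formula computed with explicit falling
# products (no shared Stirling code path: build P(K = k) by enumerating
# the recursion on the rising factorial directly)
o_fu_fs <- function(n, k_obs, theta) {
  # |S(n,k)| via the defining polynomial: theta^(rising n) coefficients
  # of prod_{j=0}^{n-1} (theta + j)
  coefs <- 1
  for (j in 0:(n - 1)) coefs <- c(0, coefs) + j * c(coefs, 0)
  # coefs[k+1] = coefficient of theta^k = |S(n, k)|
  pk <- vapply(1:n, function(k) coefs[k + 1] * theta^k, numeric(1))
  pk <- pk / sum(pk)
  sp <- sum(pk[k_obs:n])
  log(sp / (1 - sp))
}

# single-site Hudson Fst components
o_hudson_site <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

# TN93 via ape on a two-sequence alignment (independent implementation)
o_tn93_ape <- function(gm, s1, s2) {
  a <- gm$alleles[c(s1, s2), gm$valid, drop = FALSE]
  chars <- matrix(c("-", "A", "C", "G", "T")[a + 1L], nrow = 2)
  rownames(chars) <- c(s1, s2)
  db <- ape::as.DNAbin(tolower(chars))
  as.numeric(ape::dist.dna(db, model = "TN93", pairwise.deletion = TRUE))
}
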