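test_that("pi: trivial cases and agreement of pairwise and SFS routes", {
  gm <- gm_from_strings(c(a = "ACGT", b = "ACGT"))
  pm <- popmap_of(P = c("a", "b"))
  expect_equal(nucleotide_diversity(gm, pm, "P")$pi, 0)

  seq100 <- paste(rep("A", 100), collapse = "")
  seq99 <- paste(c(rep("A", 99), "C"), collapse = "")
  gm2 <- gm_from_strings(c(a = seq100, b = seq99))
  expect_equal(nucleotide_diversity(gm2, popmap_of(P = c("a", "b")), "P")$pi,
               0.01)

  for (seed in 1:5) {
    gmr <- random_gm(5, 2000, mut_rate = 0.03, seed = seed)
    strains <- strain_names(gmr)
    pi_pkg <- nucleotide_diversity(gmr, strains = strains)$pi
    expect_equal(pi_pkg, o_pi_pairwise(gmr, strains), tolerance = 1e-12)
    expect_equal(pi_pkg, o_pi_sfs(gmr, strains), tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(gm, strains = "a"), ">= 2 strains")
})

test_that("neutrality tests match direct-from-definition oracles", {
  for (seed in 1:10) {
    n <- 8
    gmr <- random_gm(n + 2, 1500, mut_rate = 0.04, seed = 100 + seed)
    strains <- strain_names(gmr)[1:n]
    # outgroup population: two copies of an independent pair
    pm <- popmap_of(P = strains, O = strain_names(gmr)[(n + 1):(n + 2)])
    snps <- select_snps(gmr)
    res <- neutrality_tests(snps, pm, "P")
    res_og <- neutrality_tests(snps, pm, "P", outgroup_pop = "O")

    # oracle quantities recomputed naively from the allele matrix
    sub <- gmr$alleles[strains, , drop = FALSE]
    seg_cols <- which(apply(sub, 2, function(col) length(unique(col))) == 2)
    S <- length(seg_cols)
    counts <- sapply(seg_cols, function(j) {
      tab <- sort(table(sub[, j]))
      tab[[1]]
    })
    pi_total <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pi_total <- pi_total + sum(sub[i, ] != sub[j, ])
    }
    pi_total <- pi_total / choose(n, 2)   # mean pairwise differences
    expect_equal(res$S, S)
    expect_equal(res$pi * snps$n_total_sites, pi_total, tolerance = 1e-10)
    expect_equal(res$tajima_d, o_tajima_d(n, S, pi_total),
                 tolerance = 1e-10)
    eta_s <- sum(counts == 1)
    expect_equal(res$fu_li, o_fuli_dstar(n, S, eta_s), tolerance = 1e-10)
    expect_equal(res$fu_li_variant, "D*")

    # polarized versions against the outgroup-consensus
    og_cons <- apply(gmr$alleles[(n + 1):(n + 2), seg_cols, drop = FALSE],
                     2, function(col) {
                       u <- unique(col)
                       if (length(u) == 1L) u else NA_integer_
                     })
    derived <- sapply(seq_along(seg_cols), function(k) {
      col <- sub[, seg_cols[k]]
      if (is.na(og_cons[k]) || !og_cons[k] %in% col) return(NA_integer_)
      sum(col != og_cons[k])
    })
    pol <- !is.na(derived)
    expect_equal(res_og$fu_li,
                 o_fuli_d(n, sum(pol), sum(derived[pol] == 1)),
                 tolerance = 1e-10)
    xi <- tabulate(derived[pol], nbins = n - 1)
    expect_equal(res_og$fay_wu_h, o_faywu_h(n, xi), tolerance = 1e-10)

    # Fu's Fs against the falling-product Ewens oracle
    k_obs <- length(unique(apply(sub, 1, paste, collapse = "")))
    expect_equal(res$fs, o_fu_fs(n, k_obs, pi_total), tolerance = 1e-8)
  }
})

test_that("neutrality edge cases: S = 0, n < 4, forced signs", {
  gm <- gm_from_strings(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  pm <- popmap_of(P = c("a", "b", "c", "d"))
  res <- neutrality_tests(select_snps(gm), pm, "P")
  expect_true(is.na(res$tajima_d))
  expect_match(res$note, "S = 0")

  # all derived singletons held by one strain: D < 0, H > 0
  base <- paste(rep("A", 100), collapse = "")
  carrier <- paste(c(rep("A", 95), rep("C", 5)), collapse = "")
  gm2 <- gm_from_strings(c(s1 = carrier, s2 = base, s3 = base, s4 = base,
                           s5 = base, s6 = base, og1 = base, og2 = base))
  pm2 <- popmap_of(P = paste0("s", 1:6), O = c("og1", "og2"))
  res2 <- neutrality_tests(select_snps(gm2), pm2, "P", outgroup_pop = "O")
  expect_equal(res2$S, 5L)
  expect_lt(res2$tajima_d, 0)
  expect_gt(res2$fay_wu_h, 0)

  pm3 <- popmap_of(P = paste0("s", 1:3))
  res3 <- neutrality_tests(select_snps(gm2), pm3, "P")
  expect_match(res3$note, "n < 4")
})

test_that("Tajima's D vanishes when pi equals S/a1 by construction", {
  # n = 4, a1 = 11/6: 8 singleton + 3 doubleton sites give
  # pi_total = 8 * 1/2 + 3 * 2/3 = 6 = 11 / a1 = S / a1 exactly
  cols <- c(rep(list(c("C", "A", "A", "A")), 4),
            rep(list(c("A", "C", "A", "A")), 4),
            rep(list(c("C", "C", "A", "A")), 3),
            list(c("A", "A", "A", "A")))
  mat <- do.call(cbind, cols)
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- paste0("s", 1:4)
  gm <- gm_from_strings(as.list(seqs))
  res <- neutrality_tests(select_snps(gm), popmap_of(P = paste0("s", 1:4)),
                          "P")
  expect_equal(res$S, 11L)
  expect_equal(res$tajima_d, 0, tolerance = 1e-12)
})

test_that("Hudson Fst: closed-form site values and ratio of averages", {
  # one site, p1 = 0.2, p2 = 0.8, n1 = n2 = 10
  s1 <- c(rep("A", 8), rep("C", 2))
  s2 <- c(rep("A", 2), rep("C", 8))
  seqs <- c(stats::setNames(s1, paste0("p", 1:10)),
            stats::setNames(s2, paste0("q", 1:10)))
  gm <- gm_from_strings(as.list(seqs))
  pm <- popmap_of(P = paste0("p", 1:10), Q = paste0("q", 1:10))
  snps <- select_snps(gm)
  o <- o_hudson_site(0.2, 0.8, 10, 10)
  expect_equal(pairwise_fst(snps, pm, "P", "Q")$fst_raw,
               unname(o["num"] / o["den"]), tolerance = 1e-12)

  # identical allele frequencies -> Fst approx 0 (raw may be negative)
  gm2 <- gm_from_strings(as.list(c(
    stats::setNames(c("A", "C", "A", "C"), paste0("p", 1:4)),
    stats::setNames(c("A", "C", "A", "C"), paste0("q", 1:4)))))
  pm2 <- popmap_of(P = paste0("p", 1:4), Q = paste0("q", 1:4))
  f2 <- pairwise_fst(select_snps(gm2), pm2, "P", "Q")
  expect_equal(f2$fst, 0)
  expect_lte(f2$fst_raw, 0)

  # reciprocally fixed site -> Fst = 1
  gm3 <- gm_from_strings(as.list(c(
    stats::setNames(rep("A", 4), paste0("p", 1:4)),
    stats::setNames(rep("C", 4), paste0("q", 1:4)))))
  f3 <- pairwise_fst(select_snps(gm3), pm2, "P", "Q")
  expect_equal(f3$fst, 1)

  # ratio of averages over many sites equals the summed oracle
  gmr <- random_gm(8, 800, mut_rate = 0.05, seed = 31)
  pmr <- popmap_of(P = strain_names(gmr)[1:4], Q = strain_names(gmr)[5:8])
  snpr <- select_snps(gmr)
  xp <- snpr$alleles[pmr$strain[pmr$population == "P"], , drop = FALSE]
  xq <- snpr$alleles[pmr$strain[pmr$population == "Q"], , drop = FALSE]
  num <- den <- 0
  for (j in seq_len(ncol(snpr$alleles))) {
    p1 <- mean(xp[, j] == snpr$allele2[j])
    p2 <- mean(xq[, j] == snpr$allele2[j])
    if (p1 == p2 && (p1 == 0 || p1 == 1)) next
    o <- o_hudson_site(p1, p2, 4, 4)
    num <- num + o["num"]; den <- den + o["den"]
  }
  expect_equal(pairwise_fst(snpr, pmr, "P", "Q")$fst_raw,
               unname(num / den), tolerance = 1e-10)
})

test_that("TN93 matches ape and dominates the raw p-distance", {
  skip_if_not_installed("ape")
  expect_equal(tn93_distance(
    gm_from_strings(c(a = "ACGTT", b = "ACGTT")), "a", "b")$tn93, 0)
  for (seed in 1:5) {
    gmr <- random_gm(2, 3000, mut_rate = 0.08, seed = 200 + seed)
    d <- tn93_distance(gmr, "s01", "s02")
    expect_equal(d$tn93, o_tn93_ape(gmr, "s01", "s02"), tolerance = 1e-8)
    expect_gte(d$tn93, d$p_distance - 1e-12)
  }
})

test_that("polymorphism classes partition segregating sites", {
  # hand-built 4+4: 2 fixed, 1 shared, 3 private-P, 1 private-Q columns
  # (columns 1-2 fixed, 3 shared, 4-6 private to P, 7 private to Q, 8-9
  # monomorphic)
  p_seqs <- c("ACACAAAAA", "ACAACAAAA", "ACCAACAAA", "ACCAAAAAA")
  q_seqs <- c("CGAAAACAA", "CGCAAAAAA", "CGCAAAAAA", "CGAAAAAAA")
  gm <- gm_from_strings(as.list(c(
    stats::setNames(p_seqs, paste0("p", 1:4)),
    stats::setNames(q_seqs, paste0("q", 1:4)))))
  pm <- popmap_of(P = paste0("p", 1:4), Q = paste0("q", 1:4))
  snps <- select_snps(gm)
  cls <- classify_polymorphisms(snps, pm, "P", "Q")
  expect_equal(cls$fixed, 2L)
  expect_equal(cls$shared, 1L)
  expect_equal(cls$private_p, 3L)
  expect_equal(cls$private_q, 1L)
  expect_equal(cls$fixed + cls$shared + cls$private_p + cls$private_q,
               ncol(snps$alleles))
  expect_equal(cls$pct_fixed, 100 * 2 / snps$n_total_sites)

  # identical monomorphic populations -> all classes zero
  gm0 <- gm_from_strings(c(p1 = "AAAA", p2 = "AAAA", q1 = "AAAA",
                           q2 = "AAAA"))
  cls0 <- classify_polymorphisms(
    select_snps(gm0), popmap_of(P = c("p1", "p2"), Q = c("q1", "q2")),
    "P", "Q")
  expect_equal(cls0$fixed + cls0$shared + cls0$private_p + cls0$private_q, 0L)
})

test_that("D statistic: trivial site patterns and P1/P2 antisymmetry", {
  # P3 shares the derived allele with P2 only -> pure ABBA, D = 1
  mk <- function(p1, p2, p3, og, L = 30) {
    reps <- function(ch) paste(rep(ch, L), collapse = "")
    gm_from_strings(c(p1a = reps(p1), p1b = reps(p1),
                      p2a = reps(p2), p2b = reps(p2),
                      p3a = reps(p3), p3b = reps(p3),
                      oga = reps(og), ogb = reps(og)))
  }
  pm <- popmap_of(P1 = c("p1a", "p1b"), P2 = c("p2a", "p2b"),
                  P3 = c("p3a", "p3b"), O = c("oga", "ogb"))
  d_abba <- d_statistic(select_snps(mk("A", "C", "C", "A")), pm,
                        "P1", "P2", "P3", "O")
  expect_equal(d_abba$d, 1)
  d_baba <- d_statistic(select_snps(mk("C", "A", "C", "A")), pm,
                        "P1", "P2", "P3", "O")
  expect_equal(d_baba$d, -1)

  # balanced ABBA/BABA counts by construction -> D = 0
  half <- function(c1, c2, L = 15) paste(
    c(rep(c1, L), rep(c2, L)), collapse = "")
  gm_bal <- gm_from_strings(c(
    p1a = half("A", "C"), p1b = half("A", "C"),
    p2a = half("C", "A"), p2b = half("C", "A"),
    p3a = half("C", "C"), p3b = half("C", "C"),
    oga = half("A", "A"), ogb = half("A", "A")))
  d_bal <- d_statistic(select_snps(gm_bal), pm, "P1", "P2", "P3", "O")
  expect_equal(d_bal$d, 0)

  # swapping P1 and P2 flips the sign exactly
  gmr <- random_gm(8, 2000, mut_rate = 0.05, seed = 77)
  pmr <- popmap_of(P1 = strain_names(gmr)[1:2], P2 = strain_names(gmr)[3:4],
                   P3 = strain_names(gmr)[5:6], O = strain_names(gmr)[7:8])
  d12 <- d_statistic(select_snps(gmr), pmr, "P1", "P2", "P3", "O")
  d21 <- d_statistic(select_snps(gmr), pmr, "P2", "P1", "P3", "O")
  expect_equal(d12$d, -d21$d, tolerance = 1e-12)
})

test_that("D is near zero when groups are arbitrary splits of one pool", {
  # null without gene flow: standing variation shared by descent only —
  # a single panmictic population whose members are relabeled into
  # P1/P2/P3, with an outside population fixing polarity
  zs <- c()
  for (seed in 1:6) {
    cfg <- sim_config(
      chromosomes = c(chrI = 300000L, chrII = 300000L),
      populations = list(
        list(label = "O", n = 2L, pi = 0.0005, parent = "root",
             div = 0.006),
        list(label = "Pool", n = 9L, pi = 0.004, parent = "root",
             div = 0.002)),
      seed = 300 + seed)
    sim <- simulate_populations(cfg)
    gm <- apply_gap_mask(sim$gm)
    pm <- tibble::tibble(
      strain = c(paste0("Pool_", 1:9), paste0("O_", 1:2)),
      population = c(rep(c("P1", "P2", "P3"), each = 3), "O", "O"),
      subpopulation = NA_character_)
    res <- d_statistic(select_snps(gm), pm, "P1", "P2", "P3", "O",
                       block_bp = 20000)
    zs <- c(zs, res$z)
    expect_gte(res$n_blocks, 20)
  }
  expect_gte(mean(abs(zs) < 3), 0.95 - 1e-9)
})

test_that("heterozygosity windows match hand counts", {
  gm <- random_gm(2, 100000, seed = 9)
  w <- make_windows(gm, 50000)
  het <- tibble::tibble(strain = "s01", contig = "chr1",
                        pos = c(10L, 20L, 30L, 40L, 50L, 60001L))
  prof <- heterozygosity_profile(het, w)
  expect_equal(prof$n_het, c(5L, 1L))
  expect_equal(prof$het_rate[1], 1e-4)
  expect_equal(unique(prof$genome_rate), 6 / 1e5)
  # no calls -> all zero
  prof0 <- heterozygosity_profile(het[0, ], w)
  expect_equal(nrow(prof0), 0L)
})

test_that("SNP PCA separates clusters and reports sane variance fractions", {
  gm <- gm_from_strings(c(a1 = "AAAAACCCCC", a2 = "AAAAACCCCC",
                          b1 = "CCCCCAAAAA", b2 = "CCCCCAAAAA"))
  p <- snp_pca(select_snps(gm))
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-12)

  sim <- shared_sim()
  gm2 <- apply_gap_mask(subset_strains(sim$gm, c(
    paste0("PopA_", 1:6), paste0("PopB_", 1:6),
    paste0("Tibet_", 1:4), paste0("NorthCarolina_", 1:2))))
  p2 <- snp_pca(select_snps(gm2))
  sc <- p2$scores
  grp <- sub("_[0-9]+$", "", sc$strain)
  # PopA is the most diverged group: positive silhouette on PC1
  a <- sc$PC1[grp == "PopA"]; rest <- sc$PC1[grp != "PopA"]
  expect_true(max(a) < min(rest) || min(a) > max(rest))  # clean PC1 split
  expect_gt(sum(p2$explained[1:2]), 0.5)
})

test_that("f4 ratio recovers an admixture proportion", {
  cfg <- sim_config(
    chromosomes = c(chrI = 300000L, chrII = 300000L),
    populations = list(
      list(label = "O", n = 2L, pi = 0.001, parent = "root", div = 0.008),
      list(label = "Anc", n = 2L, pi = 0, parent = "root", div = 0.002),
      list(label = "P1", n = 3L, pi = 0.001, parent = "Anc", div = 0.002),
      list(label = "P2", n = 3L, pi = 0.001, parent = "Anc", div = 0.002),
      list(label = "A1", n = 2L, pi = 0.0005, parent = "P1", div = 0.001)),
    seed = 91)
  sim <- simulate_populations(cfg)
  sim <- simulate_admixed(sim, "P2", "P1", f = 0.6, tract_scale = 60000,
                          seed = 92)
  gm <- apply_gap_mask(sim$gm)
  snps <- select_snps(gm)
  pm <- sim$popmap
  truth_f <- sim$truth$fractions$fraction[
    sim$truth$fractions$population == "P1"]
  # X admixed between B = P1 (fraction f) and C = P2
  res <- f4_ratio(snps, pm, a = "A1", b = "P1", x = "Admixed", c = "P2",
                  o = "O")
  expect_equal(res$alpha, truth_f, tolerance = 0.12)
})
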