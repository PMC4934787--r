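# Small builders shared across test files. All stochastic fixtures carry
# explicit seeds so the suite is deterministic.

# genotype matrix from named sequence strings; one contig unless `split`
# gives per-contig lengths
gm_from_strings <- function(seqs, split = NULL) {
  chars <- strsplit(unlist(seqs), "")
  len <- length(chars[[1]])
  stopifnot(all(lengths(chars) == len))
  alleles <- do.call(rbind, chars)
  rownames(alleles) <- names(seqs)
  if (is.null(split)) split <- len
  stopifnot(sum(split) == len)
  if (is.null(names(split))) names(split) <- paste0("chr", seq_along(split))
  genotype_matrix(
    alleles,
    contig = rep(seq_along(split), split),
    pos = unlist(lapply(split, seq_len), use.names = FALSE),
    contigs = tibble::tibble(contig = names(split), length = unname(split))
  )
}

popmap_of <- function(...) {
  x <- list(...)
  tibble::tibble(
    strain = unlist(x, use.names = FALSE),
    population = rep(names(x), lengths(x)),
    subpopulation = NA_character_
  )
}

# random gap-free genotype matrix: n strains x L sites, each site iid with
# a given chance of carrying a mutation in a random subset of strains
random_gm <- function(n, L, mut_rate = 0.05, seed = 1, n_contigs = 1) {
  withr::with_seed(seed, {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    alleles <- matrix(rep(anc, each = n), nrow = n)
    mut_sites <- which(stats::runif(L) < mut_rate)
    for (s in mut_sites) {
      k <- sample.int(n - 1, 1)
      carriers <- sample.int(n, k)
      alleles[carriers, s] <- sample(setdiff(c("A", "C", "G", "T"),
                                             anc[s]), 1)
    }
    rownames(alleles) <- sprintf("s%02d", seq_len(n))
    split <- rep(L %/% n_contigs, n_contigs)
    split[n_contigs] <- L - sum(split[-n_contigs])
    gm_from_strings(apply(alleles, 1, paste, collapse = ""), split = split)
  })
}

# cached moderate-size simulation shared by scan/classifier unit tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(chromosomes = c(chrI = 250000L, chrII = 250000L),
                        seed = 42)
      sim <- simulate_populations(cfg)
      sim <- simulate_admixed(sim, "PopA", "PopB", f = 0.42,
                              tract_scale = 60000, min_tract_bp = 50000,
                              seed = 43)
      cache <<- sim
    }
    cache
  }
})
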