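#' Simulation configuration
#'
#' Describes the standing-variation structure the analysis assumes: a set
#' of source populations with target within-population diversity (pi) and
#' fixed divergence from a parent lineage, optionally split into
#' sublineages, on a shared chromosome layout. Mutations follow an
#' infinite-sites model on a star-like within-population genealogy
#' approximation: derived-allele counts are drawn from the neutral site
#' frequency spectrum (P(i) proportional to 1/i), with the segregating
#' site count chosen so the SFS-expected pi matches the target
#' (`S = round(pi * L * a1)`). There is no recombination within source
#' populations; mosaics are created by [simulate_admixed()] /
#' [simulate_lager_like()].
#'
#' The default layout is the desk-scale study system: four 500-kbp
#' chromosomes; two diverse populations 1% diverged (pi 0.0035 / 0.0027,
#' mirroring the two Patagonian populations); and a low-diversity lineage
#' (pi target 0.002) hanging off the second population at 0.002 fixed
#' divergence, split 0.002 into a larger and a smaller sublineage
#' (mirroring the Tibetan and North Carolinian arms of the Holarctic
#' clade).
#'
#' @param chromosomes named integer vector of chromosome lengths in bp.
#' @param populations list of population specs: each a list with `label`,
#'   `n`, `pi` (target per-site diversity), `parent` (`"root"` or another
#'   population label), `div` (fixed per-site divergence accumulated from
#'   the parent founder), and optionally `sublineages`, a list of
#'   `list(label, n, ...)` whose founders each diverge `split/2` from the
#'   population founder.
#' @param seed mandatory integer seed; every stochastic draw derives from
#'   it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(chromosomes = c(chrI = 500000L, chrII = 500000L,
                                       chrIII = 500000L, chrIV = 500000L),
                       populations = default_populations(),
                       seed = 1L) {
  stopifnot(length(chromosomes) >= 1, all(chromosomes >= 1000),
            !is.null(names(chromosomes)))
  for (p in populations) {
    stopifnot(!is.null(p$label), !is.null(p$n), p$n >= 1,
              !is.null(p$pi), p$pi >= 0, !is.null(p$div), p$div >= 0)
    if ((p$pi + p$div) > 0.75) abort("infeasible config: per-site targets > 0.75")
    if (!is.null(p$sublineages)) {
      stopifnot(length(p$sublineages) >= 2, !is.null(p$split))
      if (sum(purrr::map_int(p$sublineages, "n")) != p$n) {
        abort(sprintf("sublineage sizes of '%s' must sum to n", p$label))
      }
    }
  }
  structure(list(chromosomes = chromosomes, populations = populations,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_populations <- function() {
  list(
    list(label = "PopA", n = 6L, pi = 0.0035, parent = "root", div = 0.005),
    list(label = "PopB", n = 6L, pi = 0.0027, parent = "root", div = 0.005),
    list(label = "Holarctic", n = 6L, pi = 0.001, parent = "PopB",
         div = 0.002, split = 0.002,
         sublineages = list(list(label = "Tibet", n = 4L),
                            list(label = "NorthCarolina", n = 2L)))
  )
}

#' Simulate structured populations with known truth
#'
#' Draws an ancestral sequence uniformly over A/C/G/T, accumulates
#' population- and sublineage-founder fixed differences at the configured
#' per-site rates (infinite sites: every mutation hits a fresh position),
#' then overlays within-population segregating sites whose derived-allele
#' counts follow the neutral SFS. Fully deterministic given the config
#' seed.
#'
#' @param cfg a [sim_config()].
#' @return A list with `gm` (gap-free `genotype_matrix`), `popmap`
#'   (tibble), and `truth` — a list carrying per-population realized pi
#'   and pairwise founder divergences alongside their targets.
#' @export
simulate_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    chrs <- cfg$chromosomes
    L_tot <- sum(chrs)
    ancestral <- sample.int(4L, L_tot, replace = TRUE)
    free <- rep(TRUE, L_tot)     # infinite sites: positions not yet mutated

    take_sites <- function(k) {
      avail <- which(free)
      if (k > length(avail)) abort("infeasible config: ran out of sites")
      s <- if (k > 0) sample(avail, k) else integer(0)
      free[s] <<- FALSE
      s
    }
    mutate_seq <- function(seq, sites) {
      if (length(sites)) {
        shift <- sample.int(3L, length(sites), replace = TRUE)
        seq[sites] <- ((seq[sites] - 1L + shift) %% 4L) + 1L
      }
      seq
    }

    founders <- list(root = ancestral)
    strains <- list()
    popmap <- list()
    pi_targets <- list()
    for (p in cfg$populations) {
      parent_seq <- founders[[p$parent]]
      if (is.null(parent_seq)) abort(sprintf("unknown parent '%s'", p$parent))
      founder <- mutate_seq(parent_seq, take_sites(round(p$div * L_tot)))
      founders[[p$label]] <- founder

      sub_specs <- p$sublineages %||%
        list(list(label = NA_character_, n = p$n))
      sub_founders <- lapply(sub_specs, function(sl) {
        if (is.null(p$split)) return(founder)
        mutate_seq(founder, take_sites(round(p$split / 2 * L_tot)))
      })

      # within-population segregating sites over all n members
      n <- p$n
      member_names <- unlist(lapply(sub_specs, function(sl) {
        lab <- if (is.na(sl$label)) p$label else sl$label
        sprintf("%s_%d", lab, seq_len(sl$n))
      }))
      sub_of <- rep(seq_along(sub_specs), purrr::map_int(sub_specs, "n"))
      mat <- do.call(rbind, lapply(sub_of, function(si) sub_founders[[si]]))
      if (n >= 2 && p$pi > 0) {
        a1 <- a1_fun(n)
        S <- round(p$pi * L_tot * a1)
        sites <- take_sites(S)
        i_draw <- sample(seq_len(n - 1), S, replace = TRUE,
                         prob = 1 / seq_len(n - 1))
        shift <- sample.int(3L, S, replace = TRUE)
        # at a free site every lineage still carries the ancestral base
        newb <- ((ancestral[sites] - 1L + shift) %% 4L) + 1L
        carrier_vec <- unlist(lapply(i_draw, function(k) sample.int(n, k)))
        site_vec <- rep(sites, i_draw)
        base_vec <- rep(newb, i_draw)
        mat[cbind(carrier_vec, site_vec)] <- base_vec
      }
      for (k in seq_len(n)) strains[[member_names[k]]] <- mat[k, ]
      popmap[[p$label]] <- tibble(
        strain = member_names, population = p$label,
        subpopulation = purrr::map_chr(sub_of, function(si) {
          sl <- sub_specs[[si]]$label
          if (is.na(sl)) NA_character_ else sl
        }))
      pi_targets[[p$label]] <- p$pi
    }

    alleles <- do.call(rbind, strains)
    rownames(alleles) <- names(strains)
    gm <- genotype_matrix(
      alleles = alleles,
      contig = rep(seq_along(chrs), chrs),
      pos = unlist(lapply(chrs, seq_len), use.names = FALSE),
      contigs = tibble(contig = names(chrs), length = unname(chrs))
    )
    popmap <- dplyr::bind_rows(popmap)

    realized_pi <- purrr::map_dfr(cfg$populations, function(p) {
      if (p$n < 2) return(tibble())
      nucleotide_diversity(gm, popmap, p$label) %>%
        mutate(target = pi_targets[[p$label]])
    })
    labels <- purrr::map_chr(cfg$populations, "label")
    founder_div <- if (length(labels) >= 2) {
      purrr::map_dfr(utils::combn(labels, 2, simplify = FALSE),
        function(pr) {
          tibble(pop_p = pr[1], pop_q = pr[2],
                 founder_divergence =
                   mean(founders[[pr[1]]] != founders[[pr[2]]]))
        })
    } else {
      tibble(pop_p = character(), pop_q = character(),
             founder_divergence = numeric())
    }
    list(gm = gm, popmap = popmap,
         truth = list(realized_pi = realized_pi,
                      founder_divergence = founder_div,
                      config = cfg))
  })
}

# alternating-donor crossover process along one chromosome: tracts strictly
# alternate between the two parents (each boundary is a crossover); the
# first donor is pop_b with probability f, and donor-specific tract scales
# (2 f s for b, 2 (1-f) s for a) keep the long-run b fraction at f. A
# minimum tract length is enforced by redraw.
draw_tracts <- function(clen, tract_scale, f, min_tract_bp = 0,
                        first_b = NULL) {
  if (is.null(first_b)) first_b <- stats::runif(1) < f
  scale_of <- function(is_b) 2 * tract_scale * if (is_b) f else 1 - f
  draw_len <- function(is_b) {
    len <- stats::rexp(1, rate = 1 / scale_of(is_b))
    while (len < min_tract_bp) len <- stats::rexp(1, rate = 1 / scale_of(is_b))
    len
  }
  starts <- integer(0); ends <- integer(0); is_b <- logical(0)
  pos <- 0; cur <- first_b
  repeat {
    len <- draw_len(cur)
    tr_end <- if (pos + len >= clen - min_tract_bp) clen else floor(pos + len)
    starts <- c(starts, as.integer(pos + 1))
    ends <- c(ends, as.integer(tr_end))
    is_b <- c(is_b, cur)
    if (tr_end >= clen) break
    pos <- tr_end
    cur <- !cur
  }
  tibble(start = starts, end = ends, is_b = is_b)
}

#' Add a mosaic admixed strain to a simulated genome set
#'
#' Emulates a haploselfed F1-outcross product: tracts strictly alternate
#' between the two donor populations (every boundary is a crossover), with
#' exponential tract lengths whose donor-specific scales (`2 f
#' tract_scale` for `pop_b`, `2 (1-f) tract_scale` for `pop_a`) keep the
#' expected `pop_b` genome fraction at `f`; the first donor of each
#' chromosome is `pop_b` with probability `f`. The sequence is copied from
#' one uniformly chosen donor strain per tract. The truth records the
#' realized tracts, crossover count and ancestry fractions.
#'
#' @param sim output of [simulate_populations()] (list with `gm`,
#'   `popmap`, `truth`).
#' @param pop_a,pop_b donor population labels.
#' @param f target genome fraction drawn from `pop_b`, in (0, 1).
#' @param tract_scale mean inter-crossover distance in bp.
#' @param strain name for the new strain (default `"admixed_1"`).
#' @param min_tract_bp minimum realized tract length (0 disables).
#' @param private_div per-site rate of private substitutions sprinkled on
#'   the new strain after tract copying (default 5e-4), emulating that the
#'   haplotypes it actually descends from are close relatives of — not
#'   identical to — the sampled donors.
#' @param seed RNG seed.
#' @return `sim` with the strain added to `gm`/`popmap` (population
#'   `"Admixed"`) and `truth$tracts`, `truth$crossovers`,
#'   `truth$fractions` filled in.
#' @export
simulate_admixed <- function(sim, pop_a, pop_b, f, tract_scale,
                             strain = "admixed_1", min_tract_bp = 0,
                             private_div = 5e-4, seed) {
  stopifnot(f > 0, f < 1)
  gm <- sim$gm
  if (tract_scale > max(gm$contigs$length)) {
    warn("tract_scale exceeds the longest chromosome: expect few tracts")
  }
  donors_a <- pop_strains(sim$popmap, pop_a)
  donors_b <- pop_strains(sim$popmap, pop_b)
  withr::with_seed(seed, {
    seq_new <- integer(ncol(gm$alleles))
    tracts <- list()
    for (ci in seq_len(nrow(gm$contigs))) {
      clen <- gm$contigs$length[ci]
      tr <- draw_tracts(clen, tract_scale, f, min_tract_bp)
      tr$donor_pop <- ifelse(tr$is_b, pop_b, pop_a)
      tr$is_b <- NULL
      tr$donor_strain <- purrr::map_chr(tr$donor_pop, function(dp) {
        pool <- if (dp == pop_b) donors_b else donors_a
        pool[sample.int(length(pool), 1)]
      })
      tr$contig <- gm$contigs$contig[ci]
      offset <- sum(gm$contigs$length[seq_len(ci - 1)])
      for (k in seq_len(nrow(tr))) {
        cols <- offset + (tr$start[k]:tr$end[k])
        seq_new[cols] <- gm$alleles[tr$donor_strain[k], cols]
      }
      tracts[[ci]] <- tr
    }
    if (private_div > 0) {
      k <- stats::rpois(1, private_div * length(seq_new))
      sites <- sample.int(length(seq_new), k)
      shift <- sample.int(3L, k, replace = TRUE)
      seq_new[sites] <- ((seq_new[sites] - 1L + shift) %% 4L) + 1L
    }
    tracts <- dplyr::bind_rows(tracts) %>%
      mutate(strain = strain, .before = 1) %>%
      select("strain", "contig", "start", "end", "donor_pop", "donor_strain")
    crossovers <- tracts %>%
      group_by(.data$contig) %>%
      reframe(position = .data$start[-1] - 0.5) %>%
      mutate(strain = strain, .before = 1)
    lens <- tracts$end - tracts$start + 1
    frac_b <- sum(lens[tracts$donor_pop == pop_b]) / sum(lens)
    sim$gm <- gm_add_strain(gm, strain, seq_new)
    sim$popmap <- dplyr::bind_rows(
      sim$popmap, tibble(strain = strain, population = "Admixed",
                         subpopulation = NA_character_))
    sim$truth$tracts <- dplyr::bind_rows(sim$truth$tracts, tracts)
    sim$truth$crossovers <- dplyr::bind_rows(sim$truth$crossovers, crossovers)
    sim$truth$fractions <- dplyr::bind_rows(
      sim$truth$fractions,
      tibble(strain = strain, population = c(pop_a, pop_b),
             fraction = c(1 - frac_b, frac_b)))
  })
  sim
}

#' Add lager-like hybrid subgenome queries with depth and heterozygosity
#'
#' Each query is mostly sublineage-1 ancestry of the source population with
#' implanted foreign tracts: `shared_regions` are drawn from sublineage 2
#' in every query; `discordant_regions` alternate — odd regions put the
#' foreign (sublineage 2) haplotype in query 1, even regions in query 2 —
#' so the queries carry different alleles drawn from the standing variation
#' of the source lineage. A Poisson per-1-kbp-window depth table scaled by
#' each query's chromosome ploidy map and heterozygous site flags injected
#' at `het_rate` outside the implanted regions are generated alongside.
#'
#' @param sim output of [simulate_populations()].
#' @param source_pop population with >= 2 sublineages (default
#'   `"Holarctic"`).
#' @param sublineages the background and foreign sublineage labels
#'   (default the first two of the source population).
#' @param n_queries number of query strains (default 2).
#' @param shared_regions,discordant_regions tibbles with `contig`,
#'   `start`, `end`; must not overlap each other.
#' @param ploidy_maps list (length `n_queries`) of integer vectors, one
#'   copy number per chromosome.
#' @param het_rate per-bp heterozygous-call rate outside implanted regions.
#' @param private_div per-site rate of query-private substitutions
#'   (default 5e-4; see [simulate_admixed()]).
#' @param base_depth single-copy mean depth (default 30).
#' @param depth_window_bp depth window size (default 1000).
#' @param seed RNG seed.
#' @return `sim` with queries added (population `"Lager"`), plus
#'   `depth` (tibble) and `het_calls` (tibble), and truth entries
#'   `implanted` and `ploidy`.
#' @export
simulate_lager_like <- function(sim, source_pop = "Holarctic",
                                sublineages = NULL, n_queries = 2,
                                shared_regions, discordant_regions,
                                ploidy_maps = NULL, het_rate = 2e-4,
                                private_div = 5e-4, base_depth = 30,
                                depth_window_bp = 1000, seed) {
  gm <- sim$gm
  pm <- sim$popmap
  subs <- unique(stats::na.omit(pm$subpopulation[pm$population == source_pop]))
  if (length(subs) < 2) abort("source population needs >= 2 sublineages")
  if (is.null(sublineages)) sublineages <- subs[1:2]
  regions <- dplyr::bind_rows(
    mutate(shared_regions, kind = "shared"),
    mutate(discordant_regions, kind = "discordant",
           which_query = (dplyr::row_number() - 1L) %% n_queries + 1L))
  # reject overlapping specs
  for (ct in unique(regions$contig)) {
    rr <- regions[regions$contig == ct, ]
    rr <- rr[order(rr$start), ]
    if (nrow(rr) > 1 && any(rr$start[-1] <= rr$end[-nrow(rr)])) {
      abort("implanted region specs overlap")
    }
  }
  bg_pool <- pop_strains(pm, source_pop, sublineages[1])
  fg_pool <- pop_strains(pm, source_pop, sublineages[2])
  if (is.null(ploidy_maps)) {
    ploidy_maps <- rep(list(rep(1L, nrow(gm$contigs))), n_queries)
  }
  stopifnot(length(ploidy_maps) == n_queries,
            all(lengths(ploidy_maps) == nrow(gm$contigs)))

  withr::with_seed(seed, {
    offsets <- c(0L, cumsum(gm$contigs$length))
    implanted <- list()
    depth <- list()
    het_calls <- list()
    for (qi in seq_len(n_queries)) {
      qname <- sprintf("lager_%d", qi)
      bg <- bg_pool[sample.int(length(bg_pool), 1)]
      seq_new <- gm$alleles[bg, ]
      in_region <- rep(FALSE, length(seq_new))
      for (k in seq_len(nrow(regions))) {
        rg <- regions[k, ]
        takes_foreign <- rg$kind == "shared" ||
          (rg$kind == "discordant" && rg$which_query == qi)
        ci <- match(rg$contig, gm$contigs$contig)
        cols <- offsets[ci] + (rg$start:rg$end)
        in_region[cols] <- TRUE
        if (takes_foreign) {
          donor <- fg_pool[sample.int(length(fg_pool), 1)]
          seq_new[cols] <- gm$alleles[donor, cols]
          implanted[[length(implanted) + 1]] <- tibble(
            strain = qname, contig = rg$contig, start = rg$start,
            end = rg$end, kind = rg$kind, donor_sublineage = sublineages[2],
            donor_strain = donor)
        }
      }
      if (private_div > 0) {
        kk <- stats::rpois(1, private_div * length(seq_new))
        psites <- sample.int(length(seq_new), kk)
        pshift <- sample.int(3L, kk, replace = TRUE)
        seq_new[psites] <- ((seq_new[psites] - 1L + pshift) %% 4L) + 1L
      }
      sim$gm <- gm_add_strain(sim$gm, qname, seq_new)
      sim$popmap <- dplyr::bind_rows(
        sim$popmap, tibble(strain = qname, population = "Lager",
                           subpopulation = NA_character_))
      # depth table
      dw <- purrr::map_dfr(seq_len(nrow(gm$contigs)), function(ci) {
        clen <- gm$contigs$length[ci]
        starts <- seq(1L, clen, by = depth_window_bp)
        lam <- base_depth * ploidy_maps[[qi]][ci]
        tibble(strain = qname, contig = gm$contigs$contig[ci],
               start = starts, end = pmin(starts + depth_window_bp - 1L, clen),
               depth = stats::rpois(length(starts), lam))
      })
      depth[[qi]] <- dw
      # heterozygous flags outside implanted regions
      n_het <- stats::rpois(1, het_rate * sum(!in_region))
      het_pos <- sort(sample(which(!in_region), n_het))
      het_calls[[qi]] <- tibble(
        strain = qname,
        contig = gm$contigs$contig[gm$contig[het_pos]],
        pos = gm$pos[het_pos])
      sim$truth$ploidy <- dplyr::bind_rows(
        sim$truth$ploidy,
        tibble(strain = qname, contig = gm$contigs$contig,
               copy = ploidy_maps[[qi]]))
    }
    sim$depth <- dplyr::bind_rows(depth)
    sim$het_calls <- dplyr::bind_rows(het_calls)
    sim$truth$implanted <- dplyr::bind_rows(implanted)
  })
  sim
}

#' Write simulator outputs to a directory
#'
#' Emits per-contig FASTA alignments, the population map TSV, the depth
#' table TSV (when present), heterozygous-call TSV, and the truth tables —
#' everything needed to score scan and classifier output without rerunning
#' the simulator.
#'
#' @param sim a simulation result list.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$gm, file.path(dir, "alignment"))
  write_popmap(sim$popmap, file.path(dir, "popmap.tsv"))
  wt <- function(x, name) {
    if (!is.null(x)) {
      utils::write.table(x, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wt(sim$depth, "depth.tsv")
  wt(sim$het_calls, "het_calls.tsv")
  for (nm in names(sim$truth)) {
    if (is.data.frame(sim$truth[[nm]])) {
      wt(sim$truth[[nm]], sprintf("truth_%s.tsv", nm))
    }
  }
  invisible(dir)
}
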