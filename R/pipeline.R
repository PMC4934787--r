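#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate -> scan -> classify -> stats -> cnv in dependency
#' order from a single structured config (a YAML file path or an
#' equivalent nested list), writing every stage's tables plus a run
#' manifest (JSON) recording the command, config snapshot, seeds, input
#' checksums, package version and per-stage outputs. Strain/population
#' references are validated before any compute; rerunning with the same
#' config and seeds reproduces deterministic outputs bit for bit.
#'
#' Config blocks (all optional except one of `simulate`/`input`):
#' \describe{
#'   \item{simulate}{`seed`, plus optional `admixed` (`pop_a`, `pop_b`,
#'     `f`, `tract_scale`, `min_tract_bp`, `seed`) and `lager`
#'     (`shared_regions`/`discordant_regions` as lists of
#'     `contig`/`start`/`end`, `ploidy_maps`, `het_rate`, `base_depth`,
#'     `seed`) sub-blocks.}
#'   \item{input}{`alignment_dir` (per-contig FASTAs) and `popmap` paths.}
#'   \item{scan}{`query`, `pop_neg`, `pop_pos`, `window_bp`, `B`, `alpha`,
#'     `seed`; `query` may be a vector.}
#'   \item{classify}{`panels`, `query`, `window_snps`, `smooth`,
#'     `min_confidence`.}
#'   \item{stats}{`populations` (labels for diversity/neutrality),
#'     `outgroup_pop`, `pairs` for Fst/polymorphism classes.}
#'   \item{cnv}{uses the simulated (or `depth` path) table.}
#' }
#'
#' @param config path to a YAML config or a nested list.
#' @param out_dir output directory.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("hybridscan")),
    config = config, seeds = list(), inputs = list(), stages = list()
  )
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_tsv_table(x, path)
    outputs <<- c(outputs, name)
    path
  }

  sim <- NULL
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    cfg <- sim_config(seed = sc$seed %||% 1L)
    manifest$seeds$simulate <- cfg$seed
    sim <- simulate_populations(cfg)
    if (!is.null(sc$admixed)) {
      ad <- sc$admixed
      sim <- simulate_admixed(sim, ad$pop_a, ad$pop_b, f = ad$f,
                              tract_scale = ad$tract_scale,
                              min_tract_bp = ad$min_tract_bp %||% 0,
                              seed = ad$seed %||% (cfg$seed + 1L))
      manifest$seeds$admixed <- ad$seed %||% (cfg$seed + 1L)
    }
    if (!is.null(sc$lager)) {
      lg <- sc$lager
      to_regions <- function(l) {
        purrr::map_dfr(l, function(r) {
          tibble(contig = r$contig, start = r$start, end = r$end)
        })
      }
      sim <- simulate_lager_like(
        sim,
        source_pop = lg$source_pop %||% "Holarctic",
        shared_regions = to_regions(lg$shared_regions),
        discordant_regions = to_regions(lg$discordant_regions),
        ploidy_maps = lg$ploidy_maps,
        het_rate = lg$het_rate %||% 2e-4,
        base_depth = lg$base_depth %||% 30,
        seed = lg$seed %||% (cfg$seed + 2L))
      manifest$seeds$lager <- lg$seed %||% (cfg$seed + 2L)
    }
    sim_dir <- file.path(out_dir, "simulated")
    write_simulation(sim, sim_dir)
    manifest$stages$simulate <- list(outputs = list.files(sim_dir,
                                                          recursive = TRUE))
    gm <- apply_gap_mask(sim$gm)
    popmap <- sim$popmap
  } else if (!is.null(config$input)) {
    fa <- sort(list.files(config$input$alignment_dir,
                          pattern = "\\.(fa|fasta|fna)$", full.names = TRUE))
    manifest$inputs <- as.list(tools::md5sum(c(fa, config$input$popmap)))
    gm <- apply_gap_mask(read_alignment(fa))
    popmap <- read_popmap(config$input$popmap)
  } else {
    abort("config needs a `simulate` or `input` block")
  }

  # validate references before any heavy compute
  all_refs <- c(config$scan$query, config$scan$pop_neg, config$scan$pop_pos,
                config$classify$query, config$classify$panels,
                config$stats$populations, unlist(config$stats$pairs))
  known <- c(strain_names(gm), unique(popmap$population),
             unique(stats::na.omit(popmap$subpopulation)))
  bad <- setdiff(all_refs, known)
  if (length(bad)) {
    abort(sprintf("unknown strain/population reference(s): %s",
                  paste(bad, collapse = ", ")))
  }

  scans <- list()
  if (!is.null(config$scan)) {
    sc <- config$scan
    for (q in sc$query) {
      scan <- scan_genome(gm, popmap, q, sc$pop_neg, sc$pop_pos,
                          window_bp = sc$window_bp %||% 50000,
                          B = sc$B %||% 999, alpha = sc$alpha %||% 0.019,
                          seed = sc$seed %||% 1L)
      scans[[q]] <- scan
      write_scan_tsv(scan, file.path(out_dir, sprintf("scan_%s.tsv", q)))
      outputs <- c(outputs, sprintf("scan_%s.tsv", q))
      emit(detect_breakpoints(scan), sprintf("breakpoints_%s.tsv", q))
      reg <- significant_regions(scan, side = "pos")
      write_regions_bed(reg, file.path(out_dir,
                                       sprintf("regions_pos_%s.bed", q)))
      outputs <- c(outputs, sprintf("regions_pos_%s.bed", q))
    }
    manifest$seeds$scan <- sc$seed %||% 1L
    if (length(scans) == 2) {
      emit(significant_regions(scans[[1]], scans[[2]], side = "pos"),
           "regions_shared.tsv")
      emit(discordant_regions(scans[[1]], scans[[2]]),
           "regions_discordant.tsv")
    }
  }

  if (!is.null(config$classify)) {
    cl <- config$classify
    snps <- select_snps(gm)
    model <- fit_panels(snps, popmap, panels = cl$panels,
                        window_snps = cl$window_snps %||% 20)
    for (q in cl$query) {
      tracks <- assign_query(model, snps, q,
                             min_confidence = cl$min_confidence %||% 0.8)
      tracks <- smooth_tracks(tracks, k = cl$smooth %||% 3)
      emit(tracks, sprintf("tracks_%s.tsv", q))
      emit(genome_fractions(tracks), sprintf("fractions_%s.tsv", q))
    }
  }

  if (!is.null(config$stats)) {
    st <- config$stats
    snps <- select_snps(gm)
    div <- purrr::map_dfr(st$populations, function(p) {
      neutrality_tests(snps, popmap, p, outgroup_pop = st$outgroup_pop)
    })
    emit(div, "diversity.tsv")
    if (!is.null(st$pairs)) {
      cls <- purrr::map_dfr(st$pairs, function(pr) {
        classify_polymorphisms(snps, popmap, pr[[1]], pr[[2]])
      })
      emit(cls, "polymorphism_classes.tsv")
    }
  }

  if (!is.null(config$cnv) || !is.null(sim$depth)) {
    depth <- if (!is.null(config$cnv$depth)) {
      read_depth_table(config$cnv$depth)
    } else sim$depth
    if (!is.null(depth)) {
      prof <- infer_copy_number(normalize_depth(depth))
      emit(prof$chromosomes, "copy_number.tsv")
      emit(prof$segments, "cnv_segments.tsv")
    }
  }

  manifest$stages$outputs <- outputs
  manifest$checksums <- as.list(
    tools::md5sum(file.path(out_dir, outputs)))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
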