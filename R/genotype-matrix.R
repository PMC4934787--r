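#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Allele codes: 0 = missing/gap, 1..4 = A, C, G, T.
ALLELE_CHARS <- c("A", "C", "G", "T")

encode_alleles <- function(chars) {
  x <- match(toupper(chars), ALLELE_CHARS)
  x[is.na(x)] <- 0L
  as.integer(x)
}

decode_alleles <- function(codes, missing_char = "-") {
  c(missing_char, ALLELE_CHARS)[codes + 1L]
}

#' Construct a genotype matrix
#'
#' The genotype matrix is the substrate of every statistic in the package:
#' an integer-coded strains-by-sites allele matrix together with per-site
#' contig assignment, 1-based positions, and a validity mask marking sites
#' usable in all strains. Alleles are coded 1..4 for A, C, G, T and 0 for
#' gap/missing; IUPAC ambiguity codes are mapped to missing on input.
#'
#' @param alleles integer matrix (strains x sites), codes 0..4, with strain
#'   names as rownames, or a character matrix of bases.
#' @param contig integer vector, per-site index into `contigs`.
#' @param pos integer vector of 1-based positions within each contig.
#' @param contigs tibble with columns `contig` (name) and `length` (bp).
#' @param valid logical per-site mask; defaults to all `TRUE`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, contig, pos, contigs, valid = NULL) {
  if (is.character(alleles)) {
    dn <- dimnames(alleles)
    alleles <- matrix(encode_alleles(alleles), nrow = nrow(alleles),
                      dimnames = dn)
  }
  storage.mode(alleles) <- "integer"
  if (is.null(rownames(alleles))) {
    abort("`alleles` must carry strain names as rownames")
  }
  n_sites <- ncol(alleles)
  contig <- as.integer(contig)
  pos <- as.integer(pos)
  stopifnot(length(contig) == n_sites, length(pos) == n_sites)
  contigs <- as_tibble(contigs)
  stopifnot(all(c("contig", "length") %in% names(contigs)))
  contigs$length <- as.integer(contigs$length)
  for (ci in unique(contig)) {
    p <- pos[contig == ci]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(sprintf("positions not strictly increasing on contig '%s'",
                    contigs$contig[ci]))
    }
  }
  if (is.null(valid)) valid <- rep(TRUE, n_sites)
  structure(
    list(alleles = alleles, contig = contig, pos = pos,
         contigs = contigs, valid = as.logical(valid)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d strains x %s sites (%d contigs, %s valid)\n",
              nrow(x$alleles), format(ncol(x$alleles), big.mark = ","),
              nrow(x$contigs), format(sum(x$valid), big.mark = ",")))
  cat("strains:", paste(utils::head(rownames(x$alleles), 8), collapse = ", "),
      if (nrow(x$alleles) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$alleles)

#' Strain names of a genotype or SNP matrix
#' @param x a `genotype_matrix` or `snp_matrix`.
#' @return Character vector of strain names.
#' @export
strain_names <- function(x) rownames(x$alleles)

strain_index <- function(gm, strains) {
  idx <- match(strains, rownames(gm$alleles))
  if (anyNA(idx)) {
    abort(sprintf("strain(s) not found: %s",
                  paste(strains[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Mask alignment columns containing gaps or missing data
#'
#' Sets the validity mask to `FALSE` at every column where at least one
#' strain carries a gap/missing code, mirroring the removal of gapped
#' positions before divergence is computed. Allele content is unchanged and
#' the operation is idempotent.
#'
#' @param gm a `genotype_matrix`.
#' @return The genotype matrix with an updated validity mask.
#' @export
apply_gap_mask <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  has_gap <- colSums(gm$alleles == 0L) > 0L
  gm$valid <- gm$valid & !has_gap
  gm
}

#' Add or replace a strain's sequence in a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param strain name of the strain to add.
#' @param alleles integer vector of allele codes, one per site.
#' @return The genotype matrix with the extra row.
#' @keywords internal
gm_add_strain <- function(gm, strain, alleles) {
  stopifnot(length(alleles) == ncol(gm$alleles))
  gm$alleles <- rbind(gm$alleles, matrix(as.integer(alleles), nrow = 1,
                                         dimnames = list(strain, NULL)))
  gm
}

#' Restrict a genotype matrix to a strain subset
#'
#' Sites and mask are kept as-is; reapply [apply_gap_mask()] if masking
#' should reflect only the retained strains.
#'
#' @param gm a `genotype_matrix`.
#' @param strains strain names to keep.
#' @return The subsetted `genotype_matrix`.
#' @export
subset_strains <- function(gm, strains) {
  idx <- strain_index(gm, strains)
  gm$alleles <- gm$alleles[idx, , drop = FALSE]
  gm
}

#' Read per-contig multi-strain FASTA alignments
#'
#' Each file holds one contig of the whole-genome alignment with one record
#' per strain; records within a file must have equal length. Strain sets
#' must agree across files.
#'
#' @param fasta_paths character vector of FASTA files, one per contig.
#' @param contig_names contig names; defaults to file base names.
#' @return A `genotype_matrix` with an all-`TRUE` validity mask (apply
#'   [apply_gap_mask()] before computing statistics).
#' @export
read_alignment <- function(fasta_paths, contig_names = NULL) {
  if (is.null(contig_names)) {
    contig_names <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(fasta_paths))
  }
  stopifnot(length(contig_names) == length(fasta_paths))
  per_contig <- purrr::map2(fasta_paths, contig_names, function(path, cname) {
    seqs <- Biostrings::readDNAStringSet(path)
    lens <- Biostrings::width(seqs)
    if (length(unique(lens)) != 1L) {
      abort(sprintf("unequal record lengths in contig '%s' (%s)",
                    cname, paste(unique(lens), collapse = ", ")))
    }
    mat <- as.matrix(seqs)           # strains x alignment columns
    matrix(encode_alleles(mat), nrow = length(seqs),
           dimnames = list(names(seqs), NULL))
  })
  strains <- rownames(per_contig[[1]])
  for (i in seq_along(per_contig)) {
    if (!setequal(rownames(per_contig[[i]]), strains)) {
      abort(sprintf("strain sets differ between contigs '%s' and '%s'",
                    contig_names[1], contig_names[i]))
    }
    per_contig[[i]] <- per_contig[[i]][strains, , drop = FALSE]
  }
  lens <- purrr::map_int(per_contig, ncol)
  genotype_matrix(
    alleles = do.call(cbind, per_contig),
    contig = rep(seq_along(contig_names), lens),
    pos = unlist(lapply(lens, seq_len), use.names = FALSE),
    contigs = tibble(contig = contig_names, length = lens)
  )
}

#' Write a genotype matrix as per-contig FASTA alignments
#'
#' Inverse of [read_alignment()]: one FASTA per contig, one record per
#' strain. Missing/gap codes are written as `-`.
#'
#' @param gm a `genotype_matrix`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_alignment <- function(gm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(gm$contigs))
  for (ci in seq_len(nrow(gm$contigs))) {
    cols <- which(gm$contig == ci)
    seqs <- apply(gm$alleles[, cols, drop = FALSE], 1, function(row) {
      paste(decode_alleles(row), collapse = "")
    })
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- rownames(gm$alleles)
    paths[ci] <- file.path(dir, paste0(gm$contigs$contig[ci], ".fa"))
    Biostrings::writeXStringSet(dss, paths[ci])
  }
  invisible(paths)
}

#' Read a multi-sample VCF against a reference into a genotype matrix
#'
#' Invariant columns are filled from the reference sequence; variant columns
#' from the genotype calls. Wild strains are treated as haploid/homozygous
#' consensus sequences: heterozygous calls collapse to the allele with the
#' larger allelic depth (first allele when depths are absent or tied) and
#' the collapses are reported via a message. Calls failing the genotype
#' quality or depth floor, and missing calls, get the missing code.
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param reference_fasta FASTA of the reference genome; contigs must cover
#'   every contig named in the VCF records.
#' @param min_gq,min_dp minimum genotype quality / depth when the FORMAT
#'   fields are present; calls below either floor are set to missing.
#' @return A `genotype_matrix` (one strain per VCF sample).
#' @export
read_vcf <- function(vcf_path, reference_fasta, min_gq = 20, min_dp = 8) {
  ref <- Biostrings::readDNAStringSet(reference_fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)

  contigs <- tibble(contig = names(ref), length = Biostrings::width(ref))
  ref_codes <- lapply(seq_along(ref), function(i) {
    encode_alleles(strsplit(as.character(ref[[i]]), "")[[1]])
  })

  n_rec <- nrow(vcf@fix)
  samples <- colnames(vcf@gt)[-1]
  if (n_rec > 0) {
    chrom <- vcf@fix[, "CHROM"]
    bad <- setdiff(unique(chrom), contigs$contig)
    if (length(bad)) {
      abort(sprintf("VCF contig(s) absent from reference: %s",
                    paste(bad, collapse = ", ")))
    }
  }

  alleles <- do.call(rbind, lapply(seq_along(samples), function(i) {
    unlist(ref_codes, use.names = FALSE)
  }))
  rownames(alleles) <- samples
  offsets <- c(0L, cumsum(contigs$length))

  if (n_rec > 0) {
    pos <- as.integer(vcf@fix[, "POS"])
    ci <- match(vcf@fix[, "CHROM"], contigs$contig)
    col_idx <- offsets[ci] + pos
    site_alleles <- lapply(seq_len(n_rec), function(r) {
      alt <- vcf@fix[r, "ALT"]
      c(vcf@fix[r, "REF"], if (!is.na(alt) && nzchar(alt)) {
        strsplit(alt, ",")[[1]]
      })
    })
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gq <- if (any(grepl("GQ", vcf@gt[, "FORMAT"]))) {
      suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
    }
    dp <- if (any(grepl("DP", vcf@gt[, "FORMAT"]))) {
      suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    }
    ad <- if (any(grepl("AD", vcf@gt[, "FORMAT"]))) {
      vcfR::extract.gt(vcf, element = "AD")
    }
    n_het_collapsed <- 0L
    for (s in seq_along(samples)) {
      for (r in seq_len(n_rec)) {
        call <- gt[r, s]
        code <- 0L
        if (!is.na(call) && !grepl("\\.", call)) {
          ok <- TRUE
          if (!is.null(gq) && !is.na(gq[r, s]) && gq[r, s] < min_gq) ok <- FALSE
          if (!is.null(dp) && !is.na(dp[r, s]) && dp[r, s] < min_dp) ok <- FALSE
          if (ok) {
            idx <- as.integer(strsplit(call, "[/|]")[[1]])
            if (length(unique(idx)) > 1L) {
              n_het_collapsed <- n_het_collapsed + 1L
              depths <- if (!is.null(ad) && !is.na(ad[r, s])) {
                as.numeric(strsplit(ad[r, s], ",")[[1]])
              }
              idx <- if (!is.null(depths) && length(depths) > max(idx)) {
                idx[which.max(depths[idx + 1L])]
              } else {
                idx[1L]
              }
            } else {
              idx <- idx[1L]
            }
            base <- site_alleles[[r]][idx + 1L]
            code <- if (!is.na(base) && nchar(base) == 1L) {
              encode_alleles(base)
            } else 0L  # indel or symbolic allele -> missing
          }
        }
        alleles[s, col_idx[r]] <- code
      }
    }
    if (n_het_collapsed > 0) {
      message(sprintf(
        "read_vcf: collapsed %d heterozygous call(s) to the major-depth allele",
        n_het_collapsed))
    }
  }

  genotype_matrix(
    alleles = alleles,
    contig = rep(seq_len(nrow(contigs)), contigs$length),
    pos = unlist(lapply(contigs$length, seq_len), use.names = FALSE),
    contigs = contigs
  )
}
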