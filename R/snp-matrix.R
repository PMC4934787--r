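#' Select biallelic segregating sites
#'
#' Restricts a gap-masked genotype matrix to valid, biallelic, segregating
#' columns — the SNP set on which the window classifier, PCA, Fst and the
#' site-pattern statistics operate. When an outgroup strain is designated,
#' sites where the outgroup carries a third allele are dropped and the
#' derived allele (the one the outgroup does not carry) is recorded, giving
#' the polarity needed by Fay & Wu's H and the ABBA-BABA statistics.
#'
#' @param gm a `genotype_matrix` with the gap mask applied.
#' @param outgroup optional strain name supplying ancestral state.
#' @return An object of class `snp_matrix`: allele codes (strains x SNPs),
#'   per-SNP contig/position, the two observed allele codes per site, the
#'   derived allele code (`NA` without an outgroup), and `n_total_sites`,
#'   the number of valid sites in the parent matrix (the denominator for
#'   per-site rates).
#' @export
select_snps <- function(gm, outgroup = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$alleles) < 2) abort("need at least 2 strains to call SNPs")
  a <- gm$alleles
  valid <- gm$valid & colSums(a == 0L) == 0L
  # biallelic segregating: exactly two of the four bases present
  present <- do.call(cbind, lapply(1:4, function(k) colSums(a == k) > 0L))
  n_alleles <- rowSums(present)
  idx <- which(valid & n_alleles == 2L)
  pr <- present[idx, , drop = FALSE] * 1L
  allele1 <- max.col(pr, ties.method = "first")
  pr[cbind(seq_along(idx), allele1)] <- 0L
  allele2 <- max.col(pr, ties.method = "first")
  lo <- pmin(allele1, allele2); hi <- pmax(allele1, allele2)
  allele1 <- lo; allele2 <- hi
  derived <- rep(NA_integer_, length(idx))
  if (!is.null(outgroup)) {
    og <- strain_index(gm, outgroup)
    og_allele <- unname(a[og, idx])
    keep <- og_allele == allele1 | og_allele == allele2
    idx <- idx[keep]
    allele1 <- allele1[keep]
    allele2 <- allele2[keep]
    og_allele <- og_allele[keep]
    derived <- unname(ifelse(og_allele == allele1, allele2, allele1))
  }
  structure(
    list(alleles = a[, idx, drop = FALSE],
         contig = gm$contig[idx], pos = gm$pos[idx],
         contigs = gm$contigs,
         allele1 = allele1, allele2 = allele2, derived = derived,
         outgroup = outgroup,
         n_total_sites = sum(gm$valid)),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d strains x %d biallelic SNPs (%s valid sites)%s\n",
              nrow(x$alleles), ncol(x$alleles),
              format(x$n_total_sites, big.mark = ","),
              if (!is.null(x$outgroup)) {
                sprintf(", polarized on '%s'", x$outgroup)
              } else ""))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$alleles)

#' @export
#' @rdname select_snps
#' @param x a `snp_matrix`.
#' @param ... unused.
as_tibble.snp_matrix <- function(x, ...) {
  tibble(contig = x$contigs$contig[x$contig], pos = x$pos,
         allele1 = ALLELE_CHARS[x$allele1], allele2 = ALLELE_CHARS[x$allele2],
         derived = ifelse(is.na(x$derived), NA_character_,
                          ALLELE_CHARS[x$derived]))
}

# 0/1 minor-ish encoding relative to allele1; rows = strains, cols = SNPs
snp_counts <- function(snps, strains = NULL) {
  a <- snps$alleles
  if (!is.null(strains)) a <- a[strains, , drop = FALSE]
  x <- sweep(a, 2, snps$allele2, `==`) * 1L
  x[a == 0L] <- NA_integer_
  x
}

# frequency of allele2 within a strain subset, per SNP
allele2_freq <- function(snps, strains) {
  x <- snp_counts(snps, strains)
  colMeans(x, na.rm = TRUE)
}

#' Read a population map
#'
#' A population map is a TSV with columns `strain`, `population` and
#' optionally `subpopulation`, assigning every analyzed strain to a
#' (sub)population.
#'
#' @param path TSV file path.
#' @return A tibble with columns `strain`, `population`, `subpopulation`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "population") %in% names(df)))
  if (is.null(df$subpopulation)) df$subpopulation <- NA_character_
  pm <- as_tibble(df[, c("strain", "population", "subpopulation")])
  validate_popmap(pm)
  pm
}

#' Write a population map
#' @param popmap tibble with `strain`, `population`, `subpopulation`.
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_popmap <- function(popmap) {
  stopifnot(all(c("strain", "population") %in% names(popmap)))
  if (any(!nzchar(popmap$strain)) || any(!nzchar(popmap$population)) ||
      anyNA(popmap$population)) {
    abort("population map labels must be non-empty")
  }
  if (anyDuplicated(popmap$strain)) abort("duplicated strain in population map")
  invisible(popmap)
}

# strains belonging to a population label; a subpopulation label is also
# accepted, so sublineages can serve as reference groups directly
pop_strains <- function(popmap, pop, subpop = NULL) {
  validate_popmap(popmap)
  hit <- popmap$population == pop
  if (!any(hit) && "subpopulation" %in% names(popmap)) {
    hit <- !is.na(popmap$subpopulation) & popmap$subpopulation == pop
  }
  if (!is.null(subpop)) hit <- hit & !is.na(popmap$subpopulation) &
      popmap$subpopulation == subpop
  s <- popmap$strain[hit]
  if (!length(s)) abort(sprintf("no strains in population '%s'", pop))
  s
}
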