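test_that("alignment reading, identity and polymorphic column counts", {
  dir <- withr::local_tempdir()
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTAC"),
             file.path(dir, "chrI.fa"))
  gm <- read_alignment(file.path(dir, "chrI.fa"))
  expect_equal(dim(gm), c(2L, 10L))
  expect_equal(gm$contigs$length, 10L)
  expect_true(all(gm$valid))
  expect_equal(sum(gm$alleles[1, ] != gm$alleles[2, ]), 0L)

  # 3-strain toy with exactly 2 mismatching columns
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTAC", ">s3",
               "ATGTACCTAC"), file.path(dir, "chrII.fa"))
  gm3 <- read_alignment(file.path(dir, "chrII.fa"))
  poly <- sum(apply(gm3$alleles, 2, function(col) length(unique(col)) > 1))
  expect_equal(poly, 2L)
})

test_that("unequal record lengths and inconsistent strains are format errors", {
  dir <- withr::local_tempdir()
  writeLines(c(">s1", "ACGTACGTAC", ">s2", "ACGTACGTA"),
             file.path(dir, "chrI.fa"))
  expect_error(read_alignment(file.path(dir, "chrI.fa")), "unequal record")

  writeLines(c(">s1", "ACGT", ">s2", "ACGT"), file.path(dir, "a.fa"))
  writeLines(c(">s1", "ACGT", ">s3", "ACGT"), file.path(dir, "b.fa"))
  expect_error(read_alignment(file.path(dir, c("a.fa", "b.fa"))),
               "strain sets differ")
})

test_that("alignment round-trips byte-for-byte for gap-free fixtures", {
  gm <- random_gm(4, 300, seed = 5, n_contigs = 2)
  dir <- withr::local_tempdir()
  paths <- write_alignment(gm, dir)
  gm2 <- read_alignment(paths, contig_names = gm$contigs$contig)
  expect_identical(gm2$alleles, gm$alleles)
  expect_identical(gm2$contigs, gm$contigs)
  # and the emitted FASTA is reproduced exactly on a second write
  dir2 <- withr::local_tempdir()
  write_alignment(gm2, dir2)
  for (ct in gm$contigs$contig) {
    expect_identical(readLines(file.path(dir2, paste0(ct, ".fa"))),
                     readLines(file.path(dir, paste0(ct, ".fa"))))
  }
})

test_that("gap masking invalidates exactly the gapped columns, idempotently", {
  gm <- gm_from_strings(c(s1 = "AC-TACGTAC",
                          s2 = "ACGTACNTAC",
                          s3 = "ACGTACGTAT"))
  gm1 <- apply_gap_mask(gm)
  expect_equal(which(!gm1$valid), c(3L, 7L))   # gap and ambiguity column
  expect_identical(apply_gap_mask(gm1)$valid, gm1$valid)
  expect_identical(gm1$alleles, gm$alleles)

  # no gaps -> mask untouched
  gm_clean <- gm_from_strings(c(s1 = "ACGT", s2 = "ACGT"))
  expect_true(all(apply_gap_mask(gm_clean)$valid))
})

test_that("SNP selection keeps valid biallelic segregating sites only", {
  # columns: 1 monomorphic, 2 biallelic, 3 triallelic, 4 biallelic,
  # 5 biallelic-with-gap, 6 biallelic
  gm <- gm_from_strings(c(s1 = "AAAAAA",
                          s2 = "ACCCC-",
                          s3 = "ACGC-C",
                          s4 = "ACACCC"))
  gm <- apply_gap_mask(gm)
  snps <- select_snps(gm)
  expect_equal(ncol(snps$alleles), 2L)         # columns 2 and 4
  expect_equal(snps$pos, c(2L, 4L))
  expect_equal(snps$n_total_sites, 4L)

  # monomorphic matrix -> 0 SNPs
  gm0 <- gm_from_strings(c(s1 = "ACGT", s2 = "ACGT"))
  expect_equal(ncol(select_snps(gm0)$alleles), 0L)
  expect_error(select_snps(gm_from_strings(c(s1 = "ACGT"))), "2 strains")
})

test_that("outgroup polarization flags the allele the outgroup lacks", {
  gm <- gm_from_strings(c(s1 = "AAAA", s2 = "ACAA", s3 = "ACGA",
                          og = "AATA"))
  snps <- select_snps(gm, outgroup = "og")
  # col 2: og carries A (major) -> derived = C; col 3: og carries a third
  # allele (T vs A/G) -> dropped
  expect_equal(snps$pos, 2L)
  expect_equal(snps$derived, match("C", c("A", "C", "G", "T")))

  # outgroup equal to the major allele everywhere -> derived = minor
  gm2 <- random_gm(6, 200, seed = 9)
  maj <- apply(gm2$alleles, 2, function(col) {
    as.integer(names(sort(table(col), decreasing = TRUE))[1])
  })
  gm2$alleles <- rbind(gm2$alleles, og = maj)
  snps2 <- select_snps(gm2, outgroup = "og")
  x <- snps2$alleles[setdiff(rownames(snps2$alleles), "og"), , drop = FALSE]
  for (j in seq_len(ncol(x))) {
    counts <- table(factor(x[, j], levels = 1:4))
    expect_lt(counts[snps2$derived[j]], sum(counts) / 2 + 1)
  }
})

test_that("SNP selection is invariant to strain order", {
  gm <- random_gm(6, 500, seed = 11)
  snps_a <- select_snps(gm)
  gm_r <- subset_strains(gm, rev(strain_names(gm)))
  snps_b <- select_snps(gm_r)
  expect_equal(snps_a$pos, snps_b$pos)
  expect_equal(snps_a$allele1, snps_b$allele1)
  expect_equal(snps_a$allele2, snps_b$allele2)
})

test_that("VCF reading fills reference, honors filters and collapses hets", {
  dir <- withr::local_tempdir()
  ref <- file.path(dir, "ref.fa")
  writeLines(c(">chr1", paste(rep("A", 100), collapse = "")), ref)

  # empty VCF -> all monomorphic reference columns
  vcf0 <- file.path(dir, "empty.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tx\ty"),
             vcf0)
  gm0 <- read_vcf(vcf0, ref)
  expect_equal(dim(gm0), c(2L, 100L))
  expect_true(all(gm0$alleles == 1L))

  vcf <- file.path(dir, "snps.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tx\ty\tz",
    "chr1\t5\t.\tA\tC\t50\tPASS\t.\tGT:GQ:DP\t1:99:30\t0:99:30\t0:99:30",
    "chr1\t10\t.\tA\tG\t50\tPASS\t.\tGT:GQ:DP\t.:.:.\t1:99:30\t0:99:30",
    "chr1\t20\t.\tA\tT\t50\tPASS\t.\tGT:GQ:DP\t1:5:30\t0:99:30\t0:99:30",
    "chr1\t30\t.\tA\tC\t50\tPASS\t.\tGT:GQ:DP\t1:99:3\t0:99:30\t0:99:30",
    "chr1\t40\t.\tA\tC,G\t50\tPASS\t.\tGT:GQ:DP\t2:99:30\t0:99:30\t1:99:30"),
    vcf)
  gm <- read_vcf(vcf, ref)
  # 1-based VCF position 5 is internal column 5
  expect_equal(unname(gm$alleles[, 5]), c(2L, 1L, 1L))
  expect_equal(unname(gm$alleles["x", 10]), 0L)   # missing call
  expect_equal(unname(gm$alleles["x", 20]), 0L)   # GQ below floor
  expect_equal(unname(gm$alleles["x", 30]), 0L)   # DP below floor
  expect_equal(unname(gm$alleles[, 40]), c(3L, 1L, 2L))  # multiallelic codes
  gm <- apply_gap_mask(gm)
  # 100 sites minus the three columns with a failing/missing call
  expect_equal(sum(gm$valid), 97L)

  # het call collapses to the major-depth allele with a message
  vcf_het <- file.path(dir, "het.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tx",
    "chr1\t7\t.\tA\tC\t50\tPASS\t.\tGT:AD\t0/1:3,27"), vcf_het)
  expect_message(gm_het <- read_vcf(vcf_het, ref), "collapsed 1 heterozygous")
  expect_equal(unname(gm_het$alleles["x", 7]), 2L)

  # contig absent from the reference is a consistency error
  vcf_bad <- file.path(dir, "bad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tx",
    "chr9\t5\t.\tA\tC\t50\tPASS\t.\tGT\t1"), vcf_bad)
  expect_error(read_vcf(vcf_bad, ref), "absent from reference")
})

test_that("population map round-trips and validates labels", {
  pm <- popmap_of(A = c("s1", "s2"), B = c("s3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  expect_equal(read_popmap(path)$population, pm$population)
  expect_error(read_popmap({
    p2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("strain\tpopulation\ns1\t\n", p2); p2
  }), "non-empty")
})
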