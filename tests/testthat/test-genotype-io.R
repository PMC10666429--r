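test_that("basic filtering keeps biallelic SNPs above the QUAL floor", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_lines(path, c(
    "1\t1000\t.\tA\tG\t40\tPASS\t.\tGT:DPU\t0/1:30",
    "1\t2000\t.\tC\tT\t20\tPASS\t.\tGT:DPU\t1/1:30",
    "1\t3000\t.\tA\tAT\t50\tPASS\t.\tGT:DPU\t0/1:30"))
  m <- load_vcf(path, site_filter_spec("basic"))
  expect_equal(n_sites(m), 1L)
  expect_equal(m$sites$pos, 1000L)
  expect_equal(unname(m$genotypes[1, 1]), 1L)
})

test_that("advanced filtering requires PASS and per-genotype depth", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_lines(path, c(
    "1\t1000\t.\tA\tG\t40\tMaxSB\t.\tGT:DPU\t0/1:30",
    "1\t2000\t.\tC\tT\t20\tPASS\t.\tGT:DPU\t1/1:30"))
  expect_message(m <- load_vcf(path, site_filter_spec("advanced")),
                 "no records survive")
  expect_equal(n_sites(m), 0L)

  # depth filter acts per genotype: low-DPU genotype becomes missing,
  # a site with no surviving genotype is dropped
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_lines(path2, c(
    "1\t1000\t.\tA\tG\t40\tPASS\t.\tGT:DPU\t0/1:30\t1/1:5",
    "1\t2000\t.\tC\tT\t40\tPASS\t.\tGT:DPU\t0/0:4\t./.:."),
    samples = c("S1", "S2"))
  m2 <- load_vcf(path2, site_filter_spec("advanced"))
  expect_equal(n_sites(m2), 1L)
  expect_equal(unname(m2$genotypes[, 1]), c(1L, NA))
})

test_that("non-autosomes are excluded and missing GT is fatal", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_lines(path, c(
    "X\t1000\t.\tA\tG\t40\tPASS\t.\tGT:DPU\t0/1:30",
    "chr2\t500\t.\tC\tT\t40\tPASS\t.\tGT:DPU\t0/1:30"))
  m <- load_vcf(path)
  expect_equal(m$sites$chrom, 2L)
  expect_error(load_vcf(withr::local_tempfile(fileext = ".vcf")), "read")
})

test_that("generated cohorts round-trip through VCF and honor the QUAL model", {
  spec <- cohort_spec(n_samples = 3, chrom_lengths_mb = c(`1` = 2, `2` = 2),
                      snp_density_per_kb = 0.5, qual_low_frac = 0.05,
                      error_rate = 0, missing_rate = 0,
                      segments_per_sample = 2, seed = 5)
  sim <- simulate_cohort(spec)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$matrix, path)
  back <- load_vcf(path, site_filter_spec("basic", qual_min = 0))
  expect_identical(unname(back$genotypes), unname(sim$matrix$genotypes))
  expect_equal(back$sites$pos, sim$matrix$sites$pos)
  expect_equal(back$sites$qual, sim$matrix$sites$qual)
  expect_identical(back$sample_ids, sim$matrix$sample_ids)
  expect_identical(unname(back$depth), unname(sim$matrix$depth))

  # fixture manifest: the QUAL>30 filter removes exactly the low-QUAL sites
  filt <- load_vcf(path, site_filter_spec("basic"))
  expect_equal(n_sites(filt), sim$truth$n_sites - sim$truth$n_qual_le_30)
})

test_that("merging uses union-of-sites with missing fill", {
  a <- gm(cbind(0L, 1L), pos = c(1000L, 2000L), sample_ids = "S1")
  b <- gm(cbind(2L, 1L), pos = c(2000L, 3000L), sample_ids = "S2")
  mg <- merge_cohort(list(a, b))
  expect_equal(n_sites(mg), 3L)
  expect_equal(unname(mg$genotypes[, 1]), c(0L, NA))
  expect_equal(unname(mg$genotypes[, 3]), c(NA, 1L))
  expect_equal(rowMeans(is.na(mg$genotypes)), c(S1 = 1 / 3, S2 = 1 / 3))

  # full sharing leaves no missingness
  mats <- lapply(1:8, function(s) gm(cbind(1L, 0L, 2L),
                                     sample_ids = paste0("I", s)))
  expect_equal(mean(is.na(merge_cohort(mats)$genotypes)), 0)

  # conflicting reference alleles at a shared position are fatal
  b2 <- genotype_matrix(cbind(1L), data.frame(chrom = 1L, pos = 2000L,
                                              ref = "C", alt = "T"),
                        sample_ids = "S3")
  expect_error(merge_cohort(list(a, b2)), "mismatch")
})

test_that("merge is associative up to sample order", {
  set.seed(3)
  mats <- lapply(1:3, function(s) {
    keep <- sort(sample(20L, 12L))
    gm(rbind(sample(0:2, 12, TRUE)), pos = keep * 1000L,
       sample_ids = paste0("P", s))
  })
  ab_c <- merge_cohort(list(merge_cohort(list(mats[[1]], mats[[2]])),
                            mats[[3]]))
  abc <- merge_cohort(mats)
  expect_identical(ab_c$sites, abc$sites)
  expect_identical(ab_c$genotypes, abc$genotypes)
})

test_that("QC filters in mind, geno, hwe order", {
  # 8 samples: a site called in 7/8 has missing rate 0.125 > 0.1 -> removed,
  # so every surviving site has call rate exactly 1
  set.seed(4)
  g <- matrix(sample(0:1, 8 * 40, TRUE), nrow = 8)
  g[1, 1:4] <- NA  # sample 1 at the 0.1 mind ceiling; 4 sites called in 7/8
  m <- gm(g)
  qcd <- apply_qc(m, qc_spec(hwe_p_min = 0))
  expect_equal(n_samples(qcd), 8L)
  expect_equal(n_sites(qcd), 36L)
  expect_true(all(colSums(is.na(qcd$genotypes)) == 0))

  # clean HWE-consistent matrix passes unchanged
  m2 <- gm(matrix(rep(c(0L, 1L, 1L, 2L), 10), nrow = 4))
  expect_identical(apply_qc(m2)$genotypes, m2$genotypes)

  # a sample above the mind ceiling is dropped before site filters
  g3 <- matrix(1L, nrow = 3, ncol = 20)
  g3[3, 1:3] <- NA  # 15% missing
  qcd3 <- apply_qc(gm(g3), qc_spec())
  expect_identical(qcd3$sample_ids, c("S1", "S2"))
  expect_equal(n_sites(qcd3), 20L)

  expect_error(apply_qc(gm(matrix(NA_integer_, 2, 5))), "all samples")
})

test_that("HWE stage removes only sites failing the exact test", {
  # 20 samples, one grossly het-excess site among balanced ones
  het_excess <- rep(1L, 20)
  balanced <- rep(c(0L, 1L, 1L, 2L), 5)
  m <- gm(cbind(het_excess, balanced, balanced))
  p_bad <- hwe_exact_p(0, 20, 0)
  qcd <- apply_qc(m, qc_spec(hwe_p_min = p_bad * 1.01))
  expect_equal(n_sites(qcd), 2L)
})
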