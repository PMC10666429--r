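test_that("identical seeds reproduce the cohort byte for byte", {
  spec <- cohort_spec(n_samples = 3, chrom_lengths_mb = c(`1` = 10),
                      snp_density_per_kb = 1, segments_per_sample = 5,
                      seed = 83)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(spec, vcf_dir = d1)
  s2 <- simulate_cohort(spec, vcf_dir = d2)
  expect_identical(s1$matrix$genotypes, s2$matrix$genotypes)
  expect_identical(s1$truth$tracts, s2$truth$tracts)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  spec2 <- cohort_spec(n_samples = 3, chrom_lengths_mb = c(`1` = 10),
                       snp_density_per_kb = 1, segments_per_sample = 5,
                       seed = 84)
  expect_false(identical(simulate_cohort(spec2)$matrix$genotypes,
                         s1$matrix$genotypes))
  expect_error(cohort_spec(n_samples = 2), "seed")
})

test_that("planted tracts are exponential with mean 100/(2g) cM and fully homozygous", {
  spec <- cohort_spec(n_samples = 6, chrom_lengths_mb = c(`1` = 100, `2` = 100),
                      snp_density_per_kb = 0.5, founder_g = 50,
                      segments_per_sample = 40, error_rate = 0,
                      missing_rate = 0, seed = 89)
  sim <- simulate_cohort(spec)
  tr <- sim$truth$tracts
  expect_gt(nrow(tr), 150)
  # mean within 2 SE of 1 cM (= 1 Mb at 1 cM/Mb)
  se <- sd(tr$length_mb) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$length_mb) - 1), 2.5 * se + 1e-3)
  # goodness of fit against Exp(1) by KS at the planted mean
  ks <- suppressWarnings(stats::ks.test(tr$length_mb, "pexp", 1))
  expect_gt(ks$p.value, 0.001)
  # no heterozygote inside any planted tract when error is off
  m <- sim$matrix
  for (r in sample(nrow(tr), 25)) {
    sel <- m$sites$chrom == tr$chrom[r] & m$sites$pos >= tr$start_bp[r] &
      m$sites$pos <= tr$end_bp[r]
    s <- match(tr$sample_id[r], m$sample_ids)
    expect_true(all(m$genotypes[s, sel] != 1L))
  }
  # tracts do not overlap within a sample
  by_sc <- split(tr, list(tr$sample_id, tr$chrom), drop = TRUE)
  for (b in by_sc) {
    if (nrow(b) < 2) next
    o <- order(b$start_bp)
    expect_true(all(b$start_bp[o][-1] > b$end_bp[o][-nrow(b)]))
  }
})

test_that("gene drop respects Mendelian transmission and pedigree kinship", {
  ped <- data.frame(id = c("F1", "F2", "C1"),
                    father = c(NA, NA, "F1"), mother = c(NA, NA, "F2"))
  spec <- cohort_spec(chrom_lengths_mb = c(`1` = 30), snp_density_per_kb = 1,
                      genotype_model = "freq", pedigree = ped,
                      founder_g = NULL, error_rate = 0, missing_rate = 0,
                      seed = 97)
  sim <- simulate_cohort(spec)
  pc <- pair_counts(sim$matrix, "F1", "C1")
  expect_equal(pc$n_opp_hom, 0L)  # parent and child share one allele everywhere
  expect_equal(sim$truth$kinship$expected[
    sim$truth$kinship$id1 == "F1" & sim$truth$kinship$id2 == "C1"], 0.25)
  # realized kinship of a parent-offspring pair is exactly 1/4
  expect_equal(sim$truth$kinship$realized[
    sim$truth$kinship$id1 == "F1" & sim$truth$kinship$id2 == "C1"], 0.25)

  # linked transmission: crossovers make sib realized kinship vary around 1/4
  ped2 <- data.frame(id = c("F1", "F2", "A", "B"),
                     father = c(NA, NA, "F1", "F1"),
                     mother = c(NA, NA, "F2", "F2"))
  spec2 <- cohort_spec(chrom_lengths_mb = c(`1` = 100), snp_density_per_kb = 0.5,
                       genotype_model = "freq", pedigree = ped2,
                       unlinked = FALSE, founder_g = NULL, error_rate = 0,
                       missing_rate = 0, seed = 101)
  sim2 <- simulate_cohort(spec2)
  kin2 <- sim2$truth$kinship
  ab <- kin2[kin2$id1 == "A" & kin2$id2 == "B", ]
  expect_equal(ab$expected, 0.25)
  expect_gt(ab$realized, 0.1)
  expect_lt(ab$realized, 0.4)
})

test_that("the private/shared generator books strata exactly", {
  ps <- make_private_shared_cohort(n_samples = 4, n_private = 50,
                                   n_shared = 200, seed = 103)
  expect_length(ps$matrices, 4L)
  # each sample's callset: its own privates plus all shared sites
  for (k in 1:4) expect_equal(n_sites(ps$matrices[[k]]), 50 + 200)
  merged <- merge_cohort(ps$matrices)
  expect_equal(n_sites(merged), 4 * 50 + 200)
  called <- colSums(!is.na(merged$genotypes))
  expect_equal(sum(called == 1), 4 * 50)
  expect_equal(sum(called == 4), 200)
  expect_equal(mean(is.na(merged$genotypes)),
               (4 * 50 * 3) / (4 * (4 * 50 + 200)))
  # no private stratum: merging leaves no missingness
  ps0 <- make_private_shared_cohort(n_samples = 3, n_private = 0,
                                    n_shared = 100, seed = 107)
  expect_equal(mean(is.na(merge_cohort(ps0$matrices)$genotypes)), 0)
})

test_that("error and missingness masks match the emitted matrix", {
  spec <- cohort_spec(n_samples = 4, chrom_lengths_mb = c(`1` = 20),
                      snp_density_per_kb = 1, founder_g = NULL,
                      error_rate = 0.01, missing_rate = 0.02, seed = 109)
  sim <- simulate_cohort(spec)
  expect_true(all(is.na(sim$matrix$genotypes[sim$truth$missing_mask])))
  n_gt <- length(sim$matrix$genotypes)
  expect_equal(nrow(sim$truth$missing_mask) / n_gt, 0.02, tolerance = 0.25)
  expect_equal(nrow(sim$truth$error_mask) / n_gt, 0.01, tolerance = 0.25)
})
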