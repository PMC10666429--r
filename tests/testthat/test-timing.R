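sweep_from <- function(tab) {
  # minimal sweep table: list of (sample_id, min_kb, nroh, sroh_kb)
  out <- do.call(rbind, lapply(tab, function(r) {
    data.frame(sample_id = r[[1]], min_kb = r[[2]], nroh = r[[3]],
               sroh_kb = r[[4]],
               avroh_kb = if (r[[3]] > 0) r[[4]] / r[[3]] else 0)
  }))
  class(out) <- c("roh_sweep", "data.frame")
  out
}

test_that("F_ROH divides total ROH length by the GRCh37 autosome length", {
  expect_equal(autosome_length_kb(), 2881033.286)
  sw <- sweep_from(list(list("S1", 100, 1655, 744300),
                        list("S1", 5000, 3.5, 21500)))
  expect_equal(round(f_roh(sw, 0.1)$f_roh, 3), 0.258)
  expect_equal(round(f_roh(sw, 5)$f_roh, 3), 0.007)
  z <- sweep_from(list(list("S1", 100, 0, 0)))
  expect_equal(f_roh(z, 0.1)$f_roh, 0)
  expect_equal(f_roh(z, 0.1)$r_roh, 0)
  expect_error(f_roh(sw, 0.3), "not on the sweep grid")
})

test_that("parental relatedness is exactly twice the inbreeding coefficient", {
  spec <- cohort_spec(n_samples = 4, chrom_lengths_mb = c(`1` = 40),
                      snp_density_per_kb = 1, segments_per_sample = 15,
                      seed = 73)
  sw <- sweep_roh(simulate_cohort(spec)$matrix, roh_params(),
                  seq(100, 5000, 100))
  for (x in c(0.1, 1, 2.5, 5)) {
    fr <- f_roh(sw, x)
    expect_identical(fr$r_roh, 2 * fr$f_roh)
    expect_true(all(fr$f_roh >= 0 & fr$f_roh <= 1))
  }
  # f_roh non-increasing in x
  f_grid <- sapply(seq(0.1, 5, 0.1), function(x) f_roh(sw, x)$f_roh)
  expect_true(all(apply(f_grid, 1, function(v) all(diff(v) <= 1e-12))))
})

test_that("kinship relatedness is matched to the closest R_ROH length", {
  expect_equal(match_r_to_roh(0.515, data.frame(x = c(0.1, 0.2),
                                                r_roh = c(0.517, 0.475))),
               0.1)
  expect_equal(match_r_to_roh(0.481, data.frame(x = c(0.1, 0.2),
                                                r_roh = c(0.519, 0.485))),
               0.2)
  expect_equal(match_r_to_roh(0.4, data.frame(x = c(0.3, 0.1),
                                              r_roh = c(0.4, 0.52))), 0.3)
  # ties break toward the smaller length
  expect_equal(match_r_to_roh(0.5, data.frame(x = c(0.1, 0.2),
                                              r_roh = c(0.45, 0.55))), 0.1)
})

test_that("diagonal deviations locate the start and maximum of the signal", {
  sw <- sweep_from(list(list("S1", 500, 3, 2000), list("S1", 600, 2, 4000),
                        list("S1", 1000, 1, 6000), list("S1", 1500, 1, 4000)))
  dp <- deviation_profile(sw, c(0.5, 1.5))
  expect_equal(dp$deviations$d, c(-1, 2, 5, 3))
  expect_equal(dp$l_min_mb, 0.6)
  expect_equal(dp$l_max_mb, 1.0)

  # on the diagonal everywhere: undefined with diagnostics
  flat <- sweep_from(list(list("S1", 500, 2, 2000), list("S1", 1000, 1, 1000)))
  expect_message(dp0 <- deviation_profile(flat, c(0.5, 1)), "diagonal")
  expect_true(is.na(dp0$l_min_mb))

  # l_min requires every sample below the diagonal
  two <- sweep_from(list(list("S1", 500, 1, 3000), list("S2", 500, 4, 3000),
                         list("S1", 600, 1, 2900), list("S2", 600, 2, 2900)))
  dp2 <- deviation_profile(two, c(0.5, 0.6))
  expect_equal(dp2$l_min_mb, 0.6)
})

test_that("length-to-time conversion follows the exponential segment model", {
  t1 <- date_length(1.0)
  expect_equal(t1$g_hat, 50)
  expect_equal(t1$t_years, 1345)
  expect_equal(t1$calendar_year, 615)

  t2 <- date_length(50)  # 50 cM: one generation
  expect_equal(t2$g_hat, 1)
  expect_equal(t2$t_years, 26.9)
  expect_equal(t2$calendar_year, 1933.1)

  t3 <- date_length(0.7)
  expect_equal(t3$g_hat, 100 / 1.4)
  expect_equal(t3$t_years, 26.9 * 100 / 1.4, tolerance = 1e-12)
  expect_equal(t3$calendar_year, 1960 - 26.9 * 100 / 1.4, tolerance = 1e-9)

  # sampling-year reference shifts estimates up by the year difference
  expect_equal(date_length(1.0, ref_year = 2012)$calendar_year - 615, 52)

  # inverse identity: dating the length implied by g recovers g
  for (g in c(1, 10, 25, 50, 100, 400)) {
    expect_equal(date_length(100 / (2 * g))$g_hat, g)
  }
  expect_error(date_length(0), "positive")

  # monotone: longer segments date more recent events
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), function(L)
    date_length(L)$t_years)) < 0))
})

test_that("the founder report assembles reproducible summaries", {
  spec <- cohort_spec(n_samples = 4, chrom_lengths_mb = c(`1` = 50, `2` = 50),
                      snp_density_per_kb = 1, genotype_model = "het",
                      founder_g = 50, segments_per_sample = 25, seed = 79)
  m <- simulate_cohort(spec)$matrix
  sw <- sweep_roh(m, roh_params(), seq(100, 5000, 100))
  kin <- kinship_matrix(m)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rep1 <- founder_report(m, sw, kin, out_dir = d1)
  rep2 <- founder_report(m, sw, kin, out_dir = d2)
  expect_identical(rep1$sample_summary, rep2$sample_summary)
  for (f in c("sample_summary.tsv", "roh_summary.tsv", "timing.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(all(c("nroh", "sroh_mb", "avroh_mb", "f_roh", "r_roh") %in%
                    rep1$roh_summary$parameter))
  expect_equal(sort(unique(rep1$roh_summary$x_mb)), c(0.1, 1.5, 5))
  # both reference years reported, 52 years apart
  y1 <- rep1$timing[["1960"]]$l_max$calendar_year
  y2 <- rep1$timing[["2012"]]$l_max$calendar_year
  expect_equal(y2 - y1, 52)
})
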