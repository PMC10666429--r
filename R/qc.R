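#' Quality-control specification
#'
#' Thresholds for cohort-level genotype QC, applied in the conventional
#' order: per-sample missingness (`mind`), then per-site missingness
#' (`geno`), then a Hardy-Weinberg exact-test floor (`hwe`).
#'
#' @param mind_max maximum per-sample missing rate (default 0.1).
#' @param geno_max maximum per-site missing rate (default 0.1).
#' @param hwe_p_min minimum two-sided exact HWE p-value (default 1e-7).
#' @return a list of class `qc_spec`.
#' @export
qc_spec <- function(mind_max = 0.1, geno_max = 0.1, hwe_p_min = 1e-7) {
  stopifnot(mind_max >= 0, mind_max <= 1, geno_max >= 0, geno_max <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(mind_max = mind_max, geno_max = geno_max,
                 hwe_p_min = hwe_p_min), class = "qc_spec")
}

#' Two-sided exact Hardy-Weinberg test
#'
#' Conditional on the observed allele counts, heterozygote counts under
#' random mating follow the exact distribution
#' \deqn{P(n_{Aa} = h) \propto \frac{n!}{n_{AA}!\,h!\,n_{aa}!} 2^h,}
#' over the het counts `h` compatible with the minor-allele count (same
#' parity, `0 <= h <= n_minor`). The two-sided p-value is the total
#' probability of all configurations no more probable than the observed one
#' (the SNPHWE / PLINK convention).
#'
#' @param n_hom1,n_het,n_hom2 genotype counts at one biallelic site.
#' @return p-value in (0, 1]. Monomorphic input returns 1.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0L) stop("no genotypes observed")
  a1 <- 2 * n_hom1 + n_het
  a2 <- 2 * n_hom2 + n_het
  n_minor <- min(a1, a2)
  if (n_minor == 0L) return(1)
  h <- seq.int(n_minor %% 2, n_minor, by = 2)
  hom_min <- (n_minor - h) / 2
  hom_maj <- n - h - hom_min
  lp <- lfactorial(n) - lfactorial(hom_min) - lfactorial(h) -
    lfactorial(hom_maj) + h * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, h)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Apply sample-missingness, site-missingness and HWE filters
#'
#' Filters a (typically merged) genotype matrix in the fixed order: samples
#' with missing rate above `mind_max` are removed first, then sites with
#' missing rate above `geno_max` (computed over the surviving samples),
#' then sites failing the exact HWE test at `hwe_p_min`. With eight samples
#' and `geno_max = 0.1`, the site filter leaves only sites called in every
#' sample (7/8 = 0.875 < 0.9), i.e. the complete-case SNP set.
#'
#' The HWE stage needs cohort genotype counts and is skipped (with a
#' message) for single-sample matrices, where the test is degenerate.
#'
#' @param m a [genotype_matrix].
#' @param qc a [qc_spec].
#' @param verbose emit per-stage removal counts as messages.
#' @return the filtered [genotype_matrix], with an attribute `"qc_log"`
#'   recording counts removed at each stage.
#' @export
apply_qc <- function(m, qc = qc_spec(), verbose = FALSE) {
  stopifnot(inherits(m, "genotype_matrix"), n_sites(m) > 0L)
  log <- list()

  miss_sample <- rowMeans(is.na(m$genotypes))
  keep_s <- miss_sample <= qc$mind_max
  log$samples_removed_mind <- sum(!keep_s)
  if (!any(keep_s)) {
    stop("all samples exceed the missing-rate ceiling (max rate ",
         sprintf("%.3f", max(miss_sample)), ")")
  }
  m <- subset_matrix(m, samples = which(keep_s))

  miss_site <- colMeans(is.na(m$genotypes))
  keep_g <- miss_site <= qc$geno_max
  log$sites_removed_geno <- sum(!keep_g)
  m <- subset_matrix(m, sites = keep_g)

  if (n_samples(m) >= 2L && n_sites(m) > 0L) {
    g <- m$genotypes
    n0 <- colSums(g == 0L, na.rm = TRUE)
    n1 <- colSums(g == 1L, na.rm = TRUE)
    n2 <- colSums(g == 2L, na.rm = TRUE)
    pv <- vapply(seq_len(n_sites(m)), function(k) {
      if (n0[k] + n1[k] + n2[k] == 0L) return(1)
      hwe_exact_p(n0[k], n1[k], n2[k])
    }, numeric(1))
    keep_h <- pv >= qc$hwe_p_min
    log$sites_removed_hwe <- sum(!keep_h)
    m <- subset_matrix(m, sites = keep_h)
  } else {
    log$sites_removed_hwe <- NA_integer_
    if (n_samples(m) < 2L) message("apply_qc: single sample; HWE stage skipped")
  }
  if (verbose) {
    message(sprintf(
      "apply_qc: removed %d samples (mind), %d sites (geno), %s sites (hwe)",
      log$samples_removed_mind, log$sites_removed_geno,
      ifelse(is.na(log$sites_removed_hwe), "no", log$sites_removed_hwe)))
  }
  attr(m, "qc_log") <- log
  m
}
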