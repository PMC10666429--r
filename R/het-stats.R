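#' Per-sample SNP counts, missing rate and heterozygosity
#'
#' For each sample: the number of sites with a non-missing genotype
#' (`n_snp`), the fraction of sites missing (`missing_rate`), and the SNP
#' heterozygosity `het` = heterozygous genotypes / non-missing genotypes.
#' Heterozygosity is defined over the variant sites present in the
#' (filtered) matrix, not over a monomorphic-genome denominator, matching
#' the convention of per-sample variant callsets.
#'
#' @param m a [genotype_matrix].
#' @return data.frame with columns `sample_id`, `n_snp`, `missing_rate`,
#'   `het` (NA with a warning for samples with no called genotypes).
#' @export
sample_stats <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"), n_sites(m) > 0L)
  g <- m$genotypes
  called <- rowSums(!is.na(g))
  n_het <- rowSums(g == 1L, na.rm = TRUE)
  het <- ifelse(called > 0L, n_het / called, NA_real_)
  if (any(called == 0L)) {
    warning("sample(s) with zero called genotypes: heterozygosity undefined")
  }
  data.frame(sample_id = m$sample_ids, n_snp = as.integer(called),
             missing_rate = 1 - called / n_sites(m), het = het,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call-rate-stratified heterozygosity of a merged cohort
#'
#' Bins the sites of a merged matrix by the number of samples with a call
#' (1..n) and reports, per bin, the site count and the heterozygous /
#' homozygous genotype counts among called genotypes. In cohorts built by
#' union-of-sites merging, private SNPs (call rate 1/n) are typically far
#' more heterozygous than SNPs called in every sample, so the het fraction
#' decreases with call rate; complete-case filtering therefore lowers the
#' cohort heterozygosity.
#'
#' @param m a merged [genotype_matrix] with at least two samples.
#' @return data.frame with one row per `n_called` in 1..n: `n_called`,
#'   `n_sites`, `n_het`, `n_hom`, `het_fraction` (NA for empty bins).
#' @export
het_by_call_rate <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"), n_samples(m) >= 2L,
            n_sites(m) > 0L)
  g <- m$genotypes
  n <- n_samples(m)
  n_called <- colSums(!is.na(g))
  het_site <- colSums(g == 1L, na.rm = TRUE)
  hom_site <- n_called - het_site
  out <- data.frame(n_called = seq_len(n), n_sites = 0L, n_het = 0L,
                    n_hom = 0L, het_fraction = NA_real_)
  for (k in seq_len(n)) {
    sel <- n_called == k
    out$n_sites[k] <- sum(sel)
    out$n_het[k] <- sum(het_site[sel])
    out$n_hom[k] <- sum(hom_site[sel])
    tot <- out$n_het[k] + out$n_hom[k]
    if (tot > 0L) out$het_fraction[k] <- out$n_het[k] / tot
  }
  out
}

#' Minor-allele-frequency spectrum
#'
#' Per-site minor allele frequency computed over called genotypes
#' (denominator 2 x called samples at the site, the PLINK convention on
#' missing data), aggregated into the achievable frequency grid. Sites with
#' zero called genotypes are excluded and counted in a message.
#'
#' @param m a [genotype_matrix].
#' @return data.frame with columns `maf`, `n_sites`, `fraction` (fractions
#'   sum to 1), sorted by `maf`; the per-site values are attached as
#'   attribute `"site_maf"`.
#' @export
maf_spectrum <- function(m) {
  stopifnot(inherits(m, "genotype_matrix"), n_sites(m) > 0L)
  g <- m$genotypes
  called <- colSums(!is.na(g))
  if (any(called == 0L)) {
    message("maf_spectrum: ", sum(called == 0L), " site(s) with no calls excluded")
  }
  ok <- called > 0L
  ac <- colSums(g, na.rm = TRUE)[ok]
  an <- 2 * called[ok]
  maf <- pmin(ac, an - ac) / an
  tab <- table(maf)
  out <- data.frame(maf = as.numeric(names(tab)),
                    n_sites = as.integer(tab), row.names = NULL)
  out <- out[order(out$maf), , drop = FALSE]
  out$fraction <- out$n_sites / sum(out$n_sites)
  rownames(out) <- NULL
  attr(out, "site_maf") <- maf
  out
}

#' Median / IQR / mean / SD summary
#'
#' The four-number summary convention used throughout the package's
#' reports: median (midpoint average for even n), IQR = Q3 - Q1 with
#' linear-interpolation (type-7) quantiles, mean, and SD with the n-1
#' denominator (reported as 0 for a single value).
#'
#' @param values numeric vector, length >= 1 (NAs removed).
#' @return data.frame with columns `med`, `iqr`, `mean`, `sd`, `n`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to summarize")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  data.frame(med = stats::median(values), iqr = q[2L] - q[1L],
             mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else 0,
             n = length(values))
}
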