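# Small builders used across the test files.

# genotype matrix from a samples x sites code matrix on one chromosome,
# sites 1 kb apart unless positions are given
gm <- function(codes, chrom = 1L, pos = NULL, qual = 60, sample_ids = NULL) {
  codes <- rbind(codes)
  ns <- ncol(codes)
  if (is.null(pos)) pos <- seq_len(ns) * 1000L
  genotype_matrix(codes,
                  data.frame(chrom = chrom, pos = pos,
                             ref = "A", alt = "G", qual = qual,
                             filter = "PASS"),
                  sample_ids = sample_ids %||%
                    paste0("S", seq_len(nrow(codes))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a VCF text file from explicit record fields
write_vcf_lines <- function(path, records, samples = "S1",
                            format = "GT:DPU") {
  header <- c("##fileformat=VCFv4.1",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DPU,Number=1,Type=Integer,Description=\"Depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

# independent HWE oracle: exhaustive enumeration of heterozygote counts
# compatible with the observed allele counts, configuration weights built
# from binomial coefficients (number of genotype configurations at fixed
# allele counts), two-sided p = total weight of configurations no more
# probable than the observed one.
hwe_enum_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  a_minor <- min(2 * n_hom1 + n_het, 2 * n_hom2 + n_het)
  if (a_minor == 0) return(1)
  hs <- seq(a_minor %% 2, a_minor, by = 2)
  w <- vapply(hs, function(h) {
    hom_min <- (a_minor - h) / 2
    hom_maj <- n - h - hom_min
    choose(n, hom_min) * choose(n - hom_min, h) * 2^h
  }, numeric(1))
  w_obs <- w[match(n_het, hs)]
  sum(w[w <= w_obs * (1 + 1e-12)]) / sum(w)
}

# pair_counts oracle: explicit per-site loop
pair_counts_loop <- function(gi, gj) {
  out <- list(n_het_i = 0L, n_het_j = 0L, n_both_het = 0L, n_opp_hom = 0L,
              m_shared = 0L)
  for (k in seq_along(gi)) {
    a <- gi[k]; b <- gj[k]
    if (is.na(a) || is.na(b)) next
    out$m_shared <- out$m_shared + 1L
    if (a == 1L) out$n_het_i <- out$n_het_i + 1L
    if (b == 1L) out$n_het_j <- out$n_het_j + 1L
    if (a == 1L && b == 1L) out$n_both_het <- out$n_both_het + 1L
    if ((a == 0L && b == 2L) || (a == 2L && b == 0L)) {
      out$n_opp_hom <- out$n_opp_hom + 1L
    }
  }
  out
}

# heterozygous-background genotype vector with homozygous tracts planted at
# the given [start, end] bp intervals; 1 SNP per kb
planted_chromosome <- function(length_mb, tracts_mb, het_p = 0.6,
                               seed = 1) {
  set.seed(seed)
  n <- length_mb * 1000L
  pos <- seq_len(n) * 1000L
  g <- ifelse(runif(n) < het_p, 1L, 2L * rbinom(n, 1L, 0.5))
  for (tr in tracts_mb) {
    sel <- pos >= tr[1] * 1e6 & pos <= tr[2] * 1e6
    g[sel] <- 2L * rbinom(sum(sel), 1L, 0.5)
  }
  list(g = g, pos = pos)
}
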