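#' Specification for a synthetic cohort
#'
#' Describes a synthetic whole-genome SNP cohort with known truth. The
#' defaults emulate, at desk scale, the statistical structure of a small
#' deeply-sequenced isolate cohort: eight samples, ~0.6 heterozygosity at
#' variant sites, autozygous tracts planted from a founder event
#' `founder_g` generations back with exponential lengths of mean
#' `100 / (2 * founder_g)` cM, light genotyping error and missingness, and
#' phred-like QUAL and per-genotype depth fields (mean depth 37, matching
#' high-coverage sequencing).
#'
#' Two genotype models are available:
#'
#' * `"het"`: per sample and site, the sample carries a variant with
#'   probability `p_variant`; a variant genotype is heterozygous with
#'   probability `het` (else hom-alt). Direct control of per-sample
#'   heterozygosity; sites are independent across samples.
#' * `"freq"`: founder haplotypes are drawn from a per-site alternate
#'   allele frequency `~ Uniform(freq_lo, freq_hi)` (with a `rare_frac`
#'   point mass of rare alleles below `rare_freq_max`) and, when a
#'   `pedigree` is given, transmitted by gene drop; genotypes then satisfy
#'   HWE within founders and carry pedigree-realized IBD.
#'
#' @param n_samples number of samples (ignored when `pedigree` is given).
#' @param chrom_lengths_mb named numeric vector of chromosome lengths in
#'   Mb, names in 1..22 (default three chromosomes of 80 Mb).
#' @param snp_density_per_kb expected SNP sites per kb (default 0.5).
#' @param genotype_model `"het"` or `"freq"`.
#' @param p_variant,het `"het"`-model parameters (defaults 0.7, 0.6).
#' @param freq_lo,freq_hi,rare_frac,rare_freq_max `"freq"`-model allele
#'   frequency parameters.
#' @param pedigree optional data.frame (`id`, `father`, `mother`,
#'   logical `sampled`), parents before offspring; founders have NA
#'   parents. Implies the `"freq"` model.
#' @param unlinked if `TRUE`, pedigree transmission treats every site as
#'   independently segregating; if `FALSE` (default), meioses follow a
#'   Haldane crossover model (Poisson crossovers, no interference) on a
#'   uniform map of `cm_per_mb`.
#' @param cm_per_mb genetic map density, default 1 cM/Mb.
#' @param founder_g generations back to the founder event driving planted
#'   autozygosity (default 50); `NULL` disables tract planting.
#' @param segments_per_sample expected number of planted tracts per sample
#'   (Poisson; default 60).
#' @param error_rate per-genotype miscall probability (default 0.001).
#' @param missing_rate per-genotype missingness probability (default 0.001).
#' @param qual_mean,qual_sd,qual_low_frac,qual_low_range site QUAL model:
#'   Gaussian baseline with a `qual_low_frac` fraction of sites assigned a
#'   low QUAL uniform in `qual_low_range` (default 5% in 10..30, i.e.
#'   failing a QUAL>30 filter).
#' @param depth_mean mean of the Poisson per-genotype depth (default 37).
#' @param seed integer random seed (mandatory).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 8,
                        chrom_lengths_mb = c(`1` = 80, `2` = 80, `3` = 80),
                        snp_density_per_kb = 0.5,
                        genotype_model = c("het", "freq"),
                        p_variant = 0.7, het = 0.6,
                        freq_lo = 0.05, freq_hi = 0.95,
                        rare_frac = 0.15, rare_freq_max = 0.05,
                        pedigree = NULL, unlinked = FALSE, cm_per_mb = 1,
                        founder_g = 50, segments_per_sample = 60,
                        error_rate = 0.001, missing_rate = 0.001,
                        qual_mean = 60, qual_sd = 8, qual_low_frac = 0.05,
                        qual_low_range = c(10, 30), depth_mean = 37,
                        seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  genotype_model <- match.arg(genotype_model)
  if (!is.null(pedigree)) genotype_model <- "freq"
  if (is.null(names(chrom_lengths_mb))) {
    names(chrom_lengths_mb) <- seq_along(chrom_lengths_mb)
  }
  stopifnot(all(as.integer(names(chrom_lengths_mb)) %in% 1:22),
            all(chrom_lengths_mb > 0), snp_density_per_kb > 0,
            p_variant >= 0, p_variant <= 1, het >= 0, het <= 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            qual_low_frac >= 0, qual_low_frac <= 1,
            is.null(founder_g) || founder_g > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate a synthetic cohort with known truth
#'
#' Generates a genotype matrix (and optionally VCF files) according to a
#' [cohort_spec], together with a truth record for use as a test oracle:
#' planted autozygous tract coordinates, pedigree-expected and
#' gene-drop-realized pairwise kinship, and the error / missingness masks.
#'
#' Tract planting draws per-sample tract counts from a Poisson with mean
#' `segments_per_sample` and lengths from an exponential with mean
#' `100 / (2 * founder_g)` cM; tracts are placed uniformly without overlap
#' (rejection sampling with a retry cap, after which an infeasible
#' specification is an error) and overwrite the genotype with a homozygote
#' drawn from the site's allele frequency.
#'
#' @param spec a [cohort_spec].
#' @param vcf_dir optional directory: per-sample VCFs (each restricted to
#'   the sample's variant sites, as a per-sample caller would emit) are
#'   written there as `<sample_id>.vcf`.
#' @return list with elements `matrix` (a [genotype_matrix] with QUAL and
#'   per-genotype depth fields) and `truth` (list: `tracts`, `kinship`,
#'   `founder_g`, `error_mask`, `missing_mask`, `n_sites`,
#'   `n_qual_le_30`, `seed`).
#' @export
simulate_cohort <- function(spec, vcf_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  chroms <- as.integer(names(spec$chrom_lengths_mb))
  len_bp <- round(spec$chrom_lengths_mb * 1e6)

  # site positions and alternate allele frequencies
  pos_list <- lapply(seq_along(chroms), function(k) {
    n <- max(1L, round(len_bp[k] / 1000 * spec$snp_density_per_kb))
    sort(sample.int(len_bp[k], n))
  })
  site_chrom <- rep(chroms, lengths(pos_list))
  site_pos <- unlist(pos_list)
  n_sites <- length(site_pos)
  p_alt <- stats::runif(n_sites, spec$freq_lo, spec$freq_hi)
  rare <- stats::runif(n_sites) < spec$rare_frac
  p_alt[rare] <- stats::runif(sum(rare), 1e-3, spec$rare_freq_max)

  # genotypes
  if (spec$genotype_model == "het" && is.null(spec$pedigree)) {
    sample_ids <- paste0("S", seq_len(spec$n_samples))
    n <- length(sample_ids)
    u <- matrix(stats::runif(n * n_sites), nrow = n)
    v <- matrix(stats::runif(n * n_sites), nrow = n)
    geno <- matrix(0L, nrow = n, ncol = n_sites)
    is_var <- u < spec$p_variant
    geno[is_var & v < spec$het] <- 1L
    geno[is_var & v >= spec$het] <- 2L
    kin_truth <- NULL
  } else if (is.null(spec$pedigree)) {
    # unrelated samples under HWE at the site allele frequencies
    sample_ids <- paste0("S", seq_len(spec$n_samples))
    n <- length(sample_ids)
    pmat <- matrix(p_alt, nrow = n, ncol = n_sites, byrow = TRUE)
    geno <- matrix(stats::rbinom(n * n_sites, 1L, pmat) +
                     stats::rbinom(n * n_sites, 1L, pmat),
                   nrow = n)
    kin_truth <- NULL
  } else {
    gd <- gene_drop(spec, site_chrom, site_pos, p_alt)
    geno <- gd$geno
    sample_ids <- gd$sample_ids
    kin_truth <- gd$kinship
  }
  rownames(geno) <- sample_ids
  n <- nrow(geno)

  # planted autozygous tracts
  tracts <- NULL
  if (!is.null(spec$founder_g) && spec$segments_per_sample > 0) {
    mean_mb <- 100 / (2 * spec$founder_g) / spec$cm_per_mb
    offsets <- c(0L, cumsum(lengths(pos_list)))
    tl <- list()
    for (s in seq_len(n)) {
      n_seg <- stats::rpois(1L, spec$segments_per_sample)
      placed <- place_tracts(n_seg, mean_mb, chroms, len_bp)
      if (nrow(placed)) {
        placed$sample_id <- sample_ids[s]
        for (r in seq_len(nrow(placed))) {
          ci <- match(placed$chrom[r], chroms)
          pc <- pos_list[[ci]]
          lo <- findInterval(placed$start_bp[r] - 1L, pc) + 1L
          hi <- findInterval(placed$end_bp[r], pc)
          if (hi >= lo) {
            idx <- offsets[ci] + lo:hi
            geno[s, idx] <- 2L * stats::rbinom(length(idx), 1L, p_alt[idx])
          }
        }
        tl[[length(tl) + 1L]] <- placed
      }
    }
    tracts <- if (length(tl)) do.call(rbind, tl) else NULL
    if (!is.null(tracts)) {
      tracts <- tracts[, c("sample_id", "chrom", "start_bp", "end_bp",
                           "length_mb")]
      rownames(tracts) <- NULL
    }
  }

  # genotyping error: flip to one of the other two codes
  error_mask <- NULL
  if (spec$error_rate > 0) {
    flip <- which(stats::runif(length(geno)) < spec$error_rate & !is.na(geno))
    if (length(flip)) {
      shift <- sample(1:2, length(flip), replace = TRUE)
      geno[flip] <- (geno[flip] + shift) %% 3L
      error_mask <- cbind(row = (flip - 1L) %% n + 1L,
                          col = (flip - 1L) %/% n + 1L)
    }
  }
  # missingness
  missing_mask <- NULL
  if (spec$missing_rate > 0) {
    drop <- which(stats::runif(length(geno)) < spec$missing_rate)
    if (length(drop)) {
      geno[drop] <- NA_integer_
      missing_mask <- cbind(row = (drop - 1L) %% n + 1L,
                            col = (drop - 1L) %/% n + 1L)
    }
  }

  # QUAL and per-genotype depth
  qual <- stats::rnorm(n_sites, spec$qual_mean, spec$qual_sd)
  low <- stats::runif(n_sites) < spec$qual_low_frac
  qual[low] <- stats::runif(sum(low), spec$qual_low_range[1L],
                            spec$qual_low_range[2L])
  qual <- round(qual, 2)
  depth <- matrix(stats::rpois(n * n_sites, spec$depth_mean), nrow = n)

  sites <- data.frame(chrom = site_chrom, pos = site_pos,
                      ref = "A", alt = "G", qual = qual, filter = "PASS",
                      stringsAsFactors = FALSE)
  m <- genotype_matrix(geno, sites, sample_ids = sample_ids, depth = depth)
  truth <- list(tracts = tracts, kinship = kin_truth,
                founder_g = spec$founder_g,
                error_mask = error_mask, missing_mask = missing_mask,
                n_sites = n_sites, n_qual_le_30 = sum(qual <= 30),
                seed = spec$seed)
  if (!is.null(vcf_dir)) {
    dir.create(vcf_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_len(n)) {
      write_vcf(subset_matrix(m, samples = s),
                file.path(vcf_dir, paste0(sample_ids[s], ".vcf")),
                drop_homref_sites = TRUE)
    }
  }
  list(matrix = m, truth = truth)
}

# uniform non-overlapping tract placement; lengths ~ Exp(mean_mb).
# Lengths are drawn up front and kept through placement (rejection is on
# position only, longest-first) so the emitted length distribution stays
# exponential; a length no chromosome can hold is redrawn, and persistent
# failure to place is an error (infeasible tract load).
place_tracts <- function(n_seg, mean_mb, chroms, len_bp, cap = 500L) {
  if (n_seg == 0L) {
    return(data.frame(chrom = integer(), start_bp = integer(),
                      end_bp = integer(), length_mb = numeric()))
  }
  lens_bp <- pmax(1L, round(stats::rexp(n_seg, rate = 1 / mean_mb) * 1e6))
  for (r in seq_len(cap)) {
    bad <- lens_bp >= max(len_bp)
    if (!any(bad)) break
    lens_bp[bad] <- pmax(1L, round(stats::rexp(sum(bad), 1 / mean_mb) * 1e6))
  }
  if (any(lens_bp >= max(len_bp))) {
    stop("tract length exceeds every chromosome: specification infeasible")
  }
  ord <- order(lens_bp, decreasing = TRUE)
  placed <- vector("list", n_seg)
  by_chrom <- rep(list(matrix(numeric(), ncol = 2L)), length(chroms))
  for (t in ord) {
    l_bp <- lens_bp[t]
    fits <- len_bp > l_bp
    ok <- FALSE
    for (try in seq_len(cap)) {
      ci <- which(fits)[sample.int(sum(fits), 1L, prob = len_bp[fits])]
      start <- sample.int(len_bp[ci] - l_bp, 1L)
      end <- start + l_bp - 1L
      iv <- by_chrom[[ci]]
      if (nrow(iv) && any(start <= iv[, 2L] & end >= iv[, 1L])) next
      by_chrom[[ci]] <- rbind(iv, c(start, end))
      placed[[t]] <- data.frame(chrom = chroms[ci], start_bp = start,
                                end_bp = end, length_mb = l_bp / 1e6)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place autozygous tract after ", cap,
           " attempts: specification infeasible (tract load too high)")
    }
  }
  do.call(rbind, placed)
}

# pedigree gene drop with founder-allele labels
gene_drop <- function(spec, site_chrom, site_pos, p_alt) {
  ped <- spec$pedigree
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  if (is.null(ped$sampled)) ped$sampled <- TRUE
  ids <- as.character(ped$id)
  n_ind <- length(ids)
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  n_sites <- length(site_pos)
  is_founder <- is.na(fa) & is.na(mo)
  n_f <- sum(is_founder)

  lab1 <- matrix(0L, n_ind, n_sites)
  lab2 <- matrix(0L, n_ind, n_sites)
  fidx <- cumsum(is_founder)
  chrom_set <- unique(site_chrom)
  len_mb <- spec$chrom_lengths_mb[as.character(chrom_set)]

  meiosis <- function(h1, h2) {
    if (spec$unlinked) {
      pick <- stats::runif(n_sites) < 0.5
    } else {
      pick <- logical(n_sites)
      for (k in seq_along(chrom_set)) {
        sel <- site_chrom == chrom_set[k]
        cm <- len_mb[k] * spec$cm_per_mb
        n_xo <- stats::rpois(1L, cm / 100)
        xo_bp <- sort(stats::runif(n_xo, 0, len_mb[k] * 1e6))
        phase <- stats::rbinom(1L, 1L, 0.5) +
          findInterval(site_pos[sel], xo_bp)
        pick[sel] <- phase %% 2L == 0L
      }
    }
    ifelse(pick, h1, h2)
  }

  for (i in seq_len(n_ind)) {
    if (is_founder[i]) {
      lab1[i, ] <- 2L * fidx[i] - 1L
      lab2[i, ] <- 2L * fidx[i]
    } else {
      if (is.na(fa[i]) || is.na(mo[i])) stop("non-founder needs both parents")
      lab1[i, ] <- meiosis(lab1[fa[i], ], lab2[fa[i], ])
      lab2[i, ] <- meiosis(lab1[mo[i], ], lab2[mo[i], ])
    }
  }

  # founder haplotype alleles per site
  fh <- matrix(stats::rbinom(2L * n_f * n_sites, 1L,
                             rep(p_alt, each = 2L * n_f)),
               nrow = 2L * n_f)
  site_idx <- rep(seq_len(n_sites), each = 1L)
  samp <- which(ped$sampled)
  geno <- matrix(0L, length(samp), n_sites)
  for (r in seq_along(samp)) {
    i <- samp[r]
    geno[r, ] <- fh[cbind(lab1[i, ], seq_len(n_sites))] +
      fh[cbind(lab2[i, ], seq_len(n_sites))]
  }

  # expected and realized kinship for sampled pairs
  exp_phi <- pedigree_kinship(ped)
  kin <- NULL
  if (length(samp) >= 2L) {
    prs <- utils::combn(samp, 2L)
    kin <- data.frame(
      id1 = ids[prs[1L, ]], id2 = ids[prs[2L, ]],
      expected = exp_phi[cbind(prs[1L, ], prs[2L, ])],
      realized = vapply(seq_len(ncol(prs)), function(k) {
        a <- prs[1L, k]; b <- prs[2L, k]
        mean((lab1[a, ] == lab1[b, ]) + (lab1[a, ] == lab2[b, ]) +
               (lab2[a, ] == lab1[b, ]) + (lab2[a, ] == lab2[b, ])) / 4
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  list(geno = geno, sample_ids = ids[samp], kinship = kin)
}

#' Simulate a cohort with private and shared variant strata
#'
#' Emulates the mechanism behind call-rate-dependent heterozygosity in
#' merged cohorts: *private* sites are variant in exactly one sample (and
#' absent from the other samples' callsets, hence missing after merging)
#' and heterozygous with elevated probability, while *shared* sites are
#' variant in every sample with a lower heterozygote probability. Merging
#' the returned single-sample matrices with [merge_cohort()] yields a
#' heterozygosity profile that decreases with call rate.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_private number of private sites per sample.
#' @param n_shared number of sites variant in all samples.
#' @param het_private,het_shared heterozygote probabilities for the two
#'   strata (defaults 0.8 and 0.3).
#' @param chrom_lengths_mb chromosome lengths in Mb (named by label).
#' @param seed integer random seed (mandatory).
#' @return list with `matrices` (per-sample [genotype_matrix] list, each
#'   restricted to the sample's own sites) and `truth` (site table with
#'   stratum and owner, and stratum counts).
#' @export
make_private_shared_cohort <- function(n_samples = 8, n_private = 500,
                                       n_shared = 1500, het_private = 0.8,
                                       het_shared = 0.3,
                                       chrom_lengths_mb = c(`1` = 50, `2` = 50),
                                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_samples >= 2L, n_private >= 0L, n_shared >= 1L)
  set.seed(seed)
  chroms <- as.integer(names(chrom_lengths_mb))
  len_bp <- round(chrom_lengths_mb * 1e6)
  n_tot <- n_samples * n_private + n_shared
  chrom <- chroms[sample.int(length(chroms), n_tot, replace = TRUE,
                             prob = len_bp)]
  pos <- integer(n_tot)
  for (k in seq_along(chroms)) {
    sel <- chrom == chroms[k]
    pos[sel] <- sample.int(len_bp[k], sum(sel))
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  stratum <- sample(c(rep(seq_len(n_samples), each = n_private),
                      rep(0L, n_shared)))  # 0 = shared, else owner index
  sample_ids <- paste0("S", seq_len(n_samples))
  sites_all <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                          qual = 60, filter = "PASS",
                          stringsAsFactors = FALSE)
  mats <- lapply(seq_len(n_samples), function(s) {
    sel <- stratum == 0L | stratum == s
    p_het <- ifelse(stratum[sel] == 0L, het_shared, het_private)
    g <- ifelse(stats::runif(sum(sel)) < p_het, 1L, 2L)
    genotype_matrix(matrix(g, nrow = 1L), sites_all[sel, , drop = FALSE],
                    sample_ids = sample_ids[s])
  })
  truth <- list(
    sites = data.frame(chrom = chrom, pos = pos,
                       stratum = ifelse(stratum == 0L, "shared", "private"),
                       owner = ifelse(stratum == 0L, NA_character_,
                                      sample_ids[pmax(stratum, 1L)]),
                       stringsAsFactors = FALSE),
    n_private_total = n_samples * n_private, n_shared = n_shared,
    het_private = het_private, het_shared = het_shared, seed = seed)
  list(matrices = mats, truth = truth)
}
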