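#' Construct a genotype matrix
#'
#' The central container of the package: an ordered set of autosomal
#' biallelic SNP sites together with a samples x sites matrix of diploid
#' genotype codes. Codes are `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `NA` (missing / not called).
#'
#' Sites are identified by the tuple (chrom, pos, ref, alt) and kept sorted
#' by (chrom, pos, ref, alt); site identity must be unique.
#'
#' @param genotypes integer matrix, samples in rows, sites in columns,
#'   values in `c(0L, 1L, 2L, NA)`.
#' @param sites data.frame with columns `chrom` (integer 1-22), `pos`
#'   (1-based bp), `ref`, `alt` (single characters from A/C/G/T), and
#'   optionally `qual` (numeric) and `filter` (character, e.g. `"PASS"`).
#' @param sample_ids character vector of sample names; defaults to the
#'   rownames of `genotypes`.
#' @param depth optional integer matrix of per-genotype read depths with the
#'   same dimensions as `genotypes` (the caller's per-genotype depth-used
#'   field); carried for VCF output, not used by the estimators.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `sample_ids`, `sites`, `genotypes` and (possibly `NULL`) `depth`.
#' @export
genotype_matrix <- function(genotypes, sites, sample_ids = rownames(genotypes),
                            depth = NULL) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  }
  sample_ids <- as.character(sample_ids)
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.integer(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  if (is.null(sites$qual)) sites$qual <- NA_real_
  if (is.null(sites$filter)) sites$filter <- "PASS"
  sites$qual <- as.numeric(sites$qual)
  sites$filter <- as.character(sites$filter)

  if (nrow(sites) != ncol(genotypes)) {
    stop("number of sites (", nrow(sites), ") does not match genotype columns (",
         ncol(genotypes), ")")
  }
  if (length(sample_ids) != nrow(genotypes)) {
    stop("sample_ids length does not match genotype rows")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  if (nrow(sites)) {
    if (any(is.na(sites$chrom)) || any(sites$chrom < 1L) || any(sites$chrom > 22L)) {
      stop("chrom must be an autosome label in 1..22")
    }
    if (any(sites$pos < 1L)) stop("pos must be >= 1")
    nt <- c("A", "C", "G", "T")
    if (!all(sites$ref %in% nt) || !all(sites$alt %in% nt)) {
      stop("ref and alt must be single nucleotides A/C/G/T")
    }
    if (any(sites$ref == sites$alt)) stop("ref and alt must differ")
    ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
    if (is.unsorted(ord) || any(ord != seq_along(ord))) {
      sites <- sites[ord, , drop = FALSE]
      genotypes <- genotypes[, ord, drop = FALSE]
      if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
    }
    key <- site_keys(sites)
    if (anyDuplicated(key)) stop("duplicate site identities (chrom,pos,ref,alt)")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!all(dim(depth) == dim(genotypes))) {
      stop("depth matrix dimensions must match genotypes")
    }
  }
  rownames(genotypes) <- sample_ids
  rownames(sites) <- NULL
  structure(list(sample_ids = sample_ids, sites = sites,
                 genotypes = genotypes, depth = depth),
            class = "genotype_matrix")
}

site_keys <- function(sites) {
  paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Number of samples in a genotype matrix
#' @param m a [genotype_matrix] object.
#' @return integer count.
#' @export
n_samples <- function(m) length(m$sample_ids)

#' Number of sites in a genotype matrix
#' @param m a [genotype_matrix] object.
#' @return integer count.
#' @export
n_sites <- function(m) nrow(m$sites)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", n_samples(x), "samples x", n_sites(x), "sites\n")
  if (n_sites(x)) {
    cat("  chromosomes:", paste(sort(unique(x$sites$chrom)), collapse = ", "), "\n")
    mr <- mean(is.na(x$genotypes))
    cat(sprintf("  overall missing rate: %.4f\n", mr))
  }
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param m a [genotype_matrix].
#' @param samples sample ids or indices to keep (default all).
#' @param sites logical or integer index over sites to keep (default all).
#' @return a [genotype_matrix].
#' @export
subset_matrix <- function(m, samples = NULL, sites = NULL) {
  gi <- if (is.null(samples)) seq_len(n_samples(m)) else {
    if (is.character(samples)) match(samples, m$sample_ids) else samples
  }
  if (anyNA(gi)) stop("unknown sample id")
  si <- if (is.null(sites)) seq_len(n_sites(m)) else sites
  genotype_matrix(m$genotypes[gi, si, drop = FALSE],
                  m$sites[si, , drop = FALSE],
                  sample_ids = m$sample_ids[gi],
                  depth = if (!is.null(m$depth)) m$depth[gi, si, drop = FALSE])
}

#' Restrict a merged matrix to complete-case sites
#'
#' Keeps only sites with a non-missing genotype in every sample; after
#' union-of-sites merging this is the set of SNPs shared by all samples.
#'
#' @param m a [genotype_matrix].
#' @return a [genotype_matrix] with missing rate 0.
#' @export
complete_case_sites <- function(m) {
  keep <- colSums(is.na(m$genotypes)) == 0L
  subset_matrix(m, sites = keep)
}

#' Merge single- or multi-sample genotype matrices into one cohort
#'
#' Implements union-of-sites merge semantics: the merged site set is the
#' union of the input site sets keyed by (chrom, pos, ref, alt), and a
#' sample's genotype is `NA` at any site absent from that sample's input.
#' This mirrors merging per-sample VCFs, where SNPs not called in every
#' sample become missing genotypes, and is the mechanism that drives the
#' call-rate dependence of heterozygosity in merged cohorts.
#'
#' @param matrices list of [genotype_matrix] objects (at least two, or one
#'   multi-sample matrix plus others). Sample ids must be globally unique.
#' @return a merged [genotype_matrix]; sample order is the concatenation
#'   order of the inputs.
#' @export
merge_cohort <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 2L)
  all_sites <- do.call(rbind, lapply(matrices, function(m) {
    m$sites[, c("chrom", "pos", "ref", "alt", "qual", "filter")]
  }))
  # reference consistency at shared physical positions
  cp <- paste(all_sites$chrom, all_sites$pos, sep = ":")
  ref_by_cp <- tapply(all_sites$ref, cp, function(r) length(unique(r)))
  if (any(ref_by_cp > 1L)) {
    bad <- names(ref_by_cp)[ref_by_cp > 1L][1L]
    stop("reference allele mismatch at position ", bad)
  }
  key <- paste(all_sites$chrom, all_sites$pos, all_sites$ref, all_sites$alt,
               sep = ":")
  first <- !duplicated(key)
  union_sites <- all_sites[first, , drop = FALSE]
  ord <- order(union_sites$chrom, union_sites$pos, union_sites$ref,
               union_sites$alt)
  union_sites <- union_sites[ord, , drop = FALSE]
  union_key <- site_keys(union_sites)

  sample_ids <- unlist(lapply(matrices, `[[`, "sample_ids"))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids across inputs")
  geno <- matrix(NA_integer_, nrow = length(sample_ids),
                 ncol = length(union_key))
  have_depth <- all(vapply(matrices, function(m) !is.null(m$depth), logical(1)))
  depth <- if (have_depth) matrix(NA_integer_, nrow = length(sample_ids),
                                  ncol = length(union_key))
  row0 <- 0L
  for (m in matrices) {
    cols <- match(site_keys(m$sites), union_key)
    rows <- row0 + seq_len(n_samples(m))
    geno[rows, cols] <- m$genotypes
    if (have_depth) depth[rows, cols] <- m$depth
    row0 <- row0 + n_samples(m)
  }
  genotype_matrix(geno, union_sites, sample_ids = sample_ids, depth = depth)
}
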