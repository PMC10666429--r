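#' Site filter specification
#'
#' Two filtering criteria for incoming VCF records, mirroring the common
#' practice for CASAVA-style single-sample callsets:
#'
#' * `"basic"`: biallelic SNPs with `QUAL > qual_min`.
#' * `"advanced"`: additionally requires `FILTER == "PASS"` and a
#'   per-genotype depth-used (`FMT/DPU`) strictly above `depth_min`;
#'   genotypes failing the depth requirement are set to missing and sites
#'   left with no called genotype are dropped.
#'
#' @param mode `"basic"` or `"advanced"`.
#' @param qual_min phred-scaled site quality floor (strict `>`), default 30.
#' @param depth_min per-genotype depth floor (strict `>`), default 10; used
#'   in advanced mode only.
#' @return a list of class `site_filter_spec`.
#' @export
site_filter_spec <- function(mode = c("basic", "advanced"), qual_min = 30,
                             depth_min = 10) {
  mode <- match.arg(mode)
  stopifnot(qual_min >= 0, depth_min >= 0)
  structure(list(mode = mode, qual_min = qual_min,
                 require_pass = mode == "advanced",
                 depth_min = depth_min),
            class = "site_filter_spec")
}

#' Load a VCF into a genotype matrix
#'
#' Reads a (possibly gzip-compressed) VCF 4.1+ file and applies a
#' [site_filter_spec]. Only autosomal (chrom 1-22, `chr` prefix tolerated)
#' biallelic single-nucleotide records are retained; multiallelic records
#' and indels are dropped, not split.
#'
#' @param path VCF file path.
#' @param spec a [site_filter_spec]; default basic filtering.
#' @param verbose emit per-stage record counts as messages.
#' @return a [genotype_matrix] with per-genotype depth attached when the
#'   VCF carries a `DPU` FORMAT field.
#' @export
load_vcf <- function(path, spec = site_filter_spec("basic"), verbose = FALSE) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) stop("VCF contains no records: ", path)
  fmt <- vcf@gt[, 1L]
  if (!any(grepl("(^|:)GT(:|$)", fmt))) stop("VCF has no GT FORMAT field: ", path)

  chrom <- sub("^chr", "", fix$CHROM)
  is_auto <- chrom %in% as.character(1:22)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  ok_qual <- !is.na(qual) & qual > spec$qual_min
  keep <- is_auto & is_snp & ok_qual
  if (spec$require_pass) keep <- keep & !is.na(fix$FILTER) & fix$FILTER == "PASS"
  if (verbose) {
    message(sprintf(
      "load_vcf: %d records; %d autosomal biallelic SNPs; %d pass QUAL>%g%s",
      n_in, sum(is_auto & is_snp), sum(keep), spec$qual_min,
      if (spec$require_pass) " and FILTER=PASS" else ""))
  }
  sample_ids <- colnames(vcf@gt)[-1L]
  if (!any(keep)) {
    message("load_vcf: no records survive site filtering")
    return(empty_genotype_matrix(sample_ids))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt_raw <- gt_raw[keep, , drop = FALSE]
  geno <- gt_code(gt_raw)

  depth <- NULL
  fmt_ids <- unique(unlist(strsplit(fmt, ":", fixed = TRUE)))
  if ("DPU" %in% fmt_ids) {
    depth <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DPU", as.numeric = TRUE))
    depth <- depth[keep, , drop = FALSE]
  }
  if (spec$mode == "advanced") {
    if (is.null(depth)) {
      message("load_vcf: advanced mode but no DPU field; all genotypes fail depth filter")
      geno[] <- NA_integer_
    } else {
      fail <- is.na(depth) | depth <= spec$depth_min
      n_fail <- sum(fail & !is.na(geno))
      if (n_fail && verbose) {
        message("load_vcf: ", n_fail, " genotypes failed DPU>", spec$depth_min)
      }
      geno[fail] <- NA_integer_
    }
    called <- rowSums(!is.na(geno)) > 0L
    geno <- geno[called, , drop = FALSE]
    keep[keep] <- called
    if (!is.null(depth)) depth <- depth[called, , drop = FALSE]
    if (!nrow(geno)) {
      message("load_vcf: no sites with called genotypes after depth filtering")
      return(empty_genotype_matrix(sample_ids))
    }
  }

  sites <- data.frame(chrom = as.integer(chrom[keep]),
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      qual = qual[keep], filter = fix$FILTER[keep],
                      stringsAsFactors = FALSE)
  genotype_matrix(t(geno), sites, sample_ids = sample_ids,
                  depth = if (!is.null(depth)) t(depth))
}

empty_genotype_matrix <- function(sample_ids) {
  genotype_matrix(matrix(NA_integer_, length(sample_ids), 0L),
                  data.frame(chrom = integer(), pos = integer(),
                             ref = character(), alt = character(),
                             qual = numeric(), filter = character(),
                             stringsAsFactors = FALSE),
                  sample_ids = sample_ids)
}

# "0/0"-style GT strings (sites x samples) -> integer codes
gt_code <- function(gt) {
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out[gt %in% c("0/0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1")] <- 2L
  out
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal, standards-conforming VCF 4.1 text file with `GT` (and
#' `DPU` when the matrix carries per-genotype depths), preserving site
#' QUAL and FILTER columns so that `load_vcf(write_vcf(m))` round-trips
#' the matrix.
#'
#' @param m a [genotype_matrix].
#' @param path output file path (plain text; use a `.vcf` suffix).
#' @param drop_homref_sites if `TRUE`, drop sites at which no sample carries
#'   an alternate allele (the convention of per-sample variant callers,
#'   whose VCFs list only the sample's variant sites).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, drop_homref_sites = FALSE) {
  if (drop_homref_sites) {
    variant <- colSums(m$genotypes > 0L, na.rm = TRUE) > 0L
    m <- subset_matrix(m, sites = variant)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.1",
    "##source=rohkin",
    paste0("##contig=<ID=", sort(unique(m$sites$chrom)), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(m$depth))
      "##FORMAT=<ID=DPU,Number=1,Type=Integer,Description=\"Depth used\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$sample_ids), collapse = "\t")
  ), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[m$genotypes + 1L],
                   nrow = n_samples(m))
  gt_str[is.na(gt_str)] <- "./."
  fmt <- "GT"
  if (!is.null(m$depth)) {
    dp <- m$depth
    dp_str <- ifelse(is.na(dp), ".", as.character(dp))
    gt_str <- matrix(paste(gt_str, dp_str, sep = ":"), nrow = n_samples(m))
    fmt <- "GT:DPU"
  }
  qual_str <- ifelse(is.na(m$sites$qual), ".",
                     formatC(m$sites$qual, format = "g", digits = 10))
  body <- paste(m$sites$chrom, m$sites$pos, ".", m$sites$ref, m$sites$alt,
                qual_str, m$sites$filter, ".", fmt,
                apply(gt_str, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
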