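#' ROH detection parameters
#'
#' Parameters of the sliding-window run-of-homozygosity dialect (the
#' PLINK `--homozyg` family of settings). Two named presets are provided:
#'
#' * `"plink-default"`: 50-SNP windows allowing 1 heterozygote and 5
#'   missing calls, 5% window-hit floor, runs of at least 100 SNPs, maximum
#'   gap 1000 kb, density at most 50 kb/SNP.
#' * `"ref20"`: the alternative profile used in comparative inbreeding
#'   studies of European isolates — minimum 25 SNPs per run and a 100 kb
#'   maximum gap, other settings as default.
#'
#' @param profile preset name, `"plink-default"` or `"ref20"`.
#' @param min_kb minimum emitted run length in kb (the swept threshold).
#' @param window_snps window size in SNPs.
#' @param window_het_max maximum heterozygous calls per homozygous window.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param hit_fraction_min minimum fraction of overlapping windows that are
#'   homozygous for a SNP to be supported.
#' @param min_snps minimum number of SNPs in an emitted run.
#' @param max_gap_kb maximum bp gap (in kb) between consecutive run SNPs.
#' @param density_kb_per_snp_max maximum kb per SNP within a run.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(profile = c("plink-default", "ref20"), min_kb = 100,
                       window_snps = 50, window_het_max = 1,
                       window_missing_max = 5, hit_fraction_min = 0.05,
                       min_snps = NULL, max_gap_kb = NULL,
                       density_kb_per_snp_max = 50) {
  profile <- match.arg(profile)
  if (is.null(min_snps)) min_snps <- if (profile == "ref20") 25 else 100
  if (is.null(max_gap_kb)) max_gap_kb <- if (profile == "ref20") 100 else 1000
  p <- list(profile = profile, min_kb = min_kb, window_snps = window_snps,
            window_het_max = window_het_max,
            window_missing_max = window_missing_max,
            hit_fraction_min = hit_fraction_min, min_snps = min_snps,
            max_gap_kb = max_gap_kb,
            density_kb_per_snp_max = density_kb_per_snp_max)
  stopifnot(all(vapply(p[-1L], function(x) is.numeric(x) && x >= 0, logical(1))))
  structure(p, class = "roh_params")
}

#' Call runs of homozygosity for one sample
#'
#' Sliding-window ROH detection: (1) a window of `window_snps` consecutive
#' SNPs is *homozygous* if it contains at most `window_het_max`
#' heterozygous and `window_missing_max` missing calls; (2) a SNP is
#' *supported* if at least `hit_fraction_min` of the windows overlapping it
#' are homozygous; (3) candidate runs are maximal stretches of consecutive
#' supported SNPs, broken where the bp gap between adjacent SNPs exceeds
#' `max_gap_kb`; (4) run boundaries are the outermost supported SNPs with a
#' homozygous genotype, and a run is emitted if it has at least `min_snps`
#' SNPs, spans at least `min_kb` kb, and its density does not exceed
#' `density_kb_per_snp_max` kb/SNP. Missing genotypes inside runs count
#' toward the window missing allowance but do not break runs.
#'
#' Only windows fully inside a chromosome are counted, so support near
#' chromosome ends is based on fewer windows; chromosomes with fewer SNPs
#' than one window yield no calls.
#'
#' @param m a [genotype_matrix].
#' @param sample sample id or index.
#' @param p a [roh_params].
#' @return data.frame of segments: `sample_id`, `chrom`, `start_pos`,
#'   `end_pos` (1-based inclusive bp), `n_snps`, `length_kb`.
#' @export
call_roh <- function(m, sample, p = roh_params()) {
  if (is.character(sample)) sample <- match(sample, m$sample_ids)
  stopifnot(!is.na(sample))
  g_all <- m$genotypes[sample, ]
  out <- list()
  for (chr in unique(m$sites$chrom)) {
    sel <- m$sites$chrom == chr
    segs <- roh_one_chrom(g_all[sel], m$sites$pos[sel], p)
    if (!is.null(segs) && nrow(segs)) {
      segs$chrom <- chr
      out[[length(out) + 1L]] <- segs
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_pos = integer(), end_pos = integer(),
                      n_snps = integer(), length_kb = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$sample_id <- m$sample_ids[sample]
  res[, c("sample_id", "chrom", "start_pos", "end_pos", "n_snps", "length_kb")]
}

roh_one_chrom <- function(g, pos, p) {
  L <- length(g)
  W <- p$window_snps
  if (L < W) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ch <- cumsum(het)
  cm <- cumsum(mis)
  nw <- L - W + 1L
  i <- seq_len(nw)
  w_het <- ch[i + W - 1L] - c(0L, ch)[i]
  w_mis <- cm[i + W - 1L] - c(0L, cm)[i]
  hw <- (w_het <= p$window_het_max) & (w_mis <= p$window_missing_max)
  chw <- c(0L, cumsum(hw))
  k <- seq_len(L)
  lo <- pmax(1L, k - W + 1L)
  hi <- pmin(k, nw)
  n_win <- hi - lo + 1L
  n_hom <- chw[hi + 1L] - chw[lo]
  supported <- (n_hom / n_win) >= p$hit_fraction_min
  sup <- which(supported)
  if (!length(sup)) return(NULL)
  brk <- which(diff(sup) > 1L | diff(pos[sup]) > p$max_gap_kb * 1000)
  run_id <- cumsum(c(1L, seq_along(sup)[-1L] %in% (brk + 1L)))
  hom <- !het & !mis
  segs <- lapply(split(sup, run_id), function(idx) {
    hh <- idx[hom[idx]]
    if (!length(hh)) return(NULL)
    a <- hh[1L]; b <- hh[length(hh)]
    n_snps <- b - a + 1L
    length_kb <- (pos[b] - pos[a] + 1) / 1000
    if (n_snps < p$min_snps || length_kb < p$min_kb ||
        length_kb / n_snps > p$density_kb_per_snp_max) return(NULL)
    data.frame(start_pos = pos[a], end_pos = pos[b], n_snps = n_snps,
               length_kb = length_kb)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Sweep ROH summary statistics over minimum segment lengths
#'
#' For every sample and every minimum-length threshold on the grid, reports
#' NROH (number of runs), SROH (total run length, kb) and AVROH (average
#' run length, kb; 0 when there are no runs). Because the window-support
#' step does not depend on the minimum length, runs are called once at the
#' smallest grid value and post-filtered by length for the larger
#' thresholds — equivalent to independent re-calls at every grid point.
#'
#' @param m a [genotype_matrix].
#' @param p a [roh_params]; its `min_kb` is overridden by the grid.
#' @param grid_kb ascending minimum lengths in kb (default 100..5000 by
#'   100, the 0.1-5 Mb range).
#' @return data.frame of class `roh_sweep`: `sample_id`, `min_kb`, `nroh`,
#'   `sroh_kb`, `avroh_kb`; the called segments (at the smallest grid
#'   value) are attached as attribute `"segments"`.
#' @export
sweep_roh <- function(m, p = roh_params(), grid_kb = seq(100, 5000, by = 100)) {
  stopifnot(!is.unsorted(grid_kb, strictly = TRUE))
  p$min_kb <- grid_kb[1L]
  segs <- do.call(rbind, lapply(seq_len(n_samples(m)),
                                function(s) call_roh(m, s, p)))
  rows <- list()
  for (sid in m$sample_ids) {
    len <- if (!is.null(segs) && nrow(segs)) {
      segs$length_kb[segs$sample_id == sid]
    } else numeric(0)
    for (x in grid_kb) {
      keep <- len[len >= x]
      nroh <- length(keep)
      sroh <- sum(keep)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, min_kb = x, nroh = nroh, sroh_kb = sroh,
        avroh_kb = if (nroh > 0L) sroh / nroh else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "segments") <- segs
  class(out) <- c("roh_sweep", "data.frame")
  out
}
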