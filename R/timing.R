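#' GRCh37 autosome lengths
#'
#' Reference lengths in bp of chromosomes 1-22 of the GRCh37 human
#' assembly. Their sum, 2,881,033,286 bp (2,881,033.286 kb), is the
#' autosome-length denominator used by [f_roh()].
#'
#' @format named numeric vector, names `"1"`..`"22"`, values in bp.
#' @export
grch37_autosome_lengths <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566)

#' Total autosome length in kb
#'
#' @return sum of [grch37_autosome_lengths] divided by 1000
#'   (2,881,033.286 kb).
#' @export
autosome_length_kb <- function() sum(grch37_autosome_lengths) / 1000

#' ROH-based inbreeding and parental relatedness
#'
#' The genomic inbreeding coefficient at minimum ROH length `x`,
#' \deqn{F_{ROH>x} = \sum L_{ROH>x} / L_{aut},}
#' i.e. the summed length of a sample's ROH segments at least `x` Mb long
#' divided by the autosome length, and the implied parental relatedness
#' \deqn{R_{ROH>x} = 2 F_{ROH>x}}
#' (the inbreeding coefficient of an individual equals the kinship of its
#' parents when the common ancestors are not inbred).
#'
#' @param sweep a [sweep_roh()] result.
#' @param x_mb minimum ROH length in Mb; must lie on the sweep grid.
#' @param l_aut_kb autosome length denominator in kb; defaults to the
#'   GRCh37 value 2,881,033.286.
#' @return data.frame with one row per sample: `sample_id`, `x_mb`,
#'   `f_roh`, `r_roh` (= 2 * f_roh exactly), `l_aut_kb`.
#' @export
f_roh <- function(sweep, x_mb, l_aut_kb = autosome_length_kb()) {
  x_kb <- x_mb * 1000
  sel <- abs(sweep$min_kb - x_kb) < 1e-6
  if (!any(sel)) {
    stop("x = ", x_mb, " Mb is not on the sweep grid")
  }
  sub <- sweep[sel, , drop = FALSE]
  f <- sub$sroh_kb / l_aut_kb
  data.frame(sample_id = sub$sample_id, x_mb = x_mb, f_roh = f,
             r_roh = 2 * f, l_aut_kb = l_aut_kb,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Match kinship-derived relatedness to ROH-derived parental relatedness
#'
#' Finds the minimum ROH length `x*` at which the cohort's ROH-derived
#' parental relatedness best matches its kinship-derived relatedness,
#' i.e. the approximate solution of `R = 2 F_ROH>x` over the grid. A small
#' `x*` indicates the observed relatedness is of evolutionary (ancient)
#' origin; a large `x*` would point to recent familial relatedness.
#'
#' @param r_median cohort median relatedness R from kinship.
#' @param roh_medians data.frame with columns `x` (Mb) and `r_roh`
#'   (median R_ROH at that x).
#' @return the `x` minimizing `|r_median - r_roh|` (ties broken toward
#'   smaller `x`).
#' @export
match_r_to_roh <- function(r_median, roh_medians) {
  stopifnot(nrow(roh_medians) > 0L, all(c("x", "r_roh") %in% names(roh_medians)))
  tab <- roh_medians[order(roh_medians$x), , drop = FALSE]
  tab$x[which.min(abs(r_median - tab$r_roh))]
}

#' NROH-versus-SROH diagonal-deviation profile
#'
#' In a plot of the number of ROH (NROH) against their total length
#' (SROH, Mb), samples from a bottlenecked / consanguineous population
#' drift below the diagonal `NROH = SROH` as the minimum ROH length
#' increases. The signed vertical deviation `d = SROH_Mb - NROH` (positive
#' below/right of the diagonal) is computed per sample per grid length;
#' the profile reports:
#'
#' * `l_min_mb`: the smallest grid length in the window at which *every*
#'   sample has `d > 0` (start of the bottleneck signal);
#' * `l_max_mb`: the grid length maximizing the median of `d` across
#'   samples (maximum of the signal); per-sample argmax lengths are also
#'   returned.
#'
#' Both are `NA` (with a diagnostic message) when the sign condition never
#' holds in the window.
#'
#' @param sweep a [sweep_roh()] result.
#' @param window_mb numeric length-2 vector, the minimum-length window (Mb)
#'   over which to evaluate the profile (default `c(0.4, 5)`).
#' @return list with elements `deviations` (data.frame `sample_id`, `x_mb`,
#'   `d`), `median_d` (data.frame `x_mb`, `d_median`, `d_min`), `l_min_mb`,
#'   `l_max_mb`, `per_sample_lmax` (data.frame).
#' @export
deviation_profile <- function(sweep, window_mb = c(0.4, 5)) {
  x_mb <- sweep$min_kb / 1000
  sel <- x_mb >= window_mb[1L] & x_mb <= window_mb[2L]
  if (!any(sel)) stop("sweep grid does not cover the requested window")
  dev <- data.frame(sample_id = sweep$sample_id[sel], x_mb = x_mb[sel],
                    d = sweep$sroh_kb[sel] / 1000 - sweep$nroh[sel],
                    stringsAsFactors = FALSE)
  xs <- sort(unique(dev$x_mb))
  med <- vapply(xs, function(x) stats::median(dev$d[dev$x_mb == x]), numeric(1))
  mins <- vapply(xs, function(x) min(dev$d[dev$x_mb == x]), numeric(1))
  all_below <- mins > 0
  l_min <- if (any(all_below)) xs[which(all_below)[1L]] else NA_real_
  l_max <- if (any(med > 0)) xs[which.max(med)] else NA_real_
  if (is.na(l_min)) {
    message("deviation_profile: no grid length at which all samples lie below the diagonal")
  }
  if (is.na(l_max)) {
    message("deviation_profile: median deviation never positive; l_max undefined")
  }
  per_sample <- do.call(rbind, lapply(split(dev, dev$sample_id), function(df) {
    data.frame(sample_id = df$sample_id[1L],
               l_max_mb = if (any(df$d > 0)) df$x_mb[which.max(df$d)] else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  list(deviations = dev,
       median_d = data.frame(x_mb = xs, d_median = med, d_min = mins),
       l_min_mb = l_min, l_max_mb = l_max, per_sample_lmax = per_sample)
}

#' Convert a ROH length to a dated founder-event estimate
#'
#' Under the exponential model for the lengths of autozygous segments, a
#' segment length `L` (in cM) corresponds to
#' \deqn{\hat g = \frac{100\,\mathrm{cM}}{2L}}
#' generations since the last common ancestor. With a human generation
#' time of 26.9 years, the event lies `t = 26.9 * g` years before the
#' cohort's reference year (default 1960, a birth-year convention;
#' using a sampling year such as 2012 shifts the calendar estimates up by
#' the corresponding amount).
#'
#' @param length_mb segment length in Mb, > 0.
#' @param cm_per_mb genetic map density (cM per Mb), default 1.
#' @param gen_time generation time in years, default 26.9.
#' @param ref_year reference calendar year counted back from, default 1960.
#' @return list of class `timing_estimate`: `length_mb`, `length_cm`,
#'   `g_hat`, `t_years`, `calendar_year`, `ref_year`.
#' @export
date_length <- function(length_mb, cm_per_mb = 1, gen_time = 26.9,
                        ref_year = 1960) {
  if (any(length_mb <= 0)) stop("length must be positive")
  length_cm <- length_mb * cm_per_mb
  g <- 100 / (2 * length_cm)
  t_years <- gen_time * g
  structure(list(length_mb = length_mb, length_cm = length_cm, g_hat = g,
                 t_years = t_years, calendar_year = ref_year - t_years,
                 ref_year = ref_year),
            class = "timing_estimate")
}

#' @export
print.timing_estimate <- function(x, ...) {
  for (k in seq_along(x$length_mb)) {
    cat(sprintf(
      "L = %.3g Mb (%.3g cM): g = %.4g generations, t = %.5g years, year %.4g (ref %d)\n",
      x$length_mb[k], x$length_cm[k], x$g_hat[k], x$t_years[k],
      x$calendar_year[k], x$ref_year))
  }
  invisible(x)
}

#' Assemble the cohort founder report
#'
#' Combines the pipeline outputs into the cohort-level summary: four-number
#' summaries (median/IQR/mean/SD) of per-sample N_SNP, heterozygosity and
#' pairwise relatedness; of NROH, SROH, AVROH, F_ROH and R_ROH at a subset
#' of minimum lengths; the diagonal-deviation profile with its dated
#' start (`l_min`) and maximum (`l_max`) under two reference years; and
#' the grid length at which kinship-R best matches R_ROH.
#'
#' @param m the analysis [genotype_matrix] (merged, post-QC).
#' @param sweep a [sweep_roh()] result for `m`.
#' @param kinship a [kinship_matrix()] table for `m`.
#' @param x_subset minimum lengths (Mb) at which to tabulate ROH
#'   statistics (default `c(0.1, 1.5, 5)`).
#' @param window_mb deviation-profile window (Mb), default `c(0.7, 1.5)`.
#' @param gen_time,cm_per_mb timing constants, see [date_length()].
#' @param ref_years reference years for the calendar conversion
#'   (default `c(1960, 2012)`).
#' @param out_dir optional directory; when given, the report tables are
#'   written as TSV and the timing block as JSON.
#' @return list of class `founder_report` with elements `sample_summary`,
#'   `roh_summary`, `match_x_mb`, `deviation`, `timing`.
#' @export
founder_report <- function(m, sweep, kinship, x_subset = c(0.1, 1.5, 5),
                           window_mb = c(0.7, 1.5), gen_time = 26.9,
                           cm_per_mb = 1, ref_years = c(1960, 2012),
                           out_dir = NULL) {
  ss <- sample_stats(m)
  sum_row <- function(parameter, values) {
    cbind(data.frame(parameter = parameter, stringsAsFactors = FALSE),
          summary_stats(values))
  }
  sample_summary <- rbind(
    sum_row("n_snp", ss$n_snp),
    sum_row("het", ss$het),
    sum_row("relatedness", kinship$relatedness))

  roh_rows <- list()
  roh_medians <- data.frame(x = numeric(), r_roh = numeric())
  for (x in x_subset) {
    sub <- sweep[sweep$min_kb == x * 1000, , drop = FALSE]
    fr <- f_roh(sweep, x)
    roh_rows[[length(roh_rows) + 1L]] <- cbind(
      data.frame(x_mb = x),
      rbind(sum_row("nroh", sub$nroh),
            sum_row("sroh_mb", sub$sroh_kb / 1000),
            sum_row("avroh_mb", sub$avroh_kb / 1000),
            sum_row("f_roh", fr$f_roh),
            sum_row("r_roh", fr$r_roh)))
    roh_medians <- rbind(roh_medians,
                         data.frame(x = x, r_roh = stats::median(fr$r_roh)))
  }
  roh_summary <- do.call(rbind, roh_rows)
  match_x <- match_r_to_roh(stats::median(kinship$relatedness, na.rm = TRUE),
                            roh_medians)

  dev <- deviation_profile(sweep, window_mb)
  timing <- list()
  for (ry in ref_years) {
    timing[[as.character(ry)]] <- list(
      l_min = if (!is.na(dev$l_min_mb))
        unclass(date_length(dev$l_min_mb, cm_per_mb, gen_time, ry)) else NULL,
      l_max = if (!is.na(dev$l_max_mb))
        unclass(date_length(dev$l_max_mb, cm_per_mb, gen_time, ry)) else NULL)
  }

  rep <- structure(list(sample_summary = sample_summary,
                        roh_summary = roh_summary,
                        match_x_mb = match_x, deviation = dev,
                        timing = timing),
                   class = "founder_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(sample_summary,
                       file.path(out_dir, "sample_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roh_summary, file.path(out_dir, "roh_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(dev$deviations, file.path(out_dir, "deviation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(match_x_mb = match_x, l_min_mb = dev$l_min_mb,
           l_max_mb = dev$l_max_mb, timing = timing),
      file.path(out_dir, "timing.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  rep
}

#' @export
print.founder_report <- function(x, ...) {
  cat("founder_report\n-- per-sample / per-pair summaries --\n")
  print(x$sample_summary, digits = 4)
  cat("-- ROH summaries --\n")
  print(x$roh_summary, digits = 4)
  cat(sprintf("kinship R best matches R_ROH at x = %.3g Mb\n", x$match_x_mb))
  cat(sprintf("deviation profile: l_min = %s Mb, l_max = %s Mb\n",
              format(x$deviation$l_min_mb), format(x$deviation$l_max_mb)))
  for (ry in names(x$timing)) {
    tm <- x$timing[[ry]]
    if (!is.null(tm$l_max)) {
      cat(sprintf("  ref %s: event maximum at year %.1f (g = %.1f)\n",
                  ry, tm$l_max$calendar_year, tm$l_max$g_hat))
    }
  }
  invisible(x)
}
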