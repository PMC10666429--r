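#' Build and validate a pipeline run configuration
#'
#' A run configuration names the inputs (either VCF paths or a simulation
#' spec), the filtering/QC thresholds, the kinship and ROH settings, the
#' timing constants, the output directory and the seed. It can be built
#' programmatically or loaded from a YAML file with the same field names.
#'
#' @param vcf_paths character vector of input VCFs (mutually exclusive
#'   with `simulate`).
#' @param simulate a [cohort_spec] for a simulated input cohort.
#' @param filter a [site_filter_spec] (default basic).
#' @param qc a [qc_spec]; the pipeline default disables the per-sample
#'   `mind` ceiling (`mind_max = 1`) because a union-merged cohort built
#'   from per-sample callsets legitimately carries high per-sample
#'   missingness — the merged-stage convention is site missingness plus
#'   HWE only. Pass an explicit [qc_spec()] to restore the sample filter.
#' @param kinship_estimator `"robust"` or `"within"`.
#' @param marker_set `"complete-case"` or `"pairwise"`.
#' @param roh a [roh_params] profile.
#' @param grid_kb ROH minimum-length sweep grid in kb.
#' @param x_subset minimum lengths (Mb) tabulated in the report.
#' @param window_mb deviation-profile window in Mb.
#' @param gen_time,cm_per_mb,ref_years timing constants, see
#'   [date_length()].
#' @param out_dir output directory for the run artifacts.
#' @param seed integer seed controlling any randomness in the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf_paths = NULL, simulate = NULL,
                       filter = site_filter_spec("basic"),
                       qc = qc_spec(mind_max = 1),
                       kinship_estimator = "robust",
                       marker_set = "complete-case", roh = roh_params(),
                       grid_kb = seq(100, 5000, by = 100),
                       x_subset = c(0.1, 1.5, 5), window_mb = c(0.7, 1.5),
                       gen_time = 26.9, cm_per_mb = 1,
                       ref_years = c(1960, 2012), out_dir, seed = 1L) {
  if (is.null(vcf_paths) == is.null(simulate)) {
    stop("exactly one of vcf_paths or simulate must be given")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "cohort_spec"))
  stopifnot(inherits(filter, "site_filter_spec"), inherits(qc, "qc_spec"),
            inherits(roh, "roh_params"),
            kinship_estimator %in% c("robust", "within"),
            marker_set %in% c("complete-case", "pairwise"))
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()]; nested blocks `filter`, `qc`, `roh` and `simulate` are
#' passed to [site_filter_spec()], [qc_spec()], [roh_params()] and
#' [cohort_spec()] respectively.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$filter)) args$filter <- do.call(site_filter_spec, y$filter)
  if (!is.null(y$qc)) args$qc <- do.call(qc_spec, y$qc)
  if (!is.null(y$roh)) args$roh <- do.call(roh_params, y$roh)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$chrom_lengths_mb)) {
      sim$chrom_lengths_mb <- unlist(sim$chrom_lengths_mb)
    }
    args$simulate <- do.call(cohort_spec, sim)
  }
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Sequences the stages import (or simulate) -> merge -> QC -> per-sample
#' and cohort statistics -> kinship -> ROH sweep -> founder report, writing
#' every stage output plus a structured log of record counts to the
#' configured output directory. Identical configuration and inputs yield
#' identical outputs; the configuration (with its MD5 hash) is serialized
#' alongside them.
#'
#' @param cfg a [run_config] (or a YAML path accepted by
#'   [read_run_config()]).
#' @return invisibly, a list with the main in-memory results (`matrix`,
#'   `stats`, `kinship`, `sweep`, `report`, `out_dir`). On stage failure
#'   the error names the failing stage and a `FAILED` marker file is left
#'   in the output directory with the partial outputs.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), cfg_path)
  say("config hash: %s", unname(tools::md5sum(cfg_path)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines("FAILED", file.path(cfg$out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(cfg$seed)
  merged <- if (!is.null(cfg$simulate)) {
    stage("simulate", {
      sim <- simulate_cohort(cfg$simulate)
      say("simulate: %d samples x %d sites (seed %g)",
          n_samples(sim$matrix), n_sites(sim$matrix), cfg$simulate$seed)
      sim$matrix
    })
  } else {
    stage("import+merge", {
      mats <- lapply(cfg$vcf_paths, load_vcf, spec = cfg$filter)
      for (k in seq_along(mats)) {
        say("import: %s -> %d samples x %d sites", cfg$vcf_paths[k],
            n_samples(mats[[k]]), n_sites(mats[[k]]))
      }
      if (length(mats) == 1L) mats[[1L]] else merge_cohort(mats)
    })
  }
  say("merged: %d samples x %d sites, missing rate %.4f",
      n_samples(merged), n_sites(merged), mean(is.na(merged$genotypes)))

  qcd <- stage("qc", apply_qc(merged, cfg$qc))
  ql <- attr(qcd, "qc_log")
  say("qc: removed %d samples (mind), %d sites (geno), %s sites (hwe) -> %d x %d",
      ql$samples_removed_mind, ql$sites_removed_geno,
      ifelse(is.na(ql$sites_removed_hwe), "NA", ql$sites_removed_hwe),
      n_samples(qcd), n_sites(qcd))

  stats_df <- stage("stats", sample_stats(qcd))
  utils::write.table(stats_df, file.path(cfg$out_dir, "sample_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (n_samples(merged) >= 2L) {
    bins <- stage("stats", het_by_call_rate(merged))
    utils::write.table(bins, file.path(cfg$out_dir, "het_by_call_rate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  maf <- stage("maf", maf_spectrum(qcd))
  utils::write.table(maf, file.path(cfg$out_dir, "maf_spectrum.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("stats: %d samples summarized; %d maf grid values", nrow(stats_df),
      nrow(maf))

  kin <- stage("kinship", kinship_matrix(qcd, cfg$kinship_estimator,
                                         cfg$marker_set))
  utils::write.table(kin, file.path(cfg$out_dir, "kinship.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("kinship: %d pairs (%s, %s)", nrow(kin), cfg$kinship_estimator,
      cfg$marker_set)

  sweep <- stage("roh", sweep_roh(qcd, cfg$roh, cfg$grid_kb))
  utils::write.table(sweep, file.path(cfg$out_dir, "roh_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  segs <- attr(sweep, "segments")
  if (!is.null(segs) && nrow(segs)) {
    utils::write.table(segs, file.path(cfg$out_dir, "roh_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  say("roh: %d segments at min_kb=%g over %d grid points",
      if (is.null(segs)) 0L else nrow(segs), cfg$grid_kb[1L],
      length(cfg$grid_kb))

  report <- stage("timing", founder_report(
    qcd, sweep, kin, x_subset = cfg$x_subset, window_mb = cfg$window_mb,
    gen_time = cfg$gen_time, cm_per_mb = cfg$cm_per_mb,
    ref_years = cfg$ref_years, out_dir = cfg$out_dir))
  say("report: match x = %.3g Mb; l_min = %s, l_max = %s Mb",
      report$match_x_mb, format(report$deviation$l_min_mb),
      format(report$deviation$l_max_mb))

  invisible(list(matrix = qcd, stats = stats_df, kinship = kin,
                 sweep = sweep, report = report, out_dir = cfg$out_dir))
}
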