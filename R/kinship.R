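#' Genotype-concordance counts for a sample pair
#'
#' Counts, over the markers non-missing in both samples, the quantities the
#' KING kinship estimators are built from: each sample's heterozygote count,
#' the number of sites at which both are heterozygous, and the number of
#' opposite-homozygote sites (one sample hom-ref, the other hom-alt).
#'
#' @param m a [genotype_matrix].
#' @param i,j sample ids or indices; `i != j`.
#' @return a list of class `pair_counts` with elements `n_het_i`,
#'   `n_het_j`, `n_both_het`, `n_opp_hom`, `m_shared`, `id_i`, `id_j`.
#' @export
pair_counts <- function(m, i, j) {
  if (is.character(i)) i <- match(i, m$sample_ids)
  if (is.character(j)) j <- match(j, m$sample_ids)
  stopifnot(!is.na(i), !is.na(j), i != j)
  gi <- m$genotypes[i, ]
  gj <- m$genotypes[j, ]
  shared <- !is.na(gi) & !is.na(gj)
  m_shared <- sum(shared)
  if (m_shared == 0L) stop("no shared non-missing markers for pair")
  gi <- gi[shared]
  gj <- gj[shared]
  structure(list(
    n_het_i = sum(gi == 1L),
    n_het_j = sum(gj == 1L),
    n_both_het = sum(gi == 1L & gj == 1L),
    n_opp_hom = sum(abs(gi - gj) == 2L),
    m_shared = m_shared,
    id_i = m$sample_ids[i], id_j = m$sample_ids[j]
  ), class = "pair_counts")
}

kinship_result <- function(phi, estimator, counts) {
  structure(list(phi = phi, relatedness = 2 * phi, estimator = estimator,
                 pair_het = (counts$n_het_i + counts$n_het_j) /
                   (2 * counts$m_shared),
                 counts = counts),
            class = "kinship_result")
}

#' Within-family kinship estimator
#'
#' The KING within-family estimator
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{N_{Aa}^{(i)} + N_{Aa}^{(j)}},}
#' assuming both individuals draw from the same allele-frequency
#' distribution under HWE. Relatedness is `R = 2 * phi`; estimates may be
#' negative and are reported untruncated.
#'
#' @param c a [pair_counts] object.
#' @return a list of class `kinship_result` with `phi`, `relatedness`,
#'   `estimator`, `pair_het`.
#' @export
kinship_within <- function(c) {
  denom <- c$n_het_i + c$n_het_j
  if (denom == 0L) stop("no heterozygotes in pair: within-family estimator undefined")
  kinship_result((c$n_both_het - 2 * c$n_opp_hom) / denom, "within", c)
}

#' Robust (between-family) kinship estimator
#'
#' The KING-robust estimator guards against inflation when the two
#' individuals have different heterozygosity rates (e.g. under population
#' structure or excess-heterozygosity artifacts) by scaling with the
#' *smaller* of the two observed heterozygosity rates. With individual `i`
#' relabeled as the one with lower heterozygosity rate
#' (`n_het / m_shared`),
#' \deqn{\hat\phi = \frac{N_{Aa,Aa} - 2 N_{AA,aa}}{2 N_{Aa}^{(i)}}
#'   + \frac12 - \frac14 \frac{N_{Aa}^{(i)} + N_{Aa}^{(j)}}{N_{Aa}^{(i)}}.}
#' When the two rates are equal the expression reduces algebraically to the
#' within-family estimator, which is used as the deterministic tie-break.
#' The relabeling makes the estimate symmetric in (i, j).
#'
#' @param c a [pair_counts] object.
#' @return a list of class `kinship_result`.
#' @export
kinship_robust <- function(c) {
  rate_i <- c$n_het_i / c$m_shared
  rate_j <- c$n_het_j / c$m_shared
  if (rate_i == rate_j) {
    res <- kinship_within(c)
    res$estimator <- "robust"
    return(res)
  }
  lo <- if (rate_i < rate_j) c$n_het_i else c$n_het_j
  hi <- if (rate_i < rate_j) c$n_het_j else c$n_het_i
  if (lo == 0L) stop("lower-heterozygosity sample has no heterozygotes")
  phi <- (c$n_both_het - 2 * c$n_opp_hom) / (2 * lo) + 1 / 2 -
    (lo + hi) / (4 * lo)
  kinship_result(phi, "robust", c)
}

#' Pairwise kinship table for a cohort
#'
#' Computes kinship for all n(n-1)/2 unordered sample pairs. Two marker-set
#' modes are available:
#'
#' * `"complete-case"` (default): counts are computed over the markers
#'   called in *all* samples, as after missing-genotype filtering of a
#'   merged cohort; every pair then uses the same marker panel.
#' * `"pairwise"`: counts use, per pair, the markers non-missing in the two
#'   samples of that pair (the pre-filter analysis). Pair estimates in this
#'   mode are invariant to adding further samples to the cohort; the two
#'   modes generally differ on merged data because the marker panels differ.
#'
#' @param m a [genotype_matrix] with at least two samples.
#' @param estimator `"robust"` (default) or `"within"`.
#' @param marker_set `"complete-case"` (default) or `"pairwise"`.
#' @return data.frame with one row per pair: `id1`, `id2`, `m_shared`,
#'   `n_both_het`, `n_opp_hom`, `phi`, `relatedness`, `estimator`, `note`
#'   (error message for pairs whose estimate is undefined; such pairs are
#'   flagged, not dropped).
#' @export
kinship_matrix <- function(m, estimator = c("robust", "within"),
                           marker_set = c("complete-case", "pairwise")) {
  estimator <- match.arg(estimator)
  marker_set <- match.arg(marker_set)
  stopifnot(n_samples(m) >= 2L)
  if (marker_set == "complete-case") m <- complete_case_sites(m)
  est_fun <- if (estimator == "robust") kinship_robust else kinship_within
  pairs <- utils::combn(n_samples(m), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    out <- data.frame(id1 = m$sample_ids[i], id2 = m$sample_ids[j],
                      m_shared = NA_integer_, n_both_het = NA_integer_,
                      n_opp_hom = NA_integer_, phi = NA_real_,
                      relatedness = NA_real_, estimator = estimator,
                      note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      pc <- pair_counts(m, i, j)
      est <- est_fun(pc)
      out$m_shared <- pc$m_shared
      out$n_both_het <- pc$n_both_het
      out$n_opp_hom <- pc$n_opp_hom
      out$phi <- est$phi
      out$relatedness <- est$relatedness
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
    res
  })
  do.call(rbind, rows)
}

#' Expected kinship for standard relationship classes
#'
#' Pedigree-expectation kinship coefficients: the probability that one
#' allele sampled from each of two individuals is identical by descent.
#'
#' @param class one of `"parent-offspring"`, `"full-sib"`, `"half-sib"`,
#'   `"first-cousin"`, `"half-cousin"`, `"unrelated"` (vectorized).
#' @return numeric kinship coefficient(s) (e.g. 1/4 for parent-offspring,
#'   1/32 for half first cousins).
#' @export
kinship_expectation <- function(class) {
  tab <- c("parent-offspring" = 1 / 4, "full-sib" = 1 / 4,
           "half-sib" = 1 / 8, "first-cousin" = 1 / 16,
           "half-cousin" = 1 / 32, "unrelated" = 0)
  if (!all(class %in% names(tab))) {
    stop("unknown relationship class: ",
         paste(setdiff(class, names(tab)), collapse = ", "))
  }
  unname(tab[class])
}

#' Kinship matrix implied by a pedigree
#'
#' Standard recursive computation of pedigree kinship coefficients:
#' founders are non-inbred and unrelated, `phi(i,i) = (1 + phi(f,m)) / 2`,
#' and `phi(i,j) = (phi(f_i,j) + phi(m_i,j)) / 2` for `j` not a descendant
#' of `i`.
#'
#' @param ped data.frame with columns `id`, `father`, `mother` (NA for
#'   founders); parents must appear before their offspring.
#' @return symmetric numeric matrix of kinship coefficients with
#'   `ped$id` dimnames.
#' @export
pedigree_kinship <- function(ped) {
  stopifnot(all(c("id", "father", "mother") %in% names(ped)))
  ids <- as.character(ped$id)
  n <- length(ids)
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  if (any(!is.na(fa) & fa >= seq_len(n)) || any(!is.na(mo) & mo >= seq_len(n))) {
    stop("parents must precede offspring in the pedigree")
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    phi[i, i] <- if (is.na(fa[i]) || is.na(mo[i])) 0.5 else
      0.5 * (1 + phi[fa[i], mo[i]])
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        if (is.na(fa[i]) && is.na(mo[i])) next  # founder: unrelated to priors
        v <- 0
        if (!is.na(fa[i])) v <- v + 0.5 * phi[fa[i], j]
        if (!is.na(mo[i])) v <- v + 0.5 * phi[mo[i], j]
        phi[i, j] <- phi[j, i] <- v
      }
    }
  }
  phi
}
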