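# Across-structure multiplicity control: a structure-level multiplier on the
# Bonferroni-adjusted cluster p-values (p*), and a closed-form rFDR
# significance threshold over all structure x method tests.

#' Structure-level p-value adjustment
#'
#' Multiplies a within-structure Bonferroni-adjusted cluster p-value by a
#' structure-level factor (capped at 1), giving the p* compared against the
#' rFDR threshold.
#'
#' @param p_bonf Bonferroni-adjusted cluster p-value(s).
#' @param multiplier Positive integer factor; by convention `s(s-1)/2` for
#'   `s` structure/chain combinations of the protein, but exposed explicitly
#'   because the appropriate family depends on the study design.
#' @return `min(1, p_bonf * multiplier)`, vectorized.
#' @export
structure_level_adjust <- function(p_bonf, multiplier) {
  stopifnot(multiplier >= 1)
  pmin(1, p_bonf * multiplier)
}

#' Closed-form rFDR significance threshold
#'
#' Approximates the false-discovery-rate significance threshold over k
#' independent or positively correlated tests by the expected alpha,
#' `alpha * (k + 1) / (2k)`.
#'
#' @param alpha Nominal significance level in (0, 1).
#' @param k Total number of tests (k >= 1), e.g. structures times insertion
#'   methods.
#' @return The threshold, in `(alpha/2, alpha]`.
#' @export
rfdr_threshold <- function(alpha, k) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  alpha * (k + 1) / (2 * k)
}

#' Select significant clusters and the representative method per structure
#'
#' Keeps cluster reports whose p* is at or below the rFDR threshold
#' (optionally floored to three decimals, the conventional rounding-down of
#' the printed threshold), and summarizes, per structure, which insertion
#' method yields the most significant cluster.
#'
#' @param reports Data frame of cluster reports carrying at least
#'   `structure_id`, `method`, `p_raw` and `p_star` columns.
#' @param alpha Nominal level (default 0.05).
#' @param k_total Total number of structure x method tests.
#' @param round_down Floor the threshold to 3 decimals (default `TRUE`).
#' @return List with `threshold`, `significant` (filtered reports) and
#'   `best_method` (one row per structure: the method whose minimum p-value
#'   is smallest, with that p-value).
#' @export
significant_clusters <- function(reports, alpha = 0.05, k_total,
                                 round_down = TRUE) {
  thr <- rfdr_threshold(alpha, k_total)
  if (round_down) thr <- floor(thr * 1000) / 1000
  sig <- reports[reports$p_star <= thr, , drop = FALSE]
  rownames(sig) <- NULL

  best <- do.call(rbind, lapply(split(reports, reports$structure_id),
    function(df) {
      minp <- tapply(df$p_raw, df$method, min)
      m <- names(minp)[which.min(minp)]
      data.frame(structure_id = df$structure_id[1L], method = m,
                 min_p = unname(min(minp)), stringsAsFactors = FALSE)
    }))
  rownames(best) <- NULL
  list(threshold = thr, significant = sig, best_method = best)
}
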