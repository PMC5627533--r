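#' Recovery rate of validated fusions at a score threshold
#'
#' Computes the fraction of independently validated fusion pairs that the
#' scored output reports at or above a confidence threshold. Matching is
#' by canonical gene pair (orientation- and case-insensitive): validated
#' lists rarely carry exact breakpoints. A truth pair with no scored row
#' at all counts as not recovered, so fusions the caller never detected
#' weigh against recovery.
#'
#' @param truth Character vector of validated pair keys (e.g. from
#'   [read_pair_file()]); must be non-empty.
#' @param scored Scored tibble from [score_fusions()] (or
#'   [read_scored_table()]).
#' @param threshold Score threshold; a pair is recovered when some scored
#'   row for it has `score_total >= threshold`. Default 8, the
#'   high-confidence cutoff.
#' @return A list with `n_recovered`, `n_truth`, `rate` (fraction) and
#'   `recovered` / `missed` pair keys.
#' @export
recovery_rate <- function(truth, scored, threshold = 8) {
  truth <- .canon_pairs(truth)
  if (length(truth) == 0L) {
    stop("truth set must be non-empty", call. = FALSE)
  }
  if (!is.finite(threshold)) {
    stop("threshold must be finite", call. = FALSE)
  }
  hit_pairs <- if (nrow(scored) == 0L) character(0) else {
    unique(gene_pair(scored$gene1, scored$gene2)[
      scored$score_total >= threshold])
  }
  recovered <- intersect(truth, hit_pairs)
  list(
    n_recovered = length(recovered),
    n_truth = length(truth),
    rate = length(recovered) / length(truth),
    recovered = recovered,
    missed = setdiff(truth, recovered)
  )
}

#' Sweep recovery rate over score thresholds
#'
#' Evaluates [recovery_rate()] and the surviving candidate count at each
#' of a series of thresholds, e.g. to trade off sensitivity against
#' specificity. Both the candidate count and the recovery rate are
#' non-increasing in the threshold.
#'
#' @param truth Character vector of validated pair keys.
#' @param scored Scored tibble.
#' @param thresholds Numeric vector of thresholds, sorted ascending.
#'   Defaults to 6.5 (high + medium confidence) and 8 (high confidence).
#' @return A tibble with columns `threshold`, `n_candidates` (scored rows
#'   at or above the threshold), `n_recovered`, `n_truth`, `recovery`.
#' @export
threshold_sweep <- function(truth, scored, thresholds = c(6.5, 8)) {
  if (length(thresholds) == 0L || is.unsorted(thresholds)) {
    stop("thresholds must be a nondecreasing numeric vector", call. = FALSE)
  }
  rows <- lapply(thresholds, function(th) {
    rec <- recovery_rate(truth, scored, th)
    tibble::tibble(
      threshold = th,
      n_candidates = if (nrow(scored) == 0L) 0L else
        sum(scored$score_total >= th),
      n_recovered = rec$n_recovered,
      n_truth = rec$n_truth,
      recovery = rec$rate)
  })
  dplyr::bind_rows(rows)
}
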