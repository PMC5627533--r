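#' Score weight configuration
#'
#' Assembles the full set of weights, thresholds and bin edges driving the
#' confidence score. Every candidate starts from `baseline` (10 score
#' units) and each firing rule adds its (mostly negative) weight; the total
#' is capped at `score_cap`. All defaults are the method's published
#' values:
#'
#' * `w_artifact` (-6): gene pair is on the recurrent-artifact blacklist.
#' * `w_readthrough_altsplice` (-4): candidate carries a read-through or
#'   alternative-splicing annotation.
#' * `w_adjacent_only` (-0.5): partners are neighbouring genes but no
#'   read-through/altsplice flag is set (adjacent-gene fusions can be
#'   real, so the penalty is mild).
#' * `w_intrachromosomal` (-0.5): both partners on one chromosome. Set
#'   `intra_distance_cutoff` (bases) to waive this penalty for partners
#'   further apart than the cutoff.
#' * `w_homology` (-1): breakpoint homology of at least
#'   `homology_threshold` (10) bases makes the junction ambiguous.
#' * `w_repeat_mid` (-0.5): 80% up to 90% of spanning reads lie in repeat
#'   regions; `w_repeat_high` (-1): more than 90%.
#' * `w_no_orf` (-1): no preserved open reading frame;
#'   `w_not_exon_boundary` (-1.5): splicing point not at a known exon
#'   boundary.
#' * `w_downstream_3prime` (-4): break point downstream of the 3' partner.
#' * `w_all_multimapped` (-1.5): every spanning read maps to more than one
#'   genomic location (requires at least one spanning read).
#'
#' The read-support component always fires and is tiered: with
#' `s = split_count`, `u = unique_span_count`, `o = occurrence` (number of
#' transcripts reported for the same gene pair in the sample), the support
#' index is `(s >= split_tiers[1]) + (s >= split_tiers[2]) +
#' (u >= unique_span_tiers[1]) + (u >= unique_span_tiers[2]) +
#' (o >= occurrence_tier)` and `read_support_levels[index + 1]` is the
#' component, by default -2.0, -1.0, -0.5, +0.5, +1.5, +2.5 — monotone in
#' all three inputs, never zero, and spanning the method's stated range of
#' -2.0 to +2.5.
#'
#' Confidence classes: high for totals of at least `high_min` (8), medium
#' for `medium_min`..`medium_max` (6.5..7.5), low for at most `low_max`
#' (6). Because every weight is a half-integer multiple, no total can fall
#' in the gaps (6, 6.5) or (7.5, 8).
#'
#' @param ... Named overrides for any field listed above; unknown names
#'   are rejected.
#' @return An object of class `weight_config`.
#' @examples
#' weight_config()
#' weight_config(w_artifact = -8, intra_distance_cutoff = 1e6)
#' @export
weight_config <- function(...) {
  cfg <- list(
    baseline = 10,
    score_cap = 10,
    w_artifact = -6,
    w_readthrough_altsplice = -4,
    w_adjacent_only = -0.5,
    w_intrachromosomal = -0.5,
    intra_distance_cutoff = NULL,
    w_homology = -1,
    homology_threshold = 10,
    w_repeat_mid = -0.5,
    w_repeat_high = -1,
    w_no_orf = -1,
    w_not_exon_boundary = -1.5,
    w_downstream_3prime = -4,
    w_all_multimapped = -1.5,
    split_tiers = c(10, 50),
    unique_span_tiers = c(5, 15),
    occurrence_tier = 2,
    read_support_levels = c(-2, -1, -0.5, 0.5, 1.5, 2.5),
    high_min = 8,
    medium_min = 6.5,
    medium_max = 7.5,
    low_max = 6
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("weight overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown weight config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(overrides)] <- overrides
  }
  dbl <- c(grep("^w_", names(cfg), value = TRUE), "baseline", "score_cap",
           "read_support_levels", "high_min", "medium_min", "medium_max",
           "low_max")
  cfg[dbl] <- lapply(cfg[dbl], as.numeric)
  validate_weight_config(structure(cfg, class = "weight_config"))
}

#' Validate a weight configuration
#'
#' Enforces the structural guarantees the classifier relies on: all
#' weights and the baseline are integer multiples of 0.5 (so no total can
#' land strictly between the medium and high bands), the read-support
#' levels are nonzero, monotone and within -2.0..+2.5, and the class
#' thresholds are ordered with `medium_max < high_min <= score_cap`.
#'
#' @param cfg A `weight_config`.
#' @return The configuration, invisibly, if valid.
#' @export
validate_weight_config <- function(cfg) {
  stopifnot(inherits(cfg, "weight_config"))
  half <- c("baseline", "score_cap", "w_artifact", "w_readthrough_altsplice",
            "w_adjacent_only", "w_intrachromosomal", "w_homology",
            "w_repeat_mid", "w_repeat_high", "w_no_orf",
            "w_not_exon_boundary", "w_downstream_3prime", "w_all_multimapped",
            "read_support_levels")
  for (key in half) {
    v <- cfg[[key]]
    if (!is.numeric(v) || any(abs(v * 2 - round(v * 2)) > 1e-9)) {
      stop("weight config '", key, "' must be an integer multiple of 0.5",
           call. = FALSE)
    }
  }
  ls <- cfg$read_support_levels
  if (length(ls) != 6L || any(ls == 0) || is.unsorted(ls) ||
      min(ls) < -2 || max(ls) > 2.5) {
    stop("read_support_levels must be 6 nondecreasing nonzero values ",
         "within [-2, 2.5]", call. = FALSE)
  }
  if (cfg$w_all_multimapped == 0) {
    stop("w_all_multimapped must be nonzero", call. = FALSE)
  }
  if (!(cfg$medium_max < cfg$high_min && cfg$high_min <= cfg$score_cap)) {
    stop("class thresholds must satisfy medium_max < high_min <= score_cap",
         call. = FALSE)
  }
  if (!(cfg$low_max < cfg$medium_min && cfg$medium_min <= cfg$medium_max)) {
    stop("class thresholds must satisfy low_max < medium_min <= medium_max",
         call. = FALSE)
  }
  if (length(cfg$split_tiers) != 2L || length(cfg$unique_span_tiers) != 2L ||
      is.unsorted(cfg$split_tiers) || is.unsorted(cfg$unique_span_tiers)) {
    stop("split_tiers and unique_span_tiers must each be 2 nondecreasing ",
         "values", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a weight configuration from a YAML file
#'
#' The file holds a flat mapping of `weight_config` field names to values;
#' omitted fields keep their defaults and unknown keys are rejected (a
#' typo in a weight name must not silently score with defaults).
#'
#' @param path Path to the YAML file.
#' @return A validated `weight_config`.
#' @export
read_weight_config <- function(path) {
  if (!file.exists(path)) {
    stop("weight config not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop("weight config ", path, " must be a YAML mapping", call. = FALSE)
  }
  do.call(weight_config, vals)
}

#' @export
print.weight_config <- function(x, ...) {
  cat("Fusion confidence score weights\n")
  cat("  baseline:", x$baseline, " cap:", x$score_cap, "\n")
  for (key in grep("^w_", names(x), value = TRUE)) {
    cat(sprintf("  %-24s %5.1f\n", key, x[[key]]))
  }
  cat("  read support levels:",
      paste(sprintf("%+.1f", x$read_support_levels), collapse = " "), "\n")
  cat(sprintf("  classes: high >= %.1f | medium %.1f-%.1f | low <= %.1f\n",
              x$high_min, x$medium_min, x$medium_max, x$low_max))
  invisible(x)
}
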