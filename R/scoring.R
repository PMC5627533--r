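#' Count fusion transcripts per gene pair within one sample
#'
#' Callers sometimes report several distinct fusion transcripts (splice
#' variants) for one pair of partner genes in a sample; this recurrence
#' within a sample is evidence for a genuine fusion and feeds the
#' read-support tier as the `occurrence` input.
#'
#' @param fusions Canonical fusion tibble for a single sample.
#' @return Named integer vector: canonical pair key -> number of
#'   transcripts reported for that pair in the sample.
#' @export
compute_occurrence <- function(fusions) {
  stopifnot(is.data.frame(fusions))
  if (nrow(fusions) == 0L) {
    out <- integer(0)
    names(out) <- character(0)
    return(out)
  }
  if (length(unique(fusions$sample_id)) > 1L) {
    stop("occurrence is defined per sample; got multiple sample_id values",
         call. = FALSE)
  }
  tab <- table(gene_pair(fusions$gene1, fusions$gene2))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Tiered read-support score component
#'
#' Combines split-read count, uniquely mapping spanning-read count and the
#' within-sample occurrence of the gene pair into one component between
#' -2.0 and +2.5 score units. Candidates with spanning reads of which none
#' maps uniquely get `w_all_multimapped` (-1.5) outright: such support is
#' unreliable regardless of volume. Everything else is scored by the
#' monotone tier table described in [weight_config()]; candidates with no
#' support at all fall to the lowest tier (-2.0). The component is never
#' zero: read support always speaks for or against a candidate.
#'
#' @param split_count,span_count,unique_span_count Non-negative integer
#'   vectors (recycled); `unique_span_count <= span_count`.
#' @param occurrence Positive integer vector: transcripts sharing the
#'   candidate's gene pair within its sample.
#' @param cfg A [weight_config()].
#' @return Numeric vector of score components.
#' @examples
#' read_support_score(50, 20, 0, 1)   # all spanning reads multimapped
#' read_support_score(150, 40, 40, 2) # strong unique support
#' @export
read_support_score <- function(split_count, span_count, unique_span_count,
                               occurrence = 1L, cfg = weight_config()) {
  n <- max(length(split_count), length(span_count),
           length(unique_span_count), length(occurrence))
  s <- rep_len(as.numeric(split_count), n)
  sp <- rep_len(as.numeric(span_count), n)
  u <- rep_len(as.numeric(unique_span_count), n)
  o <- rep_len(as.numeric(occurrence), n)
  if (any(s < 0 | sp < 0 | u < 0) || any(u > sp)) {
    stop("counts must be non-negative with unique_span_count <= span_count",
         call. = FALSE)
  }
  idx <- (s >= cfg$split_tiers[1]) + (s >= cfg$split_tiers[2]) +
    (u >= cfg$unique_span_tiers[1]) + (u >= cfg$unique_span_tiers[2]) +
    (o >= cfg$occurrence_tier)
  out <- cfg$read_support_levels[idx + 1L]
  all_multi <- sp > 0 & u == 0
  out[all_multi] <- cfg$w_all_multimapped
  out
}

#' Classify a confidence score
#'
#' @param total Numeric vector of total confidence scores.
#' @param cfg A [weight_config()].
#' @return Character vector: `"high"` (total >= 8), `"medium"`
#'   (6.5 <= total <= 7.5) or `"low"` (total <= 6) under defaults. With
#'   half-integer weights no total can fall between the bands; if one does
#'   (a corrupted custom configuration), an internal-consistency error is
#'   raised rather than a silent misclassification.
#' @export
classify_score <- function(total, cfg = weight_config()) {
  out <- rep(NA_character_, length(total))
  out[total >= cfg$high_min] <- "high"
  out[total >= cfg$medium_min & total <= cfg$medium_max] <- "medium"
  out[total <= cfg$low_max] <- "low"
  if (anyNA(out)) {
    stop("internal consistency error: score ", total[which(is.na(out))[1L]],
         " falls between confidence bands", call. = FALSE)
  }
  out
}

# Vectorized per-feature components for a canonical fusion table.
# Returns a tibble of the ten score_* component columns; a component is 0
# when its rule did not fire. `occurrence` is a per-row integer vector.
.score_components <- function(fusions, artifacts, occurrence, cfg) {
  n <- nrow(fusions)
  in_artifact <- if (is.null(artifacts)) {
    rep(FALSE, n)
  } else {
    artifact_contains(artifacts, fusions$gene1, fusions$gene2)
  }
  rt_as <- fusions$read_through | fusions$altsplice
  intra <- !fusions$interchromosomal
  if (!is.null(cfg$intra_distance_cutoff)) {
    far <- abs(fusions$break_pos1 - fusions$break_pos2) >
      cfg$intra_distance_cutoff
    intra <- intra & !far
  }
  r <- fusions$repeat_proportion
  tibble::tibble(
    score_artifact = ifelse(in_artifact, cfg$w_artifact, 0),
    score_read_through_altsplice = ifelse(rt_as,
                                          cfg$w_readthrough_altsplice, 0),
    score_adjacent = ifelse(fusions$adjacent & !rt_as,
                            cfg$w_adjacent_only, 0),
    score_intrachromosomal = ifelse(intra, cfg$w_intrachromosomal, 0),
    score_homology = ifelse(
      fusions$breakpoint_homology >= cfg$homology_threshold,
      cfg$w_homology, 0),
    score_repeat = ifelse(r > 0.9, cfg$w_repeat_high,
                          ifelse(r >= 0.8, cfg$w_repeat_mid, 0)),
    score_no_orf = ifelse(!fusions$orf, cfg$w_no_orf, 0),
    score_not_exon_boundary = ifelse(!fusions$exon_boundary,
                                     cfg$w_not_exon_boundary, 0),
    score_downstream_3prime = ifelse(fusions$downstream_3prime_break,
                                     cfg$w_downstream_3prime, 0),
    score_read_support = read_support_score(
      fusions$split_count, fusions$span_count, fusions$unique_span_count,
      occurrence, cfg)
  )
}

#' Score a single fusion candidate
#'
#' Applies every scoring rule to one candidate and returns the full
#' per-feature breakdown. The total is
#' `min(score_cap, baseline + sum(components))`; components are reported
#' only for rules that fired (the read-support component always fires).
#'
#' @param rec A one-row canonical fusion tibble, or a named list with the
#'   canonical fields (see [read_fusion_table()]).
#' @param artifacts Optional `artifact_list` for the blacklist rule.
#' @param occurrence Number of transcripts sharing this candidate's gene
#'   pair within its sample (>= 1); use [compute_occurrence()] when
#'   scoring rows out of a full table.
#' @param cfg A [weight_config()].
#' @return An object of class `score_breakdown`: list with `components`
#'   (named numeric vector over fired rules), `raw_total`, `total`,
#'   `confidence_class`, and `occurrence`.
#' @examples
#' clean <- list(
#'   cluster_id = "c1", sample_id = "s1", gene1 = "AKAP9", gene2 = "BRAF",
#'   chrom1 = "7", chrom2 = "12", break_pos1 = 1000L, break_pos2 = 2000L,
#'   strand1 = "+", strand2 = "-", split_count = 150L, span_count = 40L,
#'   unique_span_count = 40L, breakpoint_homology = 3L,
#'   repeat_proportion = 0.1, read_through = FALSE, altsplice = FALSE,
#'   adjacent = FALSE, interchromosomal = TRUE, orf = TRUE,
#'   exon_boundary = TRUE, downstream_3prime_break = FALSE,
#'   caller_probability = 0.9)
#' score_candidate(clean, occurrence = 2)
#' @export
score_candidate <- function(rec, artifacts = NULL, occurrence = 1L,
                            cfg = weight_config()) {
  if (!is.data.frame(rec)) rec <- tibble::as_tibble(rec[names(.fusion_columns)])
  if (nrow(rec) != 1L) {
    stop("score_candidate expects exactly one record", call. = FALSE)
  }
  validate_fusion_table(rec)
  occurrence <- as.integer(occurrence)
  if (is.na(occurrence) || occurrence < 1L) {
    stop("occurrence must be an integer >= 1", call. = FALSE)
  }
  comp <- .score_components(rec, artifacts, occurrence, cfg)
  vals <- unlist(comp[1L, ])
  names(vals) <- sub("^score_", "", names(vals))
  fired <- vals[vals != 0 | names(vals) == "read_support"]
  raw_total <- cfg$baseline + sum(vals)
  total <- min(cfg$score_cap, raw_total)
  structure(
    list(components = fired, raw_total = raw_total, total = total,
         confidence_class = classify_score(total, cfg),
         occurrence = occurrence),
    class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat("Fusion confidence score:", sprintf("%.1f", x$total),
      sprintf("(%s confidence)\n", x$confidence_class))
  for (nm in names(x$components)) {
    cat(sprintf("  %-24s %+5.1f\n", nm, x$components[[nm]]))
  }
  if (x$raw_total != x$total) {
    cat(sprintf("  raw total %.1f capped at %.1f\n", x$raw_total, x$total))
  }
  invisible(x)
}

#' Score a fusion-candidate table
#'
#' Scores every row of a candidate table: occurrence is computed per
#' sample, each scoring rule contributes its component, and the total
#' `min(score_cap, baseline + sum(components))` is classified into
#' high/medium/low confidence. Results are independent of input row order;
#' output rows are sorted by total score descending, ties broken by
#' `cluster_id` then `sample_id` ascending.
#'
#' @param fusions Canonical fusion tibble (one or more samples).
#' @param artifacts Optional `artifact_list`.
#' @param cfg A [weight_config()].
#' @return The input columns plus `occurrence`, one `score_*` column per
#'   rule (0 when the rule did not fire), `score_total` and
#'   `confidence_class`.
#' @export
score_fusions <- function(fusions, artifacts = NULL, cfg = weight_config()) {
  validate_fusion_table(fusions)
  if (nrow(fusions) == 0L) {
    out <- fusions
    for (col in .score_columns) {
      out[[col]] <- if (col == "confidence_class") character(0) else numeric(0)
    }
    out$occurrence <- integer(0)
    return(out)
  }
  pair <- gene_pair(fusions$gene1, fusions$gene2)
  occ <- stats::ave(rep(1L, nrow(fusions)),
                    fusions$sample_id, pair, FUN = length)
  comp <- .score_components(fusions, artifacts, occ, cfg)
  raw_total <- cfg$baseline + rowSums(comp)
  total <- pmin(cfg$score_cap, raw_total)
  out <- dplyr::bind_cols(fusions, tibble::tibble(occurrence = occ), comp)
  out$score_total <- total
  out$confidence_class <- classify_score(total, cfg)
  out[order(-out$score_total, out$cluster_id, out$sample_id), ]
}
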