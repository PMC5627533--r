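#' Construct a single fusion candidate record
#'
#' Builds a one-row canonical candidate table, convenient for probing
#' individual scoring rules. The defaults describe a "clean"
#' interchromosomal candidate with strong unique read support, low
#' breakpoint homology, low repeat content, a preserved reading frame and
#' an exon-boundary breakpoint — a candidate on which no penalty fires —
#' so setting a single field isolates that rule's component.
#'
#' @param gene1,gene2 Partner gene identifiers.
#' @param chrom1,chrom2 Chromosome names; `interchromosomal` defaults to
#'   their inequality (after stripping any `chr` prefix).
#' @param split_count,span_count,unique_span_count Read support counts.
#' @param breakpoint_homology Bases mapping equally well to both partners.
#' @param repeat_proportion Maximum fraction of spanning reads in repeat
#'   regions.
#' @param read_through,altsplice,adjacent,orf,exon_boundary,downstream_3prime_break
#'   Structure flags.
#' @param interchromosomal Override for the interchromosomal flag (must
#'   stay consistent with the chromosome names).
#' @param cluster_id,sample_id Identifiers.
#' @param break_pos1,break_pos2,strand1,strand2 Breakpoint coordinates.
#' @param caller_probability Pass-through caller probability.
#' @return A one-row canonical fusion tibble.
#' @examples
#' score_candidate(fusion_candidate())                  # clean: scores 10
#' score_candidate(fusion_candidate(altsplice = TRUE))  # -4 penalty
#' @export
fusion_candidate <- function(gene1 = "GENEA", gene2 = "GENEB",
                             chrom1 = "1", chrom2 = "2",
                             split_count = 150L, span_count = 40L,
                             unique_span_count = 40L,
                             breakpoint_homology = 3L,
                             repeat_proportion = 0.1,
                             read_through = FALSE, altsplice = FALSE,
                             adjacent = FALSE,
                             interchromosomal =
                               .norm_chrom(chrom1) != .norm_chrom(chrom2),
                             orf = TRUE, exon_boundary = TRUE,
                             downstream_3prime_break = FALSE,
                             cluster_id = "c0001", sample_id = "sample1",
                             break_pos1 = 1000L, break_pos2 = 2000L,
                             strand1 = "+", strand2 = "+",
                             caller_probability = 0.9) {
  rec <- tibble::tibble(
    cluster_id = as.character(cluster_id),
    sample_id = as.character(sample_id),
    gene1 = as.character(gene1), gene2 = as.character(gene2),
    chrom1 = as.character(chrom1), chrom2 = as.character(chrom2),
    break_pos1 = as.integer(break_pos1), break_pos2 = as.integer(break_pos2),
    strand1 = strand1, strand2 = strand2,
    split_count = as.integer(split_count),
    span_count = as.integer(span_count),
    unique_span_count = as.integer(unique_span_count),
    breakpoint_homology = as.integer(breakpoint_homology),
    repeat_proportion = as.numeric(repeat_proportion),
    read_through = read_through, altsplice = altsplice, adjacent = adjacent,
    interchromosomal = interchromosomal, orf = orf,
    exon_boundary = exon_boundary,
    downstream_3prime_break = downstream_3prime_break,
    caller_probability = as.numeric(caller_probability))
  validate_fusion_table(rec)
  rec
}
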