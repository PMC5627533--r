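# Independent brute-force scorer: a straight-line transcription of the
# published rule list with the default weights hard-coded, deliberately
# sharing no code with the package's scoring path. Scalar, one record at
# a time.
oracle_score <- function(rec, in_artifact = FALSE, occurrence = 1) {
  s <- 10
  if (in_artifact) s <- s - 6
  if (rec$read_through || rec$altsplice) {
    s <- s - 4
  } else if (rec$adjacent) {
    s <- s - 0.5
  }
  if (!rec$interchromosomal) s <- s - 0.5
  if (rec$breakpoint_homology >= 10) s <- s - 1
  if (rec$repeat_proportion > 0.9) {
    s <- s - 1
  } else if (rec$repeat_proportion >= 0.8) {
    s <- s - 0.5
  }
  if (!rec$orf) s <- s - 1
  if (!rec$exon_boundary) s <- s - 1.5
  if (rec$downstream_3prime_break) s <- s - 4
  if (rec$span_count > 0 && rec$unique_span_count == 0) {
    rs <- -1.5
  } else {
    idx <- (rec$split_count >= 10) + (rec$split_count >= 50) +
      (rec$unique_span_count >= 5) + (rec$unique_span_count >= 15) +
      (occurrence >= 2)
    rs <- c(-2, -1, -0.5, 0.5, 1.5, 2.5)[idx + 1]
  }
  min(10, s + rs)
}

# Random but invariant-respecting candidate rows for property tests.
# Pairs are drawn from a limited pool so within-sample occurrence > 1
# happens regularly.
random_fusion_rows <- function(n, seed, n_samples = 4, pair_pool = NULL) {
  withr::local_seed(seed)
  if (is.null(pair_pool)) pair_pool <- max(20L, as.integer(n / 3))
  pick <- function(x, size) x[sample.int(length(x), size, replace = TRUE)]
  gi <- sample.int(pair_pool, n, replace = TRUE)
  inter <- stats::runif(n) < 0.5
  chrom1 <- pick(c(as.character(1:22), "X", "Y"), n)
  chrom2 <- ifelse(inter,
                   pick(c(as.character(1:22), "X", "Y"), n),
                   chrom1)
  redraw <- which(inter & chrom1 == chrom2)
  while (length(redraw) > 0) {
    chrom2[redraw] <- pick(c(as.character(1:22), "X", "Y"), length(redraw))
    redraw <- which(inter & chrom1 == chrom2)
  }
  span <- sample(0:60, n, replace = TRUE)
  uniq <- vapply(span, function(sp) {
    if (sp == 0) 0L else sample(0:sp, 1)[1]
  }, integer(1))
  adjacent <- stats::runif(n) < 0.3
  read_through <- adjacent & stats::runif(n) < 0.4
  tbl <- tibble::tibble(
    cluster_id = sprintf("r%05d", seq_len(n)),
    sample_id = sprintf("rs%02d", sample.int(n_samples, n, replace = TRUE)),
    gene1 = sprintf("rga%04d", gi),
    gene2 = sprintf("rgb%04d", gi),
    chrom1 = chrom1, chrom2 = chrom2,
    break_pos1 = sample.int(2e8, n, replace = TRUE),
    break_pos2 = sample.int(2e8, n, replace = TRUE),
    strand1 = pick(c("+", "-"), n),
    strand2 = pick(c("+", "-"), n),
    split_count = sample(0:250, n, replace = TRUE),
    span_count = as.integer(span),
    unique_span_count = uniq,
    breakpoint_homology = sample(0:25, n, replace = TRUE),
    repeat_proportion = round(stats::runif(n), 4),
    read_through = read_through,
    altsplice = stats::runif(n) < 0.3,
    adjacent = adjacent,
    interchromosomal = inter,
    orf = stats::runif(n) < 0.6,
    exon_boundary = stats::runif(n) < 0.6,
    downstream_3prime_break = stats::runif(n) < 0.15,
    caller_probability = round(stats::runif(n), 4))
  # plant a few boundary values
  k <- min(n, 10L)
  tbl$breakpoint_homology[seq_len(k)] <- 10L
  tbl$repeat_proportion[seq_len(k)] <- rep(c(0.8, 0.9), length.out = k)
  tbl
}

# Artifact list over a set of pair keys, constructed through the public
# persistence path (not by poking the object's internals).
artifact_list_from_pairs <- function(pairs, min_entities = 3L) {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    sprintf("# min_entities=%d", min_entities),
    "# whitelist_size=0",
    "pair\tentity_count",
    if (length(pairs) > 0) paste(pairs, min_entities, sep = "\t")), path)
  load_artifact_list(path)
}
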