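test_that("occurrence counts transcripts per gene pair within a sample", {
  tbl <- dplyr::bind_rows(
    fusion_candidate(cluster_id = "c1", gene1 = "A", gene2 = "B"),
    fusion_candidate(cluster_id = "c2", gene1 = "C", gene2 = "D"),
    fusion_candidate(cluster_id = "c3", gene1 = "E", gene2 = "F"))
  expect_true(all(compute_occurrence(tbl) == 1L))

  tbl2 <- dplyr::bind_rows(
    fusion_candidate(cluster_id = "c1", gene1 = "A", gene2 = "B"),
    fusion_candidate(cluster_id = "c2", gene1 = "B", gene2 = "A"),
    fusion_candidate(cluster_id = "c3", gene1 = "C", gene2 = "D"))
  occ <- compute_occurrence(tbl2)
  expect_identical(unname(occ["a--b"]), 2L)
  expect_identical(unname(occ["c--d"]), 1L)

  mixed <- tbl
  mixed$sample_id <- c("s1", "s1", "s2")
  expect_error(compute_occurrence(mixed), "sample")
})

test_that("occurrence on a 200-row sample equals a brute-force tally", {
  rows <- random_fusion_rows(200, seed = 21, n_samples = 1)
  rows$sample_id <- "s1"
  occ <- compute_occurrence(rows)
  brute <- table(paste(pmin(tolower(rows$gene1), tolower(rows$gene2)),
                       pmax(tolower(rows$gene1), tolower(rows$gene2)),
                       sep = "--"))
  expect_identical(occ[order(names(occ))],
                   structure(as.integer(brute), names = names(brute)))
})

test_that("read support scoring matches the published tier behaviour", {
  # all spanning reads multimapped: fixed -1.5 regardless of volume
  expect_identical(read_support_score(50, 20, 0, 1), -1.5)
  expect_identical(read_support_score(500, 100, 0, 5), -1.5)
  # no support at all: lowest tier
  expect_identical(read_support_score(0, 0, 0, 1), -2)
  # strong support with recurrence: top tier
  expect_identical(read_support_score(150, 40, 40, 2), 2.5)
  # vectorized
  expect_identical(read_support_score(c(50, 0), c(20, 0), c(0, 0), 1),
                   c(-1.5, -2))
})

test_that("the read-support component is bounded, nonzero and monotone", {
  grid <- expand.grid(s = c(0, 5, 10, 49, 50, 200),
                      sp = c(0, 1, 10, 40),
                      frac = c(0, 0.5, 1),
                      o = c(1, 2, 3))
  grid$u <- floor(grid$sp * grid$frac)
  val <- read_support_score(grid$s, grid$sp, grid$u, grid$o)
  expect_true(all(val >= -2 & val <= 2.5))
  expect_true(all(val != 0))
  # monotone in split reads, unique spanning reads, occurrence
  # (holding the all-multimapped override fixed)
  keep <- !(grid$sp > 0 & grid$u == 0)
  g <- grid[keep, ]
  v <- val[keep]
  expect_true(all(read_support_score(g$s + 10, g$sp, g$u, g$o) >= v))
  g2 <- g[g$u >= 1, ]
  sp2 <- pmax(g2$sp, g2$u + 5)
  expect_true(all(read_support_score(g2$s, sp2, g2$u + 5, g2$o) >=
                    read_support_score(g2$s, sp2, g2$u, g2$o)))
  expect_true(all(read_support_score(g$s, g$sp, g$u, g$o + 1) >= v))
})

test_that("confidence classes follow the published score bands", {
  expect_identical(classify_score(8), "high")
  expect_identical(classify_score(7), "medium")
  expect_identical(classify_score(6), "low")
  expect_identical(classify_score(c(10, 7.5, 6.5, 0, -8)),
                   c("high", "medium", "medium", "low", "low"))
  # gaps between bands are unreachable with half-integer weights;
  # a score inside one signals a corrupted configuration
  expect_error(classify_score(7.7), "between confidence bands")
  expect_error(classify_score(6.2), "between confidence bands")
})

test_that("a clean candidate scores baseline plus support, capped at 10", {
  bd <- score_candidate(fusion_candidate(), occurrence = 2)
  expect_identical(names(bd$components), "read_support")
  expect_identical(unname(bd$components["read_support"]), 2.5)
  expect_identical(bd$raw_total, 12.5)
  expect_identical(bd$total, 10)
  expect_identical(bd$confidence_class, "high")
})

test_that("each adverse feature contributes exactly its published weight", {
  base <- score_candidate(fusion_candidate(), occurrence = 2)
  cases <- list(
    list(rec = fusion_candidate(altsplice = TRUE),
         comp = "read_through_altsplice", w = -4),
    list(rec = fusion_candidate(read_through = TRUE, adjacent = TRUE),
         comp = "read_through_altsplice", w = -4),
    list(rec = fusion_candidate(adjacent = TRUE), comp = "adjacent",
         w = -0.5),
    list(rec = fusion_candidate(chrom2 = "1"), comp = "intrachromosomal",
         w = -0.5),
    list(rec = fusion_candidate(breakpoint_homology = 12L),
         comp = "homology", w = -1),
    list(rec = fusion_candidate(repeat_proportion = 0.85),
         comp = "repeat", w = -0.5),
    list(rec = fusion_candidate(repeat_proportion = 0.95),
         comp = "repeat", w = -1),
    list(rec = fusion_candidate(orf = FALSE), comp = "no_orf", w = -1),
    list(rec = fusion_candidate(exon_boundary = FALSE),
         comp = "not_exon_boundary", w = -1.5),
    list(rec = fusion_candidate(downstream_3prime_break = TRUE),
         comp = "downstream_3prime", w = -4))
  for (case in cases) {
    bd <- score_candidate(case$rec, occurrence = 2)
    expect_identical(unname(bd$components[case$comp]), case$w)
    expect_identical(bd$raw_total, base$raw_total + case$w)
    expect_identical(bd$total, min(10, 12.5 + case$w))
  }
  # artifact membership
  al <- artifact_list_from_pairs(gene_pair("GENEA", "GENEB"))
  bd <- score_candidate(fusion_candidate(), al, occurrence = 2)
  expect_identical(unname(bd$components["artifact"]), -6)
  expect_identical(bd$total, 6.5)
})

test_that("repeat-proportion penalties switch at 0.8 and just above 0.9", {
  comp <- function(r) {
    bd <- score_candidate(fusion_candidate(repeat_proportion = r))
    unname(bd$components["repeat"])
  }
  expect_identical(comp(0.79), NA_real_) # rule did not fire
  expect_identical(comp(0.8), -0.5)
  expect_identical(comp(0.9), -0.5) # -1 applies strictly above 90%
  expect_identical(comp(0.901), -1)
  expect_identical(comp(1), -1)
})

test_that("the adjacent-only and read-through penalties never co-fire", {
  bd <- score_candidate(fusion_candidate(adjacent = TRUE, altsplice = TRUE))
  expect_identical(unname(bd$components["read_through_altsplice"]), -4)
  expect_false("adjacent" %in% names(bd$components))
  bd2 <- score_candidate(fusion_candidate(read_through = TRUE,
                                          adjacent = TRUE))
  expect_false("adjacent" %in% names(bd2$components))
})

test_that("the intrachromosomal penalty can be waived beyond a distance", {
  far <- fusion_candidate(chrom2 = "1", break_pos1 = 1000L,
                          break_pos2 = 90000000L)
  cfg <- weight_config(intra_distance_cutoff = 1e6)
  bd <- score_candidate(far, cfg = cfg)
  expect_false("intrachromosomal" %in% names(bd$components))
  near <- fusion_candidate(chrom2 = "1", break_pos1 = 1000L,
                           break_pos2 = 2000L)
  bd2 <- score_candidate(near, cfg = cfg)
  expect_identical(unname(bd2$components["intrachromosomal"]), -0.5)
})

test_that("flipping any single adverse feature never raises the total", {
  rows <- random_fusion_rows(300, seed = 77)
  al <- artifact_list_from_pairs(
    unique(gene_pair(rows$gene1, rows$gene2))[1:30])
  scored <- score_fusions(rows, al)
  flips <- list(
    function(r) { r$altsplice <- TRUE; r },
    function(r) { r$adjacent <- TRUE; r },
    function(r) { r$orf <- FALSE; r },
    function(r) { r$exon_boundary <- FALSE; r },
    function(r) { r$downstream_3prime_break <- TRUE; r },
    function(r) { r$breakpoint_homology <- pmax(r$breakpoint_homology, 10L); r },
    function(r) { r$repeat_proportion <- pmin(r$repeat_proportion + 0.2, 1); r })
  for (flip in flips) {
    worse <- score_fusions(flip(rows), al)
    m <- merge(scored[c("cluster_id", "score_total")],
               worse[c("cluster_id", "score_total")], by = "cluster_id")
    expect_true(all(m$score_total.y <= m$score_total.x))
  }
})

test_that("totals are additive, capped, and on the half-integer lattice", {
  rows <- random_fusion_rows(1000, seed = 42)
  al <- artifact_list_from_pairs(
    unique(gene_pair(rows$gene1, rows$gene2))[1:50])
  scored <- score_fusions(rows, al)
  comps <- rowSums(scored[grep("^score_", names(scored), value = TRUE)]) -
    scored$score_total
  expect_equal(scored$score_total, pmin(10, 10 + comps), tolerance = 1e-12)
  expect_true(all(scored$score_total * 2 == round(scored$score_total * 2)))
  expect_false(any(scored$score_total > 7.5 & scored$score_total < 8))
  expect_false(any(scored$score_total > 6 & scored$score_total < 6.5))
  expect_true(all(scored$score_total <= 10))
})

test_that("table scoring agrees with the brute-force oracle row by row", {
  rows <- random_fusion_rows(2000, seed = 8)
  pairs <- unique(gene_pair(rows$gene1, rows$gene2))
  al <- artifact_list_from_pairs(pairs[seq(1, length(pairs), by = 7)])
  scored <- score_fusions(rows, al)
  key <- paste(rows$sample_id, gene_pair(rows$gene1, rows$gene2))
  occ <- as.integer(table(key)[key])
  expected <- vapply(seq_len(nrow(rows)), function(i) {
    oracle_score(as.list(rows[i, ]),
                 in_artifact = gene_pair(rows$gene1[i], rows$gene2[i]) %in%
                   al$pairs,
                 occurrence = occ[i])
  }, numeric(1))
  got <- scored$score_total[match(rows$cluster_id, scored$cluster_id)]
  expect_identical(got, expected)
})

test_that("scoring a shuffled table yields identical per-row results", {
  rows <- random_fusion_rows(500, seed = 55)
  al <- artifact_list_from_pairs(
    unique(gene_pair(rows$gene1, rows$gene2))[1:20])
  s1 <- score_fusions(rows, al)
  withr::local_seed(1)
  s2 <- score_fusions(rows[sample(nrow(rows)), ], al)
  m1 <- setNames(s1$score_total, s1$cluster_id)
  m2 <- setNames(s2$score_total, s2$cluster_id)
  expect_identical(m1[order(names(m1))], m2[order(names(m2))])
  # and the emitted ordering itself is deterministic
  expect_identical(s1$cluster_id, s2$cluster_id)
})

test_that("empty tables and bad occurrence arguments are handled", {
  empty <- score_fusions(empty_fusion_table())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("score_total", "confidence_class") %in% names(empty)))
  expect_error(score_candidate(fusion_candidate(), occurrence = 0), ">= 1")
})
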