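#' Parameters for the synthetic cohort generator
#'
#' The generator emulates a multi-entity cohort of caller output tables:
#' planted true fusions with the feature profile observed for validated
#' fusions (under 200 split reads, under 50 spanning reads, mostly
#' uniquely mapping, breakpoint homology under 10 bases, repeat
#' proportion under 0.8, open reading frame preserved, breakpoint at an
#' exon boundary, enriched for interchromosomal events), plus planted
#' artifacts: read-through / alternative-splicing rows, rows whose
#' spanning reads all multimap, and gene pairs recurrently planted across
#' entities so the artifact-list builder has something to find.
#'
#' @param n_samples Number of samples in the cohort.
#' @param n_entities Number of distinct tumour entity labels; samples are
#'   assigned round-robin.
#' @param n_true True fusions planted per sample (each with its own gene
#'   pair, unique to the sample; about 20% get a second splice-variant
#'   transcript so the occurrence rule is exercised).
#' @param n_artifact Flagged artifact rows planted per sample
#'   (read-through/altsplice or all-multimapped spanning reads).
#' @param n_ambiguous Rows planted exactly on decision boundaries
#'   (homology at the threshold, repeat proportion at a bin edge), for
#'   boundary testing.
#' @param n_recurrent_pairs Gene pairs planted across entities; each pair
#'   is assigned between 2 and `n_entities` entities and appears in every
#'   sample of those entities, so pairs with spread >= 3 are expected in a
#'   default artifact list.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_samples = 12L, n_entities = 5L, n_true = 5L,
                          n_artifact = 10L, n_ambiguous = 2L,
                          n_recurrent_pairs = 10L) {
  p <- list(n_samples = as.integer(n_samples),
            n_entities = as.integer(n_entities),
            n_true = as.integer(n_true),
            n_artifact = as.integer(n_artifact),
            n_ambiguous = as.integer(n_ambiguous),
            n_recurrent_pairs = as.integer(n_recurrent_pairs))
  if (anyNA(unlist(p)) || any(unlist(p) < 0L)) {
    stop("cohort parameters must be non-negative integers", call. = FALSE)
  }
  if (p$n_samples < 1L || p$n_entities < 1L) {
    stop("need at least one sample and one entity", call. = FALSE)
  }
  if (p$n_recurrent_pairs > 0L && p$n_entities < 2L) {
    stop("recurrent artifact pairs require at least 2 entities",
         call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

.chroms <- c(as.character(1:22), "X", "Y")

# sample() treats a length-1 numeric x as 1:x; .pick never does
.pick <- function(x, n = 1L) x[sample.int(length(x), n)]

.sample_chroms <- function(inter) {
  c1 <- sample(.chroms, 1L)
  c2 <- if (inter) sample(setdiff(.chroms, c1), 1L) else c1
  c(c1, c2)
}

# One synthetic row as a named list; `kind` selects the feature profile.
.synth_row <- function(kind, sample_id, cluster_id, gene1, gene2) {
  if (kind == "true") {
    inter <- stats::runif(1) < 0.8
    split <- sample(5:199, 1L)
    span <- sample(2:49, 1L)
    uniq <- max(1L, as.integer(round(span * stats::runif(1, 0.8, 1))))
    homology <- sample(0:9, 1L)
    rep_prop <- round(stats::runif(1, 0, 0.8 - 1e-6), 6)
    rt <- FALSE; as_ <- FALSE; adj <- FALSE
    orf <- stats::runif(1) < 0.97
    exb <- stats::runif(1) < 0.97
    down <- FALSE
    prob <- round(stats::runif(1, 0.7, 1), 6)
  } else if (kind == "artifact") {
    subtype <- sample(c("readthrough", "altsplice", "multimapped"), 1L)
    adj <- subtype %in% c("readthrough", "altsplice")
    inter <- if (adj) FALSE else stats::runif(1) < 0.3
    rt <- subtype == "readthrough"
    as_ <- subtype == "altsplice" || (rt && stats::runif(1) < 0.5)
    split <- sample(0:49, 1L)
    span <- sample(0:19, 1L)
    uniq <- if (subtype == "multimapped") 0L else .pick(0:span)
    if (subtype == "multimapped" && span == 0L) span <- sample(1:19, 1L)
    homology <- sample(0:29, 1L)
    rep_prop <- round(stats::runif(1), 6)
    orf <- stats::runif(1) < 0.4
    exb <- stats::runif(1) < 0.5
    down <- stats::runif(1) < 0.2
    prob <- round(stats::runif(1), 6)
  } else if (kind == "recurrent") {
    adj <- stats::runif(1) < 0.5
    inter <- if (adj) FALSE else stats::runif(1) < 0.3
    rt <- adj && stats::runif(1) < 0.5
    as_ <- adj && stats::runif(1) < 0.7
    split <- sample(0:49, 1L)
    span <- sample(1:19, 1L)
    uniq <- .pick(0:span)
    homology <- sample(0:29, 1L)
    rep_prop <- round(stats::runif(1), 6)
    orf <- stats::runif(1) < 0.4
    exb <- stats::runif(1) < 0.5
    down <- FALSE
    prob <- round(stats::runif(1), 6)
  } else { # ambiguous: planted exactly on decision boundaries
    inter <- TRUE
    split <- 10L
    span <- 5L
    uniq <- 5L
    homology <- 10L                     # exactly at the homology threshold
    rep_prop <- sample(c(0.8, 0.9), 1L) # exactly at a repeat bin edge
    rt <- FALSE; as_ <- FALSE; adj <- FALSE
    orf <- TRUE; exb <- TRUE; down <- FALSE
    prob <- 0.5
  }
  ch <- .sample_chroms(inter)
  list(
    cluster_id = cluster_id, sample_id = sample_id,
    gene1 = gene1, gene2 = gene2,
    chrom1 = ch[1L], chrom2 = ch[2L],
    break_pos1 = sample.int(2e8, 1L), break_pos2 = sample.int(2e8, 1L),
    strand1 = sample(c("+", "-"), 1L), strand2 = sample(c("+", "-"), 1L),
    split_count = as.integer(split), span_count = as.integer(span),
    unique_span_count = as.integer(uniq),
    breakpoint_homology = as.integer(homology),
    repeat_proportion = rep_prop,
    read_through = rt, altsplice = as_, adjacent = adj,
    interchromosomal = inter, orf = orf, exon_boundary = exb,
    downstream_3prime_break = down, caller_probability = prob)
}

#' Generate a seeded synthetic fusion cohort with truth labels
#'
#' Builds a full multi-sample cohort in the canonical table dialect, with
#' a per-row label (`true_fusion`, `artifact` or `ambiguous`) recording
#' what was planted. Identical `(params, seed)` reproduce the cohort
#' bit-for-bit.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `synthetic_cohort`: list with `manifest`
#'   (sample_id, entity, path — paths filled by [write_cohort()]),
#'   `tables` (named list of canonical tibbles per sample), `labels`
#'   (tibble sample_id, cluster_id, label), `truth` (character vector of
#'   planted true-fusion pair keys), `recurrent_pairs` (tibble pair,
#'   n_entities planned), `params` and `seed`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_samples = 4, n_entities = 2,
#'                                         n_recurrent_pairs = 3), seed = 1)
#' names(cohort$tables)
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  entities <- sprintf("entity%02d", seq_len(params$n_entities))
  sample_ids <- sprintf("S%03d", seq_len(params$n_samples))
  sample_entity <- entities[((seq_len(params$n_samples) - 1L) %%
                               params$n_entities) + 1L]

  # recurrent gene pairs, each spread over 2..n_entities entities
  recurrent <- NULL
  rec_assign <- list()
  if (params$n_recurrent_pairs > 0L) {
    g1 <- sprintf("RECA%03d", seq_len(params$n_recurrent_pairs))
    g2 <- sprintf("RECB%03d", seq_len(params$n_recurrent_pairs))
    spread <- vapply(seq_len(params$n_recurrent_pairs), function(i) {
      .pick(2:params$n_entities)
    }, integer(1))
    rec_assign <- lapply(seq_len(params$n_recurrent_pairs), function(i) {
      sample(entities, spread[i])
    })
    recurrent <- tibble::tibble(
      gene1 = g1, gene2 = g2, pair = gene_pair(g1, g2),
      n_entities = spread)
  }

  tables <- vector("list", params$n_samples)
  names(tables) <- sample_ids
  labels <- list()
  truth_pairs <- character(0)

  for (si in seq_len(params$n_samples)) {
    sid <- sample_ids[si]
    ent <- sample_entity[si]
    rows <- list()
    labs <- character(0)
    k <- 0L
    nxt <- function() {
      k <<- k + 1L
      sprintf("c%04d", k)
    }
    for (i in seq_len(params$n_true)) {
      g1 <- sprintf("TRA%s_%03d", sid, i)
      g2 <- sprintf("TRB%s_%03d", sid, i)
      rows[[length(rows) + 1L]] <- .synth_row("true", sid, nxt(), g1, g2)
      labs <- c(labs, "true_fusion")
      truth_pairs <- c(truth_pairs, gene_pair(g1, g2))
      if (stats::runif(1) < 0.2) { # second splice variant: occurrence 2
        rows[[length(rows) + 1L]] <- .synth_row("true", sid, nxt(), g1, g2)
        labs <- c(labs, "true_fusion")
      }
    }
    for (i in seq_len(params$n_artifact)) {
      g1 <- sprintf("ARA%s_%03d", sid, i)
      g2 <- sprintf("ARB%s_%03d", sid, i)
      rows[[length(rows) + 1L]] <- .synth_row("artifact", sid, nxt(), g1, g2)
      labs <- c(labs, "artifact")
    }
    if (params$n_recurrent_pairs > 0L) {
      for (i in seq_len(params$n_recurrent_pairs)) {
        if (!ent %in% rec_assign[[i]]) next
        rows[[length(rows) + 1L]] <- .synth_row(
          "recurrent", sid, nxt(), recurrent$gene1[i], recurrent$gene2[i])
        labs <- c(labs, "artifact")
      }
    }
    for (i in seq_len(params$n_ambiguous)) {
      g1 <- sprintf("AMA%s_%03d", sid, i)
      g2 <- sprintf("AMB%s_%03d", sid, i)
      rows[[length(rows) + 1L]] <- .synth_row("ambiguous", sid, nxt(), g1, g2)
      labs <- c(labs, "ambiguous")
    }
    tbl <- if (length(rows) == 0L) empty_fusion_table() else
      dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    tables[[sid]] <- tbl
    labels[[si]] <- tibble::tibble(
      sample_id = sid,
      cluster_id = if (nrow(tbl) == 0L) character(0) else tbl$cluster_id,
      label = labs)
  }

  structure(
    list(
      manifest = tibble::tibble(sample_id = sample_ids,
                                entity = sample_entity,
                                path = NA_character_),
      tables = tables,
      labels = dplyr::bind_rows(labels),
      truth = unique(truth_pairs),
      recurrent_pairs = recurrent,
      params = params,
      seed = seed),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic fusion cohort:", nrow(x$manifest), "sample(s),",
      length(unique(x$manifest$entity)), "entity label(s), seed", x$seed, "\n")
  cat("  rows:", sum(vapply(x$tables, nrow, integer(1))),
      "| planted true pairs:", length(x$truth),
      "| recurrent pairs:",
      if (is.null(x$recurrent_pairs)) 0L else nrow(x$recurrent_pairs), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one candidate TSV per sample (canonical dialect), the cohort
#' manifest, the per-row truth labels, and the planted-truth pair list, so
#' a full simulate / build-artifacts / score / evaluate round can run from
#' files alone.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The cohort with `manifest$path` filled in, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(cohort$manifest$sample_id, ".tsv"))
  for (i in seq_along(paths)) {
    write_fusion_table(cohort$tables[[cohort$manifest$sample_id[i]]],
                       paths[i])
  }
  manifest <- cohort$manifest
  manifest$path <- paste0(manifest$sample_id, ".tsv") # relative to manifest
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$labels, file.path(dir, "labels.tsv"),
                   progress = FALSE)
  writeLines(cohort$truth, file.path(dir, "truth.txt"))
  cohort$manifest$path <- paths
  invisible(cohort)
}
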