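#' Read a cohort manifest
#'
#' A manifest lists the per-sample candidate tables used to build an
#' artifact list: TSV with columns `sample_id`, `entity` (tumour entity
#' label) and `path` (candidate table location, resolved relative to the
#' manifest's directory when not absolute).
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `sample_id`, `entity`, `path`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("sample_id", "entity", "path"), names(m))
  if (length(missing) > 0L) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_cohort_manifest(m)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m[c("sample_id", "entity", "path")]
}

#' Validate a cohort manifest
#'
#' @param manifest Data frame with `sample_id`, `entity`, `path` columns.
#' @return The manifest, invisibly, if valid.
#' @export
validate_cohort_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest))
  missing <- setdiff(c("sample_id", "entity", "path"), names(manifest))
  if (length(missing) > 0L) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         manifest$sample_id[duplicated(manifest$sample_id)][1L],
         call. = FALSE)
  }
  if (any(!nzchar(trimws(manifest$entity)))) {
    stop("manifest entity labels must be non-empty", call. = FALSE)
  }
  invisible(manifest)
}

#' Build the cross-entity recurrent-artifact list
#'
#' The same true fusion is rarely found across multiple unrelated tumour
#' entities, so gene pairs recurrently called across entities are treated
#' as mapping or library artifacts. For every gene pair seen in any cohort
#' table, the number of *distinct entities* with at least one sample
#' containing the pair is counted (multiple samples or multiple transcripts
#' within one entity count once). Pairs observed in at least `min_entities`
#' entities enter the blacklist; verified fusions supplied as a whitelist
#' are removed even when they meet the recurrence threshold.
#'
#' @param manifest Cohort manifest (tibble with `sample_id`, `entity`,
#'   `path`), e.g. from [read_cohort_manifest()].
#' @param min_entities Minimum number of distinct entities (default 3, the
#'   shipped recurrence threshold).
#' @param whitelist Character vector of pair keys (or anything accepted by
#'   [gene_pair()] after splitting with `"--"`) excluded from the list.
#' @param column_aliases Alias mapping forwarded to [read_fusion_table()].
#' @return An object of class `artifact_list`: a list with `pairs`
#'   (character vector of canonical pair keys), `entity_counts` (named
#'   integer vector over every observed pair), `min_entities`, and
#'   `whitelist`.
#' @export
build_artifact_list <- function(manifest, min_entities = 3L,
                                whitelist = character(0),
                                column_aliases = default_column_aliases()) {
  validate_cohort_manifest(manifest)
  min_entities <- as.integer(min_entities)
  if (is.na(min_entities) || min_entities < 1L) {
    stop("min_entities must be an integer >= 1", call. = FALSE)
  }
  whitelist <- .canon_pairs(whitelist)
  obs <- list()
  for (i in seq_len(nrow(manifest))) {
    tbl <- tryCatch(
      read_fusion_table(manifest$path[i], column_aliases = column_aliases,
                        sample_id = manifest$sample_id[i]),
      error = function(e) {
        stop("manifest entry '", manifest$sample_id[i], "': ",
             conditionMessage(e), call. = FALSE)
      })
    if (nrow(tbl) == 0L) next
    obs[[length(obs) + 1L]] <- tibble::tibble(
      pair = gene_pair(tbl$gene1, tbl$gene2),
      entity = manifest$entity[i])
  }
  if (length(obs) == 0L) {
    counts <- integer(0)
    names(counts) <- character(0)
  } else {
    pe <- unique(dplyr::bind_rows(obs))
    tab <- table(pe$pair)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts <- counts[order(names(counts))]
  }
  pairs <- names(counts)[counts >= min_entities]
  pairs <- setdiff(pairs, whitelist)
  structure(
    list(pairs = pairs, entity_counts = counts,
         min_entities = min_entities, whitelist = whitelist),
    class = "artifact_list")
}

.canon_pairs <- function(x) {
  if (length(x) == 0L) return(character(0))
  parts <- strsplit(x, "--", fixed = TRUE)
  ok <- vapply(parts, length, integer(1)) == 2L
  out <- character(length(x))
  out[ok] <- gene_pair(vapply(parts[ok], `[`, character(1), 1L),
                       vapply(parts[ok], `[`, character(1), 2L))
  out[!ok] <- tolower(trimws(x[!ok]))
  unique(out)
}

#' An empty artifact list
#'
#' @param min_entities Recurrence threshold recorded on the object.
#' @return An empty `artifact_list`.
#' @export
empty_artifact_list <- function(min_entities = 3L) {
  counts <- integer(0)
  names(counts) <- character(0)
  structure(
    list(pairs = character(0), entity_counts = counts,
         min_entities = as.integer(min_entities), whitelist = character(0)),
    class = "artifact_list")
}

#' Test gene pairs for artifact-list membership
#'
#' Membership is orientation- and case-insensitive: the query is
#' canonicalized with [gene_pair()] before lookup, so a pair listed as
#' `A--B` is found when queried as `(B, A)`.
#'
#' @param artifacts An `artifact_list`.
#' @param gene1,gene2 Character vectors of partner gene identifiers.
#' @return Logical vector.
#' @export
artifact_contains <- function(artifacts, gene1, gene2) {
  stopifnot(inherits(artifacts, "artifact_list"))
  gene_pair(gene1, gene2) %in% artifacts$pairs
}

#' @export
print.artifact_list <- function(x, ...) {
  cat("Artifact list:", length(x$pairs), "gene pair(s)\n")
  cat("  recurrence threshold (entities):", x$min_entities, "\n")
  cat("  observed pairs:", length(x$entity_counts),
      "| whitelisted:", length(x$whitelist), "\n")
  invisible(x)
}

#' Save an artifact list
#'
#' Writes a TSV with columns `pair` and `entity_count` (every observed
#' pair, blacklisted or not), preceded by header comment lines recording
#' the recurrence threshold, whitelist size, and the whitelisted pairs, so
#' that [load_artifact_list()] reproduces the object exactly.
#'
#' @param artifacts An `artifact_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_artifact_list <- function(artifacts, path) {
  stopifnot(inherits(artifacts, "artifact_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# min_entities=", artifacts$min_entities),
    paste0("# whitelist_size=", length(artifacts$whitelist)),
    if (length(artifacts$whitelist) > 0L)
      paste0("# whitelist=", paste(artifacts$whitelist, collapse = ",")),
    "pair\tentity_count"), con)
  if (length(artifacts$entity_counts) > 0L) {
    writeLines(paste(names(artifacts$entity_counts),
                     artifacts$entity_counts, sep = "\t"), con)
  }
  invisible(path)
}

#' Load an artifact list
#'
#' @param path Path to a file written by [save_artifact_list()].
#' @return An `artifact_list`.
#' @export
load_artifact_list <- function(path) {
  if (!file.exists(path)) {
    stop("artifact list not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  me <- sub("^# min_entities=", "", grep("^# min_entities=", hdr, value = TRUE))
  if (length(me) != 1L || is.na(suppressWarnings(as.integer(me)))) {
    stop("artifact list file ", path,
         " lacks a '# min_entities=' header line", call. = FALSE)
  }
  wl_line <- grep("^# whitelist=", hdr, value = TRUE)
  whitelist <- if (length(wl_line) == 1L) {
    strsplit(sub("^# whitelist=", "", wl_line), ",", fixed = TRUE)[[1L]]
  } else character(0)
  body_idx <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body_idx) == 0L || lines[body_idx[1L]] != "pair\tentity_count") {
    stop("artifact list file ", path, " lacks the 'pair\tentity_count' header",
         call. = FALSE)
  }
  data_idx <- body_idx[-1L]
  counts <- integer(0)
  names(counts) <- character(0)
  if (length(data_idx) > 0L) {
    parts <- strsplit(lines[data_idx], "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 2L)
    if (length(bad) > 0L) {
      stop("malformed artifact list line ", data_idx[bad[1L]], " in ", path,
           call. = FALSE)
    }
    counts <- .parse_int(vapply(parts, `[`, character(1), 2L),
                         data_idx, "entity_count")
    names(counts) <- vapply(parts, `[`, character(1), 1L)
    counts <- counts[order(names(counts))]
  }
  min_entities <- as.integer(me)
  pairs <- setdiff(names(counts)[counts >= min_entities], whitelist)
  structure(
    list(pairs = pairs, entity_counts = counts,
         min_entities = min_entities, whitelist = whitelist),
    class = "artifact_list")
}
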