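# Canonical column set for a fusion-candidate table, with expected types.
# Coordinates are 1-based and passthrough: no arithmetic is done on them
# beyond chromosome equality for the interchromosomal flag.
.fusion_columns <- c(
  cluster_id = "character",
  sample_id = "character",
  gene1 = "character",
  gene2 = "character",
  chrom1 = "character",
  chrom2 = "character",
  break_pos1 = "integer",
  break_pos2 = "integer",
  strand1 = "strand",
  strand2 = "strand",
  split_count = "integer",
  span_count = "integer",
  unique_span_count = "integer",
  breakpoint_homology = "integer",
  repeat_proportion = "double",
  read_through = "logical",
  altsplice = "logical",
  adjacent = "logical",
  interchromosomal = "logical",
  orf = "logical",
  exon_boundary = "logical",
  downstream_3prime_break = "logical",
  caller_probability = "double"
)

#' Default column aliases for the deFuse output dialect
#'
#' Maps each canonical column used by fusescore onto the header names found
#' in deFuse v0.6.x output, so genuine deFuse tables can be read without
#' renaming. Each entry is a list of alternatives tried in order; an
#' alternative is either a single header name or a combination rule:
#'
#' * `repeat_proportion` falls back to the row-wise maximum of
#'   `repeat_proportion1` and `repeat_proportion2` (the larger of the two
#'   partners' repeat fractions is the one that compromises mapping).
#' * `unique_span_count` falls back, with a warning, to `span_count` itself
#'   (optimistically assuming every spanning read maps uniquely) when no
#'   dedicated column exists; supply your own alias of the form
#'   `list(op = "minus", cols = c("span_count", "<multimap column>"))` if
#'   your caller version exposes multimapping as a separate count.
#'
#' @return A named list suitable for the `column_aliases` argument of
#'   [read_fusion_table()]. Override individual entries by modifying the
#'   returned list.
#' @export
default_column_aliases <- function() {
  list(
    cluster_id = list("cluster_id"),
    sample_id = list("sample_id", "library_name"),
    gene1 = list("gene1", "gene_name1"),
    gene2 = list("gene2", "gene_name2"),
    chrom1 = list("chrom1", "gene_chromosome1"),
    chrom2 = list("chrom2", "gene_chromosome2"),
    break_pos1 = list("break_pos1", "genomic_break_pos1"),
    break_pos2 = list("break_pos2", "genomic_break_pos2"),
    strand1 = list("strand1", "gene_strand1"),
    strand2 = list("strand2", "gene_strand2"),
    split_count = list("split_count", "splitr_count"),
    span_count = list("span_count"),
    unique_span_count = list(
      "unique_span_count",
      list(op = "identity", cols = "span_count", warn = paste0(
        "no unique_span_count column found; assuming all spanning reads ",
        "map uniquely (unique_span_count = span_count)"))
    ),
    breakpoint_homology = list("breakpoint_homology"),
    repeat_proportion = list(
      "repeat_proportion",
      list(op = "max", cols = c("repeat_proportion1", "repeat_proportion2"))
    ),
    read_through = list("read_through"),
    altsplice = list("altsplice"),
    adjacent = list("adjacent"),
    interchromosomal = list("interchromosomal"),
    orf = list("orf"),
    exon_boundary = list("exon_boundary", "exonboundaries"),
    downstream_3prime_break = list("downstream_3prime_break"),
    caller_probability = list("caller_probability", "probability")
  )
}

# Normalize chromosome names for equality comparison only: case-fold and
# strip a leading "chr". Stored values are untouched.
.norm_chrom <- function(x) sub("^chr", "", tolower(trimws(x)))

.parse_bool <- function(x, row, column) {
  key <- tolower(trimws(x))
  out <- c(y = TRUE, n = FALSE, "true" = TRUE, "false" = FALSE,
           "1" = TRUE, "0" = FALSE, t = TRUE, f = FALSE)[key]
  bad <- which(is.na(out) | is.na(key))
  if (length(bad) > 0L) {
    stop("row ", row[bad[1L]], ", column '", column, "': cannot parse '",
         x[bad[1L]], "' as Y/N boolean", call. = FALSE)
  }
  unname(out)
}

.parse_int <- function(x, row, column) {
  out <- suppressWarnings(as.integer(trimws(x)))
  bad <- which(is.na(out) | trimws(x) != as.character(out))
  if (length(bad) > 0L) {
    stop("row ", row[bad[1L]], ", column '", column, "': cannot parse '",
         x[bad[1L]], "' as integer", call. = FALSE)
  }
  out
}

.parse_dbl <- function(x, row, column) {
  out <- suppressWarnings(as.numeric(trimws(x)))
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("row ", row[bad[1L]], ", column '", column, "': cannot parse '",
         x[bad[1L]], "' as number", call. = FALSE)
  }
  out
}

.parse_strand <- function(x, row, column) {
  out <- trimws(x)
  out[out == "−"] <- "-" # Unicode minus
  bad <- which(!out %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop("row ", row[bad[1L]], ", column '", column, "': strand must be + or -",
         call. = FALSE)
  }
  out
}

#' Validate a canonical fusion-candidate table
#'
#' Checks the record invariants: non-negative counts,
#' `unique_span_count <= span_count`, proportions in \[0, 1\], the
#' `interchromosomal` flag consistent with chromosome equality (after
#' stripping any `chr` prefix), and `read_through` implying `adjacent`
#' (read-through transcription requires neighbouring genes). Violations are
#' reported with row indices.
#'
#' @param fusions A tibble with the canonical columns (see
#'   [read_fusion_table()]).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_fusion_table <- function(fusions) {
  stopifnot(is.data.frame(fusions))
  missing <- setdiff(names(.fusion_columns), names(fusions))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(fusions) == 0L) return(invisible(fusions))
  fail <- function(rows, what) {
    if (any(rows)) {
      stop("invalid fusion record(s) at row(s) ",
           paste(utils::head(which(rows), 5L), collapse = ", "),
           ": ", what, call. = FALSE)
    }
  }
  fail(fusions$split_count < 0L | fusions$span_count < 0L |
         fusions$unique_span_count < 0L | fusions$breakpoint_homology < 0L,
       "counts must be non-negative")
  fail(fusions$unique_span_count > fusions$span_count,
       "unique_span_count exceeds span_count")
  fail(fusions$repeat_proportion < 0 | fusions$repeat_proportion > 1,
       "repeat_proportion outside [0, 1]")
  fail(fusions$caller_probability < 0 | fusions$caller_probability > 1,
       "caller_probability outside [0, 1]")
  fail(fusions$interchromosomal !=
         (.norm_chrom(fusions$chrom1) != .norm_chrom(fusions$chrom2)),
       "interchromosomal flag inconsistent with chromosome names")
  fail(fusions$read_through & !fusions$adjacent,
       "read_through set on non-adjacent gene pair")
  if (any(duplicated(fusions[c("sample_id", "cluster_id")]))) {
    stop("cluster_id values must be unique within a sample", call. = FALSE)
  }
  invisible(fusions)
}

# Resolve one canonical column from the raw character table via its alias
# alternatives; returns a character vector or NULL if unresolvable.
.resolve_column <- function(raw, alts) {
  for (alt in alts) {
    if (is.character(alt) && length(alt) == 1L) {
      if (alt %in% names(raw)) return(raw[[alt]])
    } else if (is.list(alt)) {
      if (!all(alt$cols %in% names(raw))) next
      if (!is.null(alt$warn)) warning(alt$warn, call. = FALSE)
      vals <- lapply(alt$cols, function(cn) {
        suppressWarnings(as.numeric(raw[[cn]]))
      })
      out <- switch(alt$op,
        identity = vals[[1L]],
        max = do.call(pmax, vals),
        minus = pmax(vals[[1L]] - vals[[2L]], 0),
        stop("unknown alias op: ", alt$op, call. = FALSE))
      return(as.character(out))
    }
  }
  NULL
}

#' Read a fusion-candidate table in the deFuse output dialect
#'
#' Reads a tab-separated candidate table (one row per putative fusion
#' transcript), resolves caller-specific header names onto the canonical
#' column set through an alias mapping, parses the dialect's `Y`/`N`
#' boolean encoding (case-insensitive `true`/`false`/`1`/`0` also
#' accepted), and validates every record. Rows are returned in file order.
#'
#' @param path Path to the TSV file. A header row is required; a file with
#'   a header and no data rows (or a zero-byte file) yields an empty table.
#' @param column_aliases Named list mapping canonical columns to candidate
#'   header names; see [default_column_aliases()].
#' @param sample_id Optional sample identifier overriding (or standing in
#'   for) the table's sample column.
#' @return A tibble with one row per fusion transcript and the canonical
#'   columns: identifiers (`cluster_id`, `sample_id`, `gene1`, `gene2`),
#'   breakpoint coordinates (`chrom1/2`, `break_pos1/2`, `strand1/2`),
#'   read support (`split_count`, `span_count`, `unique_span_count`),
#'   mapping quality (`breakpoint_homology`, `repeat_proportion`),
#'   structure flags (`read_through`, `altsplice`, `adjacent`,
#'   `interchromosomal`, `orf`, `exon_boundary`,
#'   `downstream_3prime_break`) and the pass-through `caller_probability`.
#' @export
read_fusion_table <- function(path, column_aliases = default_column_aliases(),
                              sample_id = NULL) {
  if (!file.exists(path)) {
    stop("fusion table not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) return(empty_fusion_table())
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character(),
                         show_col_types = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) return(empty_fusion_table())
  out <- vector("list", length(.fusion_columns))
  names(out) <- names(.fusion_columns)
  n <- nrow(raw)
  rows <- seq_len(n)
  for (col in names(.fusion_columns)) {
    vals <- .resolve_column(raw, column_aliases[[col]])
    if (is.null(vals)) {
      if (col == "sample_id" && !is.null(sample_id)) {
        vals <- rep(as.character(sample_id), n)
      } else {
        stop("required column '", col, "' not found in ", path,
             " under the supplied alias mapping", call. = FALSE)
      }
    }
    out[[col]] <- switch(.fusion_columns[[col]],
      character = trimws(vals),
      integer = .parse_int(vals, rows, col),
      double = .parse_dbl(vals, rows, col),
      logical = .parse_bool(vals, rows, col),
      strand = .parse_strand(vals, rows, col))
  }
  if (!is.null(sample_id)) out$sample_id <- rep(as.character(sample_id), n)
  fusions <- tibble::as_tibble(out)
  validate_fusion_table(fusions)
  fusions
}

#' An empty canonical fusion table
#'
#' @return A zero-row tibble with all canonical columns correctly typed.
#' @export
empty_fusion_table <- function() {
  tibble::as_tibble(lapply(.fusion_columns, function(type) {
    switch(type,
           character = character(0), strand = character(0),
           integer = integer(0), double = numeric(0), logical = logical(0))
  }))
}

.format_bool <- function(x) ifelse(x, "Y", "N")

.format_num <- function(x) {
  # enough digits to round-trip values the generator and scorer produce
  format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Write a canonical fusion table to disk
#'
#' Emits the canonical TSV dialect: tab-delimited, header, no quoting,
#' booleans encoded `Y`/`N`. The output reads back with
#' [read_fusion_table()] without an alias mapping.
#'
#' @param fusions Canonical fusion tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fusion_table <- function(fusions, path) {
  validate_fusion_table(fusions)
  out <- fusions[names(.fusion_columns)]
  for (col in names(.fusion_columns)) {
    out[[col]] <- switch(.fusion_columns[[col]],
      logical = .format_bool(out[[col]]),
      double = .format_num(out[[col]]),
      as.character(out[[col]]))
  }
  readr::write_tsv(out, path, quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

# Score columns appended by write_scored_table, in output order.
.score_columns <- c(
  "occurrence",
  "score_artifact", "score_read_through_altsplice", "score_adjacent",
  "score_intrachromosomal", "score_homology", "score_repeat",
  "score_no_orf", "score_not_exon_boundary", "score_downstream_3prime",
  "score_read_support", "score_total", "confidence_class"
)

#' Write a scored fusion table
#'
#' Writes the scored candidates as TSV with every input column preserved
#' plus the per-feature score components, the total confidence score and
#' the confidence class. Rows are ordered by total score descending, ties
#' broken by `cluster_id` ascending, so output is deterministic and
#' diffable. All score weights are half-integer multiples, so scores are
#' serialized with one decimal place and re-read bit-exactly.
#'
#' @param scored A scored tibble as returned by [score_fusions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_scored_table()]
#' @export
write_scored_table <- function(scored, path) {
  cols <- c(names(.fusion_columns), .score_columns)
  missing <- setdiff(cols, names(scored))
  if (length(missing) > 0L) {
    stop("scored table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- scored[cols]
  out <- out[order(-out$score_total, out$cluster_id), ]
  for (col in names(.fusion_columns)) {
    out[[col]] <- switch(.fusion_columns[[col]],
      logical = .format_bool(out[[col]]),
      double = .format_num(out[[col]]),
      as.character(out[[col]]))
  }
  for (col in grep("^score_", .score_columns, value = TRUE)) {
    out[[col]] <- sprintf("%.1f", out[[col]])
  }
  out$occurrence <- as.character(out$occurrence)
  readr::write_tsv(out, path, quote = "none", escape = "none",
                   progress = FALSE)
  invisible(path)
}

#' Read back a scored fusion table
#'
#' @param path Path to a file written by [write_scored_table()].
#' @return A tibble with the canonical columns plus the score columns.
#' @export
read_scored_table <- function(path) {
  if (!file.exists(path)) {
    stop("scored table not found: ", path, call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character(),
                         show_col_types = FALSE)
  cols <- c(names(.fusion_columns), .score_columns)
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0L) {
    stop("scored table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- seq_len(nrow(raw))
  out <- raw[cols]
  for (col in names(.fusion_columns)) {
    out[[col]] <- switch(.fusion_columns[[col]],
      character = trimws(out[[col]]),
      integer = .parse_int(out[[col]], rows, col),
      double = .parse_dbl(out[[col]], rows, col),
      logical = .parse_bool(out[[col]], rows, col),
      strand = .parse_strand(out[[col]], rows, col))
  }
  out$occurrence <- .parse_int(out$occurrence, rows, "occurrence")
  for (col in grep("^score_", .score_columns, value = TRUE)) {
    out[[col]] <- .parse_dbl(out[[col]], rows, col)
  }
  out
}
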