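#' Canonical unordered gene-pair keys
#'
#' Fusion partners are matched against artifact blacklists and
#' validated-fusion lists by gene pair, ignoring 5'/3' orientation: verified
#' lists rarely preserve partner order and mapping artifacts are
#' orientation-unstable. `gene_pair()` builds a canonical key by stripping
#' whitespace, case-folding, and sorting the two identifiers
#' lexicographically, so `gene_pair("TMPRSS2", "erg")` and
#' `gene_pair("ERG", "tmprss2")` yield the same key.
#'
#' @param a,b Character vectors of gene identifiers (recycled to a common
#'   length).
#' @param sep Separator used in the key string (default `"--"`).
#' @return A character vector of canonical pair keys, e.g. `"erg--tmprss2"`.
#' @examples
#' gene_pair("TMPRSS2", "ERG")
#' gene_pair(" erg ", "TMPRSS2") # same key
#' @export
gene_pair <- function(a, b, sep = "--") {
  a <- tolower(trimws(as.character(a)))
  b <- tolower(trimws(as.character(b)))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    stop("gene identifiers must be non-empty after whitespace stripping",
         call. = FALSE)
  }
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = sep)
}

#' Read a one-pair-per-line fusion list (whitelist or truth set)
#'
#' Whitelists of verified fusions and truth sets for evaluation share one
#' plain-text dialect: one fusion per line, the two partners joined by a
#' separator (`GENEA--GENEB` by default). Blank lines and `#` comments are
#' ignored; pairs are canonicalized with [gene_pair()].
#'
#' @param path Path to the file.
#' @param sep Separator between the two gene identifiers.
#' @return Character vector of canonical pair keys (unique, in file order).
#' @export
read_pair_file <- function(path, sep = "--") {
  if (!file.exists(path)) {
    stop("pair file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character(0))
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop("line ", bad[1L], " of ", path,
         " does not contain exactly one '", sep, "' separator",
         call. = FALSE)
  }
  unique(gene_pair(vapply(parts, `[`, character(1), 1L),
                   vapply(parts, `[`, character(1), 2L)))
}
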