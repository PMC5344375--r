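#' Construct a string collection
#'
#' A string collection is the basic input container: a data frame with a
#' stable 0-based integer `id` and a character `text` per record. Ids are
#' assigned in input order.
#'
#' @param texts character vector of strings (each of length >= 1 symbol
#'   unless `allow_empty` is TRUE).
#' @param meta optional character vector of per-record metadata (e.g. FASTA
#'   headers), recycled against `texts`.
#' @param allow_empty keep empty strings instead of erroring.
#' @return An object of class `string_collection`: a data frame with
#'   columns `id` (integer, 0-based) and `text` (character), plus a `meta`
#'   column when metadata is supplied.
#' @examples
#' string_collection(c("abc", "abd"))
#' @export
string_collection <- function(texts, meta = NULL, allow_empty = FALSE) {
  texts <- as.character(texts)
  if (length(texts) == 0L) stop("a string collection must contain at least one string")
  if (anyNA(texts)) stop("strings may not be NA")
  if (!allow_empty && any(!nzchar(texts)))
    stop("strings must have length >= 1")
  out <- data.frame(
    id = seq_along(texts) - 1L,
    text = texts,
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) out$meta <- rep_len(as.character(meta), length(texts))
  class(out) <- c("string_collection", "data.frame")
  out
}

#' @export
print.string_collection <- function(x, ...) {
  cat(sprintf("<string_collection: %d strings, lengths %d-%d>\n",
              nrow(x), min(nchar(x$text)), max(nchar(x$text))))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a string collection from disk
#'
#' `lines` format: each line (minus its terminator) is one record; interior
#' whitespace is preserved, blank lines are skipped with a warning.
#' `fasta` format: record sequences are uppercased on read and headers kept
#' in the `meta` column. Ids are assigned in file order starting at 0.
#'
#' @param path file path.
#' @param format `"lines"` or `"fasta"`.
#' @return A [string_collection()].
#' @export
read_collection <- function(path, format = c("lines", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "lines") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    blank <- !nzchar(lines)
    if (any(blank)) {
      warning(sprintf("skipped %d blank line(s) in %s", sum(blank), path))
      lines <- lines[!blank]
    }
    if (length(lines) == 0L) stop("no records in ", path)
    return(string_collection(lines))
  }
  read_fasta_collection(path)
}

# Minimal-dependency FASTA reader: Biostrings when available, else a
# line-based fallback (plain-text FASTA only; sequences uppercased).
read_fasta_collection <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) stop("no FASTA records in ", path)
    return(string_collection(toupper(as.character(ss)), meta = names(ss)))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("malformed FASTA (no '>' header) in ", path, " at line 1")
  if (!hdr[1L] && nzchar(trimws(lines[1L])))
    stop("malformed FASTA in ", path, " at line 1: sequence before header")
  rec <- cumsum(hdr)
  keep <- rec > 0L & !hdr & nzchar(lines)
  seqs <- vapply(split(lines[keep], rec[keep]), paste0, "", collapse = "")
  seqs <- seqs[as.character(seq_len(sum(hdr)))]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1L]
    stop("malformed FASTA in ", path, ": record ", bad, " (header line ",
         which(hdr)[bad], ") has an empty sequence")
  }
  string_collection(toupper(seqs), meta = sub("^>\\s*", "", lines[hdr]))
}

#' Write a similar-pair set to a TSV file
#'
#' Writes the canonical three-column table `id_a`, `id_b`,
#' `edit_distance`, sorted by (id_a, id_b). Output bytes are identical
#' across runs with the same configuration.
#'
#' @param pairs a `similar_pairs` object (or data frame with those columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  df <- as.data.frame(pairs)[, c("id_a", "id_b", "edit_distance"), drop = FALSE]
  df <- df[order(df$id_a, df$id_b), , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("id_a\tid_b\tedit_distance", con, sep = "\n")
  if (nrow(df) > 0L)
    writeLines(sprintf("%d\t%d\t%d", df$id_a, df$id_b, df$edit_distance),
               con, sep = "\n")
  invisible(path)
}

#' Read a similar-pair TSV written by [write_pairs()]
#' @param path file path.
#' @return a `similar_pairs` data frame.
#' @export
read_pairs <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("integer", "integer", "integer"))
  similar_pairs(df$id_a, df$id_b, df$edit_distance)
}

# Canonical pair-set container: id_a < id_b, unique, sorted.
similar_pairs <- function(id_a = integer(), id_b = integer(),
                          edit_distance = integer()) {
  lo <- pmin(id_a, id_b)
  hi <- pmax(id_a, id_b)
  df <- data.frame(id_a = as.integer(lo), id_b = as.integer(hi),
                   edit_distance = as.integer(edit_distance))
  df <- df[df$id_a != df$id_b, , drop = FALSE]
  df <- unique(df)
  df <- df[order(df$id_a, df$id_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("similar_pairs", "data.frame")
  df
}

#' @export
print.similar_pairs <- function(x, ...) {
  cat(sprintf("<similar_pairs: %d pair(s)>\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# rbind + dedupe a list of similar_pairs
combine_pairs <- function(pieces) {
  pieces <- pieces[vapply(pieces, NROW, 0L) > 0L]
  if (length(pieces) == 0L) return(similar_pairs())
  df <- do.call(rbind, lapply(pieces, as.data.frame))
  similar_pairs(df$id_a, df$id_b, df$edit_distance)
}

pairs_equal <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  isTRUE(all.equal(a[order(a$id_a, a$id_b), c("id_a", "id_b", "edit_distance")],
                   b[order(b$id_a, b$id_b), c("id_a", "id_b", "edit_distance")],
                   check.attributes = FALSE))
}
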