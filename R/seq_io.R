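#' Sequence collections
#'
#' An `rpi_seqs` object is a named character vector of residue strings with a
#' `kind` attribute (`"rna"` or `"protein"`). Residues are normalized on
#' construction: letters are uppercased and, for RNA, `T` is rewritten to `U`.
#' RNA sequences may contain `A`, `C`, `G`, `U` and the ambiguity letter `N`;
#' protein sequences the 20 standard one-letter codes plus `B`, `Z`, `X`, `U`.
#' Ambiguity letters are kept verbatim here and resolved at encoding time, so
#' I/O is lossless.
#'
#' @param x named character vector of sequences (names are identifiers).
#' @param kind `"rna"` or `"protein"`.
#' @return An `rpi_seqs` object.
#' @examples
#' rpi_seqs(c(r1 = "acgt"), "rna")   # -> "ACGU"
#' @export
rpi_seqs <- function(x, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  if (length(x) == 0L) {
    out <- character(0)
    attr(out, "kind") <- kind
    class(out) <- "rpi_seqs"
    return(out)
  }
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty identifier", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  res <- vapply(unname(x), normalize_residues, character(1), kind = kind)
  bad <- !nzchar(res)
  if (any(bad))
    stop("empty sequence for record(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  allowed <- seq_alphabet(kind)
  for (i in seq_along(res)) {
    letters_i <- unique(strsplit(res[[i]], "", fixed = TRUE)[[1]])
    extra <- setdiff(letters_i, allowed)
    if (length(extra))
      stop(sprintf("record '%s': residue(s) %s not in the %s alphabet",
                   ids[i], paste(extra, collapse = ","), kind), call. = FALSE)
  }
  out <- stats::setNames(res, ids)
  attr(out, "kind") <- kind
  class(out) <- "rpi_seqs"
  out
}

seq_alphabet <- function(kind) {
  if (kind == "rna") c(RNA_ALPHABET, names(RNA_AMBIGUITY))
  else c(PROTEIN_ALPHABET, names(PROTEIN_AMBIGUITY))
}

# Deterministic normalization: uppercase; for RNA also T -> U. Idempotent.
normalize_residues <- function(s, kind) {
  s <- toupper(as.character(s))
  if (kind == "rna") s <- gsub("T", "U", s, fixed = TRUE)
  s
}

#' @export
print.rpi_seqs <- function(x, ...) {
  cat(sprintf("<rpi_seqs> %d %s sequence(s)\n", length(x), attr(x, "kind")))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %s (%d nt/aa): %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read a FASTA file into a sequence collection
#'
#' Multi-record FASTA with wrapped or unwrapped lines. Record order is
#' preserved; identifiers are the first whitespace-delimited token of each
#' header. Records are normalized (see [rpi_seqs()]); duplicated ids, empty
#' sequences and alphabet violations are errors naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param kind `"rna"` or `"protein"`.
#' @return An [rpi_seqs()] collection.
#' @export
read_fasta <- function(path, kind = c("rna", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ", conditionMessage(e),
                         call. = FALSE))
  if (length(set) == 0L)
    stop("no FASTA records in '", path, "'", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("malformed FASTA '", path, "': record with empty header",
         call. = FALSE)
  rpi_seqs(stats::setNames(as.character(set), ids), kind = kind)
}

#' Write a sequence collection as FASTA
#'
#' @param seqs an [rpi_seqs()] collection.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(inherits(seqs, "rpi_seqs"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- unclass(seqs)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

PAIR_LABELS <- c("interactive", "non-interactive")

#' Labeled RNA-protein pair tables
#'
#' A pair table is a data frame with character columns `rna_id`,
#' `protein_id`, `label` (one of `"interactive"`, `"non-interactive"`) and an
#' optional `provenance` column recording the source complex or database
#' entry.
#'
#' @param rna_id,protein_id identifier vectors.
#' @param label label vector.
#' @param provenance optional provenance strings.
#' @return A validated `data.frame`.
#' @export
rpi_pairs <- function(rna_id, protein_id, label,
                      provenance = NA_character_) {
  df <- data.frame(rna_id = as.character(rna_id),
                   protein_id = as.character(protein_id),
                   label = as.character(label),
                   provenance = rep_len(as.character(provenance),
                                        length(rna_id)),
                   stringsAsFactors = FALSE)
  validate_pairs(df)
}

validate_pairs <- function(df) {
  need <- c("rna_id", "protein_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pair table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !df$label %in% PAIR_LABELS
  if (any(bad))
    stop("unknown label(s): ", paste(unique(df$label[bad]), collapse = ", "),
         "; expected one of ", paste(PAIR_LABELS, collapse = "/"),
         call. = FALSE)
  if (is.null(df$provenance)) df$provenance <- NA_character_
  df[c("rna_id", "protein_id", "label", "provenance")]
}

#' Read a labeled pair table (TSV)
#'
#' The file must be tab-separated with a header row containing at least
#' `rna_id`, `protein_id` and `label`. An empty file (header only) yields an
#' empty table.
#'
#' @param path path to a TSV file.
#' @return A pair table (see [rpi_pairs()]).
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L)) == 0L)
    return(rpi_pairs(character(0), character(0), character(0)))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  validate_pairs(df)
}

#' Write a labeled pair table (TSV)
#'
#' @param pairs a pair table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- validate_pairs(pairs)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Resolve ids of a pair table against sequence collections; errors name the
# unresolvable ids.
resolve_pairs <- function(pairs, rna, protein) {
  miss_r <- setdiff(unique(pairs$rna_id), names(rna))
  miss_p <- setdiff(unique(pairs$protein_id), names(protein))
  if (length(miss_r) || length(miss_p))
    stop("unresolvable pair id(s): ",
         paste(c(miss_r, miss_p), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
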