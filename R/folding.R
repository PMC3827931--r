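#' RNA folding backends
#'
#' A folding backend is a function `function(sequence, n)` returning up to
#' `n` dot-bracket strings, each exactly as long as the sequence, balanced,
#' over the alphabet `.()`. The built-in backend is a maximum base-pairing
#' (Nussinov-style) folder that enumerates co-optimal structures -- a
#' desk-scale proxy for a thermodynamic suboptimal folder, which orders
#' structures by base-pair count instead of free energy. An adapter backend
#' replays precomputed suboptimal-folder output files.
#'
#' @param min_loop minimum hairpin loop length (unpaired bases enclosed by a
#'   pair); default 3.
#' @param max_len sequences longer than this raise an error (`policy =
#'   "error"`) or are folded on their first `max_len` bases (`policy =
#'   "truncate"`), mirroring the 4095-nucleotide limit of the external
#'   folder the method was designed around.
#' @param policy `"error"` or `"truncate"`.
#' @return A folding backend function with class `rna_folder`.
#' @export
rna_folder_nussinov <- function(min_loop = 3L, max_len = 4095L,
                                policy = c("error", "truncate")) {
  policy <- match.arg(policy)
  f <- function(sequence, n) {
    stopifnot(n >= 1)
    if (nchar(sequence) > max_len) {
      if (policy == "error")
        stop("RNA longer than ", max_len, " nt (", nchar(sequence),
             "); set policy = \"truncate\" to fold the first ", max_len,
             " bases", call. = FALSE)
      sequence <- substr(sequence, 1L, max_len)
    }
    .nussinov_structures(sequence, as.integer(n), as.integer(min_loop))
  }
  structure(f, backend = list(type = "nussinov", min_loop = min_loop,
                              max_len = max_len, policy = policy),
            class = c("rna_folder", "function"))
}

#' Folding backend replaying precomputed structure files
#'
#' Reads suboptimal-folder output (one file per sequence id: first line the
#' sequence, following lines dot-bracket structures, extra per-line fields
#' ignored) and serves the stored structures.
#'
#' @param files named character vector mapping sequence id to file path.
#' @return A folding backend function with class `rna_folder`.
#' @export
rna_folder_precomputed <- function(files) {
  stopifnot(length(files) > 0, !is.null(names(files)))
  store <- lapply(files, read_subopt_file)
  f <- function(sequence, n) {
    hit <- NULL
    for (id in names(store)) {
      if (identical(normalize_residues(store[[id]]$sequence, "rna"),
                    sequence)) { hit <- store[[id]]; break }
    }
    if (is.null(hit))
      stop("no precomputed structures for the given sequence", call. = FALSE)
    utils::head(hit$structures, n)
  }
  structure(f, backend = list(type = "precomputed", files = files),
            class = c("rna_folder", "function"))
}

# Parse one suboptimal-folder output file: a sequence line followed by
# dot-bracket lines (free-energy columns after whitespace are dropped).
read_subopt_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("structure file '", path, "' needs a sequence line and at least ",
         "one structure line", call. = FALSE)
  structs <- sub("\\s.*$", "", lines[-1])
  list(sequence = sub("\\s.*$", "", lines[1]), structures = structs)
}

# Backend-contract validation shared by every folder: right length, right
# alphabet, balanced brackets.
validate_structures <- function(structs, len) {
  if (length(structs) < 1L)
    stop("folding backend returned no structures", call. = FALSE)
  for (s in structs) {
    if (nchar(s) != len)
      stop("folding backend contract violation: structure length ",
           nchar(s), " != sequence length ", len, call. = FALSE)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(ch %in% c(".", "(", ")")))
      stop("folding backend contract violation: invalid character in ",
           "dot-bracket string", call. = FALSE)
    depth <- cumsum((ch == "(") - (ch == ")"))
    if (any(depth < 0) || depth[length(depth)] != 0)
      stop("folding backend contract violation: unbalanced dot-bracket ",
           "string", call. = FALSE)
  }
  invisible(TRUE)
}
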