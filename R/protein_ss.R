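#' Protein secondary-structure backends
#'
#' A predictor backend is a function `function(sequence)` returning a
#' per-residue state string over `{H, E, C}` of the same length as the
#' input. The built-in predictor applies Chou-Fasman-style sliding-window
#' rules (window-averaged helix and sheet propensities, nucleation threshold
#' 1, ties to sheet); it is a coarse stand-in for a dedicated secondary
#' structure predictor and only needs to supply a plausible 3-state string.
#' An adapter backend replays precomputed 3-state strings.
#'
#' @param helix_window,sheet_window smoothing window sizes (classic
#'   nucleation window sizes 6 and 5).
#' @param scales Chou-Fasman table set as in [default_scales()]`$chou_fasman`.
#' @return A predictor function with class `protein_ss`.
#' @export
protein_ss_choufasman <- function(helix_window = 6L, sheet_window = 5L,
                                  scales = NULL) {
  if (is.null(scales)) scales <- default_scales()$chou_fasman
  f <- function(sequence) {
    res <- strsplit(sequence, "", fixed = TRUE)[[1]]
    pH <- resolve_ambiguity(scales$H)[res]
    pE <- resolve_ambiguity(scales$E)[res]
    mH <- running_mean(pH, helix_window)
    mE <- running_mean(pE, sheet_window)
    states <- rep("C", length(res))
    states[mE >= 1 & mE >= mH] <- "E"
    states[mH >= 1 & mH > mE] <- "H"
    paste(states, collapse = "")
  }
  structure(f, backend = list(type = "choufasman",
                              helix_window = helix_window,
                              sheet_window = sheet_window),
            class = c("protein_ss", "function"))
}

# Centered running mean with shrinking windows at the ends.
running_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Predictor backend replaying precomputed 3-state strings
#'
#' @param states named character vector mapping protein id (or raw sequence)
#'   to an `{H,E,C}` state string.
#' @param seqs optional [rpi_seqs()] collection used to resolve ids to
#'   sequences.
#' @return A predictor function with class `protein_ss`.
#' @export
protein_ss_precomputed <- function(states, seqs = NULL) {
  stopifnot(length(states) > 0, !is.null(names(states)))
  map <- states
  if (!is.null(seqs)) {
    keep <- intersect(names(map), names(seqs))
    names(map)[match(keep, names(map))] <- unclass(seqs)[keep]
  }
  f <- function(sequence) {
    if (!sequence %in% names(map))
      stop("no precomputed secondary-structure string for the given ",
           "sequence", call. = FALSE)
    unname(map[[sequence]])
  }
  structure(f, backend = list(type = "precomputed"),
            class = c("protein_ss", "function"))
}

validate_ss_states <- function(states, len) {
  if (nchar(states) != len)
    stop("secondary-structure backend contract violation: state string ",
         "length ", nchar(states), " != sequence length ", len,
         call. = FALSE)
  ch <- unique(strsplit(states, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, c("H", "E", "C"))
  if (length(bad))
    stop("secondary-structure backend contract violation: state(s) ",
         paste(bad, collapse = ","), " outside {H,E,C}", call. = FALSE)
  invisible(TRUE)
}
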