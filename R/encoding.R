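#' Encode RNA secondary-structure pairedness
#'
#' Folds the sequence into `n` candidate secondary structures, rewrites each
#' dot-bracket string as a binary paired/unpaired profile (brackets 1, dots
#' 0) and sums the `n` binaries, giving a per-residue integer in `[0, n]`:
#' the number of structures in which that base is paired. If the backend
#' yields fewer than `n` distinct structures, the first (best) structure is
#' repeated to reach `n`, keeping the channel magnitude comparable across
#' sequences.
#'
#' @param seq a single RNA sequence (string) or 1-element [rpi_seqs()].
#' @param folder a folding backend (see [rna_folder_nussinov()]).
#' @param n number of structures (default 6).
#' @return Numeric profile of sequence length with attribute
#'   `channel = "rna_structure"`.
#' @export
encode_rna_structure <- function(seq, folder = rna_folder_nussinov(),
                                 n = 6L) {
  s <- as_single_seq(seq, "rna")
  stopifnot(n >= 1)
  structs <- folder(s, n)
  validate_structures(structs, nchar(s))
  if (length(structs) < n)
    structs <- c(structs, rep(structs[1], n - length(structs)))
  structs <- structs[seq_len(n)]
  mat <- vapply(structs,
                function(x) strsplit(x, "", fixed = TRUE)[[1]] != ".",
                logical(nchar(s)))
  prof <- if (nchar(s) == 1L) sum(mat) else as.numeric(rowSums(mat))
  attr(prof, "channel") <- "rna_structure"
  prof
}

#' Encode a sequence with a propensity scale
#'
#' Per-residue lookup: `values[i] = scale(residues[i])`. Ambiguity letters
#' are resolved to the arithmetic mean of the scale over their compatible
#' residues (RNA `N` over A/C/G/U; protein `B` over D/N, `Z` over E/Q, `X`
#' and `U` over all 20).
#'
#' @param seq a single sequence (string or 1-element [rpi_seqs()]).
#' @param scale a [propensity_scale()] whose alphabet matches the sequence
#'   kind.
#' @return Numeric profile of sequence length; the `channel` attribute names
#'   the scale.
#' @export
encode_propensity <- function(seq, scale) {
  if (!inherits(scale, "propensity_scale"))
    stop("`scale` must be a propensity_scale", call. = FALSE)
  kind <- attr(scale, "alphabet")
  s <- as_single_seq(seq, kind)
  v <- resolve_ambiguity(scale)
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  missing <- setdiff(unique(res), names(v))
  if (length(missing))
    stop("residue(s) ", paste(missing, collapse = ","),
         " absent from scale '", attr(scale, "scale_name"), "'",
         call. = FALSE)
  prof <- unname(v[res])
  attr(prof, "channel") <- attr(scale, "scale_name")
  prof
}

#' Encode the protein structure channel
#'
#' Predicts a per-residue 3-state secondary structure and encodes each amino
#' acid with the Chou-Fasman propensity of its predicted state: the helix
#' table under `H`, the sheet table under `E`, and -- the classic tables
#' having no coil class -- the turn table under `C`.
#'
#' @param seq a single protein sequence.
#' @param predictor a predictor backend (see [protein_ss_choufasman()]).
#' @param chou_fasman list of three [propensity_scale()]s keyed `H`, `E`,
#'   `C`.
#' @return Numeric profile with attribute `channel = "prot_structure"`.
#' @export
encode_protein_structure <- function(seq,
                                     predictor = protein_ss_choufasman(),
                                     chou_fasman = NULL) {
  s <- as_single_seq(seq, "protein")
  if (is.null(chou_fasman)) chou_fasman <- default_scales()$chou_fasman
  states <- predictor(s)
  validate_ss_states(states, nchar(s))
  st <- strsplit(states, "", fixed = TRUE)[[1]]
  res <- strsplit(s, "", fixed = TRUE)[[1]]
  tabs <- lapply(chou_fasman, resolve_ambiguity)
  prof <- numeric(length(res))
  for (state in c("H", "E", "C")) {
    idx <- st == state
    if (!any(idx)) next
    vals <- tabs[[state]][res[idx]]
    if (anyNA(vals))
      stop("residue(s) absent from the Chou-Fasman '", state, "' table",
           call. = FALSE)
    prof[idx] <- unname(vals)
  }
  attr(prof, "channel") <- "prot_structure"
  prof
}

#' Encode an RNA sequence into its three compressed channels
#'
#' Secondary-structure pairedness, hydrogen-bonding propensity and Van der
#' Waals propensity profiles, each compressed to `n_terms` cosine-series
#' coefficients. The channel count is always 3, whatever the sequence
#' length.
#'
#' @param seq a single RNA sequence.
#' @param folder folding backend.
#' @param scales scale set as from [default_scales()].
#' @param n_struct number of folded structures.
#' @param n_terms compressed dimension.
#' @return Named list of numeric vectors `structure`, `hbond`, `vdw`, each
#'   of length `n_terms`.
#' @export
encode_rna <- function(seq, folder = rna_folder_nussinov(),
                       scales = default_scales(), n_struct = 6L,
                       n_terms = 10L) {
  list(
    structure = compress_profile(encode_rna_structure(seq, folder, n_struct),
                                 n_terms),
    hbond = compress_profile(encode_propensity(seq, scales$rna_hbond),
                             n_terms),
    vdw = compress_profile(encode_propensity(seq, scales$rna_vdw), n_terms)
  )
}

#' Encode a protein sequence into its five compressed channels
#'
#' Chou-Fasman structure, Grantham and Zimmerman polarity (hydrogen
#' bonding), Kyte-Doolittle and Bull-Breese (Van der Waals), each compressed
#' to `n_terms` coefficients. The channel count is always 5.
#'
#' @param seq a single protein sequence.
#' @param predictor secondary-structure backend.
#' @param scales scale set as from [default_scales()].
#' @param n_terms compressed dimension.
#' @return Named list `structure`, `grantham`, `zimmerman`, `kd`, `bb`.
#' @export
encode_protein <- function(seq, predictor = protein_ss_choufasman(),
                           scales = default_scales(), n_terms = 10L) {
  list(
    structure = compress_profile(
      encode_protein_structure(seq, predictor, scales$chou_fasman), n_terms),
    grantham = compress_profile(encode_propensity(seq, scales$grantham),
                                n_terms),
    zimmerman = compress_profile(encode_propensity(seq, scales$zimmerman),
                                 n_terms),
    kd = compress_profile(encode_propensity(seq, scales$kd), n_terms),
    bb = compress_profile(encode_propensity(seq, scales$bb), n_terms)
  )
}

# Accept either a bare string or a 1-element rpi_seqs of the right kind.
as_single_seq <- function(seq, kind) {
  if (inherits(seq, "rpi_seqs")) {
    if (length(seq) != 1L)
      stop("expected a single sequence, got ", length(seq), call. = FALSE)
    if (attr(seq, "kind") != kind)
      stop("expected a ", kind, " sequence", call. = FALSE)
    return(unclass(seq)[[1]])
  }
  s <- normalize_residues(seq, kind)
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]),
                 seq_alphabet(kind))
  if (length(bad))
    stop("residue(s) ", paste(bad, collapse = ","), " not in the ", kind,
         " alphabet", call. = FALSE)
  s
}
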