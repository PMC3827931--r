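#' Dataset-construction configuration
#'
#' @param distance_cutoff interaction cutoff in Angstrom (default 5.0; the
#'   alternative labeling regime uses 7.0). A pair is interactive iff its
#'   least atom distance is strictly below the cutoff.
#' @param min_rna_len keep a pair only if its RNA is strictly longer than
#'   this (default 100 nt).
#' @param max_rna_len and at most this long (default 4095 nt, the external
#'   folder's input limit).
#' @param protein_identity,rna_identity redundancy-removal identity cutoffs
#'   in `(0, 1]` (default 0.9 for both): a pair is redundant only when it
#'   matches a retained pair on *both* sequences.
#' @param heavy_only restrict the distance computation to heavy atoms
#'   (default `FALSE`: every atom participates).
#' @return A named list.
#' @export
dataset_config <- function(distance_cutoff = 5.0, min_rna_len = 100L,
                           max_rna_len = 4095L, protein_identity = 0.9,
                           rna_identity = 0.9, heavy_only = FALSE) {
  stopifnot(distance_cutoff > 0, min_rna_len >= 0, max_rna_len > 0,
            protein_identity > 0, protein_identity <= 1,
            rna_identity > 0, rna_identity <= 1)
  list(distance_cutoff = distance_cutoff,
       min_rna_len = as.integer(min_rna_len),
       max_rna_len = as.integer(max_rna_len),
       protein_identity = protein_identity, rna_identity = rna_identity,
       heavy_only = heavy_only)
}

#' Least atom distance between two atom sets
#'
#' Minimum Euclidean distance over all cross pairs of atoms; symmetric in
#' its arguments.
#'
#' @param atoms_a,atoms_b numeric matrices with columns x, y, z (rows =
#'   atoms); both nonempty.
#' @param heavy_only drop hydrogen atoms (rows whose `element` rowname is
#'   `"H"`) before computing the minimum.
#' @return Distance in the coordinate units (Angstrom for PDB input).
#' @export
least_atom_distance <- function(atoms_a, atoms_b, heavy_only = FALSE) {
  atoms_a <- as_atom_matrix(atoms_a, heavy_only)
  atoms_b <- as_atom_matrix(atoms_b, heavy_only)
  # block-wise cross distances; atom sets at desk scale are small
  sq <- outer(rowSums(atoms_a^2), rowSums(atoms_b^2), "+") -
    2 * tcrossprod(atoms_a, atoms_b)
  sqrt(max(0, min(sq)))
}

as_atom_matrix <- function(atoms, heavy_only) {
  m <- as.matrix(atoms)
  if (heavy_only && !is.null(rownames(m)))
    m <- m[rownames(m) != "H", , drop = FALSE]
  if (nrow(m) == 0L) stop("empty atom set", call. = FALSE)
  if (ncol(m) != 3L || any(!is.finite(m)))
    stop("atoms must be an n x 3 finite coordinate matrix", call. = FALSE)
  m
}

#' Label interactivity of an RNA/protein chain pair
#'
#' Interactive iff the least atom distance is strictly less than the
#' cutoff; a pair sitting exactly at the cutoff is non-interactive.
#' Labeling is monotone in the cutoff.
#'
#' @param rna_chain,protein_chain chain entries of a `complex_record` (or
#'   any lists with an `atoms` matrix).
#' @param cutoff distance cutoff in Angstrom.
#' @param heavy_only see [least_atom_distance()].
#' @return `"interactive"` or `"non-interactive"`.
#' @export
label_interactivity <- function(rna_chain, protein_chain, cutoff = 5.0,
                                heavy_only = FALSE) {
  d <- least_atom_distance(rna_chain$atoms, protein_chain$atoms,
                           heavy_only = heavy_only)
  if (d < cutoff) "interactive" else "non-interactive"
}

#' Extract labeled pairs from one complex
#'
#' Chains with identical sequences within the complex are collapsed to one
#' representative per polymer kind before pairing (the classic 18-chain
#' example with one duplicated chain keeps 17). Every RNA x protein
#' representative pair is then labeled; a collapsed representative is
#' interactive if *any* of its copies lies within the cutoff of any copy of
#' the partner, and conflicts between copies are reported via `message()`.
#'
#' @param complex a `complex_record`.
#' @param config a [dataset_config()].
#' @return A pair table with provenance `complexid:chainR:chainP`; ids are
#'   `complexid_chain`. The representatives' sequences are attached as
#'   attributes `rna` and `protein` ([rpi_seqs()]).
#' @export
extract_pairs <- function(complex, config = dataset_config()) {
  stopifnot(inherits(complex, "complex_record"))
  kinds <- vapply(complex$chains, `[[`, character(1), "kind")
  groups <- list(rna = which(kinds == "rna"),
                 protein = which(kinds == "protein"))
  if (length(groups$rna) == 0L || length(groups$protein) == 0L) {
    warning("complex '", complex$id, "' lacks an RNA or a protein chain",
            call. = FALSE)
    empty <- rpi_pairs(character(0), character(0), character(0))
    attr(empty, "rna") <- rpi_seqs(character(0), "rna")
    attr(empty, "protein") <- rpi_seqs(character(0), "protein")
    return(empty)
  }
  # within-kind dedup of identical sequences; keep first chain, remember
  # all copies for the ANY-copy labeling rule
  reps <- lapply(groups, function(idx) {
    seqs <- vapply(complex$chains[idx], `[[`, character(1), "sequence")
    lapply(split(idx, factor(seqs, unique(seqs))), identity)
  })
  rows <- list()
  for (r_copies in reps$rna) {
    for (p_copies in reps$protein) {
      dists <- outer(r_copies, p_copies,
                     Vectorize(function(ri, pi)
                       least_atom_distance(complex$chains[[ri]]$atoms,
                                           complex$chains[[pi]]$atoms,
                                           heavy_only = config$heavy_only)))
      lab <- ifelse(min(dists) < config$distance_cutoff, "interactive",
                    "non-interactive")
      copy_labs <- dists < config$distance_cutoff
      if (length(unique(as.vector(copy_labs))) > 1L)
        message("complex '", complex$id, "': copies of a deduplicated ",
                "chain disagree on interactivity; using the ANY-copy rule")
      rid <- complex$chains[[r_copies[1]]]$chain_id
      pid <- complex$chains[[p_copies[1]]]$chain_id
      rows[[length(rows) + 1L]] <- data.frame(
        rna_id = paste0(complex$id, "_", rid),
        protein_id = paste0(complex$id, "_", pid),
        label = lab,
        provenance = paste(complex$id, rid, pid, sep = ":"),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- validate_pairs(do.call(rbind, rows))
  rna_seqs <- vapply(reps$rna, function(c0)
    complex$chains[[c0[1]]]$sequence, character(1))
  names(rna_seqs) <- paste0(complex$id, "_", vapply(reps$rna, function(c0)
    complex$chains[[c0[1]]]$chain_id, character(1)))
  prot_seqs <- vapply(reps$protein, function(c0)
    complex$chains[[c0[1]]]$sequence, character(1))
  names(prot_seqs) <- paste0(complex$id, "_",
                             vapply(reps$protein, function(c0)
                               complex$chains[[c0[1]]]$chain_id,
                               character(1)))
  attr(pairs, "rna") <- rpi_seqs(rna_seqs, "rna")
  attr(pairs, "protein") <- rpi_seqs(prot_seqs, "protein")
  pairs
}

#' Filter pairs by RNA length
#'
#' Keeps a pair iff its RNA is strictly longer than `min_len` and at most
#' `max_len` (the strict lower bound mirrors the "longer than" selection
#' rule; the upper bound mirrors the folder input limit). Idempotent.
#'
#' @param pairs pair table.
#' @param rna RNA sequence collection.
#' @param min_len,max_len length bounds in nucleotides.
#' @return The filtered pair table.
#' @export
filter_rna_length <- function(pairs, rna, min_len = 100L,
                              max_len = 4095L) {
  pairs <- validate_pairs(pairs)
  len <- nchar(unclass(rna)[pairs$rna_id])
  if (anyNA(len)) stop("pair table references unknown RNA id(s)",
                       call. = FALSE)
  pairs[len > min_len & len <= max_len, , drop = FALSE]
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match 1, mismatch 0 and linear
#' gap penalty 1; identity is matches over alignment length (gapped
#' columns included). This is a simple approximation of the word-based
#' identity of the usual clustering tool; [read_cdhit_clusters()] ingests
#' that tool's output for exact reproduction.
#'
#' @param a,b sequences (strings).
#' @return Identity fraction in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  stopifnot(nzchar(a), nzchar(b))
  if (identical(a, b)) return(1)
  letters_u <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1]])
  mat <- diag(1, length(letters_u))
  dimnames(mat) <- list(letters_u, letters_u)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1,
    type = "global")
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' Remove redundant pairs
#'
#' Greedy scan in input order (no silent re-sorting): a pair is dropped iff
#' some already-retained pair has protein identity at or above the protein
#' cutoff *and* RNA identity at or above the RNA cutoff with it. Sharing
#' only one of the two sequences never removes a pair. Idempotent.
#'
#' @param pairs pair table.
#' @param rna,protein sequence collections.
#' @param config a [dataset_config()].
#' @param identity_fun identity function (default [sequence_identity()];
#'   swap in a cluster-file lookup from [read_cdhit_clusters()] for exact
#'   external-tool behavior).
#' @return The non-redundant pair table.
#' @export
remove_redundancy <- function(pairs, rna, protein,
                              config = dataset_config(),
                              identity_fun = sequence_identity) {
  pairs <- validate_pairs(pairs)
  resolve_pairs(pairs, rna, protein)
  if (nrow(pairs) <= 1L) return(pairs)
  keep <- logical(nrow(pairs))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    redundant <- FALSE
    for (j in kept_idx) {
      pid <- identity_fun(unclass(protein)[[pairs$protein_id[i]]],
                         unclass(protein)[[pairs$protein_id[j]]])
      if (pid < config$protein_identity) next
      rid <- identity_fun(unclass(rna)[[pairs$rna_id[i]]],
                          unclass(rna)[[pairs$rna_id[j]]])
      if (rid >= config$rna_identity) { redundant <- TRUE; break }
    }
    if (!redundant) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  pairs[keep, , drop = FALSE]
}

#' Identity lookup from CD-HIT cluster files
#'
#' Parses `.clstr` output (protein and RNA runs) and returns an identity
#' function that reports 1 for two sequences clustered together and 0
#' otherwise, for use as `identity_fun` in [remove_redundancy()].
#'
#' @param path a `.clstr` file.
#' @param seqs the sequence collection the clustering was run on.
#' @return A function `(a, b) -> 0/1`.
#' @export
read_cdhit_clusters <- function(path, seqs) {
  lines <- readLines(path)
  cluster <- cumsum(grepl("^>Cluster", lines))
  is_member <- grepl("^\\d+\\s", lines)
  ids <- sub("\\.\\.\\..*$", "", sub("^.*>", "", lines[is_member]))
  assign_tab <- stats::setNames(cluster[is_member], ids)
  lookup <- stats::setNames(assign_tab[names(seqs)], unclass(seqs))
  function(a, b) {
    ca <- unname(lookup[a]); cb <- unname(lookup[b])
    if (is.na(ca) || is.na(cb)) return(0)
    as.numeric(ca == cb)
  }
}

#' Classify an NPInter-style evidence code
#'
#' Codes 1, 5 and 6 (binding, RNA-affects-protein-function and
#' protein-affects-RNA-function) carry direct evidence of physical
#' interaction; the remaining codes 2, 3, 4, 7, 8 are indirect.
#'
#' @param code integer evidence code(s) in 1..8.
#' @return `"direct"` or `"indirect"` per code.
#' @export
classify_npinter_evidence <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code)) || any(code < 1L | code > 8L))
    stop("evidence code must be in 1..8", call. = FALSE)
  ifelse(code %in% c(1L, 5L, 6L), "direct", "indirect")
}

#' Build a shuffled (randomized) pair set
#'
#' Re-pairs the table's RNA ids against a seeded permutation of its protein
#' ids, preserving the pair count. Permutations that recreate an input
#' pair are rejected and redrawn (up to 100 attempts); if unavoidable --
#' e.g. a single input pair -- the collisions are kept with a warning.
#' Labels are set to `"non-interactive"` (the shuffled set plays the role
#' of a randomized negative set).
#'
#' @param pairs pair table.
#' @param seed RNG seed (required).
#' @return A pair table of the same size.
#' @export
shuffle_pairs <- function(pairs, seed) {
  pairs <- validate_pairs(pairs)
  n <- nrow(pairs)
  if (n == 0L) return(pairs)
  key <- paste(pairs$rna_id, pairs$protein_id)
  perm <- with_seed(seed, {
    best <- sample(n)
    for (try in seq_len(100L)) {
      cand_key <- paste(pairs$rna_id, pairs$protein_id[best])
      if (!any(cand_key %in% key)) break
      best <- sample(n)
    }
    best
  })
  out_key <- paste(pairs$rna_id, pairs$protein_id[perm])
  if (any(out_key %in% key))
    warning("shuffled set reproduces ", sum(out_key %in% key),
            " original pair(s); unavoidable for this input", call. = FALSE)
  rpi_pairs(pairs$rna_id, pairs$protein_id[perm],
            rep("non-interactive", n),
            provenance = rep("shuffled", n))
}

#' Build a labeled dataset from a directory of PDB-format complexes
#'
#' Orchestrates [read_pdb()], [extract_pairs()], [filter_rna_length()] and
#' [remove_redundancy()] over every `*.pdb`/`*.ent` file, logging the pair
#' count after each stage.
#'
#' @param paths PDB file paths (or a single directory).
#' @param config a [dataset_config()].
#' @return List with `pairs`, `rna`, `protein` and a `stats` data frame of
#'   per-stage pair counts.
#' @export
build_dataset <- function(paths, config = dataset_config()) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(pdb|ent)$",
                        full.names = TRUE)
  if (length(paths) == 0L) stop("no PDB files found", call. = FALSE)
  all_pairs <- list(); rna_all <- character(0); prot_all <- character(0)
  for (p in sort(paths)) {
    px <- extract_pairs(read_pdb(p), config)
    all_pairs[[length(all_pairs) + 1L]] <- px
    rna_all <- c(rna_all, unclass(attr(px, "rna")))
    prot_all <- c(prot_all, unclass(attr(px, "protein")))
  }
  pairs <- do.call(rbind, all_pairs)
  rna <- rpi_seqs(rna_all[!duplicated(names(rna_all))], "rna")
  protein <- rpi_seqs(prot_all[!duplicated(names(prot_all))], "protein")
  n0 <- nrow(pairs)
  pairs_len <- filter_rna_length(pairs, rna, config$min_rna_len,
                                 config$max_rna_len)
  pairs_nr <- remove_redundancy(pairs_len, rna, protein, config)
  stats_df <- data.frame(
    stage = c("extracted", "rna_length_filter", "redundancy_removal"),
    pairs = c(n0, nrow(pairs_len), nrow(pairs_nr)),
    interactive = c(sum(pairs$label == "interactive"),
                    sum(pairs_len$label == "interactive"),
                    sum(pairs_nr$label == "interactive")))
  message(paste(sprintf("%-20s %5d pairs (%d interactive)", stats_df$stage,
                        stats_df$pairs, stats_df$interactive),
                collapse = "\n"))
  list(pairs = pairs_nr, rna = rna, protein = protein, stats = stats_df)
}
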