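# Shared fixtures: toy scales, mock backends, brute-force oracles. All
# fixtures are built in code; nothing is read from disk except tempfiles
# the tests themselves write.

toy_rna_scale <- function(values = c(A = 1, C = 2, G = 3, U = 4))
  propensity_scale(values, name = "toy_rna", alphabet = "rna")

toy_protein_scale <- function() {
  v <- seq_along(rpiscore:::PROTEIN_ALPHABET)
  names(v) <- rpiscore:::PROTEIN_ALPHABET
  propensity_scale(v, name = "toy_prot", alphabet = "protein")
}

# A folding backend that replays canned structures (honoring n).
mock_folder <- function(structs) {
  structure(function(sequence, n) utils::head(structs, n),
            class = c("rna_folder", "function"))
}

# A secondary-structure backend returning a fixed state string.
mock_predictor <- function(states) {
  structure(function(sequence) states,
            class = c("protein_ss", "function"))
}

write_tmp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

# Independent oracle for the cosine-series compression: literal double loop.
brute_compress <- function(x, n_terms) {
  L <- length(x)
  vapply(seq_len(n_terms) - 1L, function(k) {
    acc <- 0
    for (n in seq_len(L) - 1L)
      acc <- acc + x[n + 1L] * cos((pi / L) * (n + 0.5) * (k + 0.5))
    2 * acc / L
  }, numeric(1))
}

# Independent oracle for discriminative power: quadratic double loop over
# all (positive, negative) comparisons with theta(0) = 1 in both sums.
brute_dp <- function(pos, neg) {
  fwd <- 0; bwd <- 0
  for (p in pos) for (n in neg) {
    if (p - n >= 0) fwd <- fwd + 1
    if (n - p >= 0) bwd <- bwd + 1
  }
  fwd / (fwd + bwd)
}

# Deterministic small planted dataset reused across model tests.
small_planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- planted_pair_dataset(n_pairs = 40, separation = 4,
                                     noise = 0.1, seed = 5,
                                     rna_len = c(30L, 60L),
                                     protein_len = c(40L, 80L))
    cache
  }
})

# 2FTC-style toy complex: 18 chains = 1 RNA + 17 proteins, two of which
# (E, F) share a sequence. Protein offsets are chosen so exactly 8 of the
# 16 representatives lie strictly inside 5 A of the RNA; the duplicated
# chain's copies disagree (E at 4 A, F at 20 A), exercising the ANY-copy
# rule. All labels are known by construction.
toy_2ftc <- function() {
  rna_seq <- unclass(random_sequences(1, c(120L, 120L), "rna",
                                      seed = 21))[[1]]
  prot <- unclass(random_sequences(16, c(30L, 30L), "protein", seed = 22))
  ids <- LETTERS[2:17]                      # chains B..Q
  chains <- list(list(chain_id = "A", kind = "rna", sequence = rna_seq,
                      pos = c(0, 0)))
  # first 8 representatives interactive (4.0 A), last 8 not (6.0 A)
  for (i in seq_len(16)) {
    chains[[length(chains) + 1L]] <-
      list(chain_id = ids[i], kind = "protein", sequence = prot[[i]],
           pos = c(if (i <= 8) 4.0 else 6.0, 0))
  }
  # duplicate of chain E's sequence (protein #4), far away
  chains[[length(chains) + 1L]] <-
    list(chain_id = "R", kind = "protein", sequence = prot[[4]],
         pos = c(20, 0))
  toy_complex(chains, id = "T2F")
}
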