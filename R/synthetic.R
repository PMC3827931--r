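#' Random sequence collections
#'
#' I.i.d. residues, uniform over the unambiguous alphabet by default or
#' tilted by a propensity scale: with `tilt != 0` residue probabilities are
#' proportional to `exp(tilt * z)` where `z` is the standardized scale
#' value, which shifts the sequence composition along that scale. All
#' randomness is governed by `seed`; the caller's RNG state is untouched.
#'
#' @param n number of sequences.
#' @param length_range inclusive length range (lengths drawn uniformly).
#' @param kind `"rna"` or `"protein"`.
#' @param seed RNG seed (required).
#' @param tilt composition tilt strength (default 0 = uniform).
#' @param scale [propensity_scale()] used for the tilt.
#' @param prefix id prefix.
#' @return An [rpi_seqs()] collection.
#' @export
random_sequences <- function(n, length_range, kind = c("rna", "protein"),
                             seed, tilt = 0, scale = NULL,
                             prefix = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, length(length_range) == 2L,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  alphabet <- if (kind == "rna") RNA_ALPHABET else PROTEIN_ALPHABET
  probs <- tilt_probs(alphabet, tilt, scale)
  prefix <- prefix %||% substr(kind, 1, 1)
  with_seed(seed, {
    len_choices <- seq(length_range[1], length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n,
                                   replace = TRUE)]
    seqs <- vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    rpi_seqs(stats::setNames(seqs, sprintf("%s%04d", prefix, seq_len(n))),
             kind = kind)
  })
}

tilt_probs <- function(alphabet, tilt, scale) {
  if (tilt == 0 || is.null(scale)) return(rep(1, length(alphabet)))
  v <- unclass(scale)[alphabet]
  z <- (v - mean(v)) / stats::sd(v)
  p <- exp(tilt * z)
  p / sum(p)
}

#' Build a toy complex with known geometry
#'
#' Places every chain's pseudo-atoms on a shared y-grid (one atom per
#' residue, `spacing` Angstrom apart) at a caller-chosen (x, z) offset, so
#' the least atom distance between any two chains is exactly the Euclidean
#' distance between their offsets and every expected interactivity label
#' is known by construction. Deterministic (a pure function of its spec).
#'
#' @param chains list of chain specs: `list(chain_id =, kind =, sequence =,
#'   pos = c(x, z))`.
#' @param id complex identifier.
#' @param spacing per-residue atom spacing along y.
#' @return A `complex_record` (serialize with [write_pdb()]).
#' @export
toy_complex <- function(chains, id = "TOY", spacing = 10) {
  stopifnot(length(chains) >= 1)
  rec <- lapply(chains, function(ch) {
    stopifnot(!is.null(ch$chain_id), !is.null(ch$kind),
              !is.null(ch$sequence), length(ch$pos) == 2L)
    L <- nchar(ch$sequence)
    atoms <- cbind(x = rep(ch$pos[1], L), y = spacing * (seq_len(L) - 1L),
                   z = rep(ch$pos[2], L))
    rownames(atoms) <- rep(if (ch$kind == "protein") "C" else "P", L)
    list(chain_id = ch$chain_id, kind = ch$kind,
         sequence = normalize_residues(ch$sequence,
                                       if (ch$kind == "rna") "rna"
                                       else "protein"),
         atoms = atoms)
  })
  structure(list(id = id, chains = rec), class = "complex_record")
}

# Mean compressed-coefficient pattern of a constant unit profile, averaged
# over lengths uniform in len_range: the expected channel vector of an
# i.i.d. sequence is (mean propensity) * this pattern.
unit_compression_pattern <- function(len_range, n_terms) {
  Ls <- seq(len_range[1], len_range[2])
  cols <- vapply(Ls, function(L)
    as.numeric(compress_profile(rep(1, L), n_terms)), numeric(n_terms))
  if (n_terms == 1L) mean(cols) else rowMeans(matrix(cols, nrow = n_terms))
}

tilted_mean_value <- function(scale, tilt) {
  alphabet <- if (attr(scale, "alphabet") == "rna") RNA_ALPHABET
              else PROTEIN_ALPHABET
  v <- unclass(scale)[alphabet]
  sum(tilt_probs(alphabet, tilt, scale) * v)
}

# Compressed propensity vectors of a sequence collection (rows = seqs).
compress_collection <- function(seqs, scale, n_terms) {
  t(vapply(unclass(seqs), function(s)
    as.numeric(compress_profile(encode_propensity(s, scale), n_terms)),
    numeric(n_terms)))
}

row_kronecker <- function(P, R) {
  out <- matrix(0, nrow = nrow(P), ncol = ncol(P) * ncol(R))
  for (i in seq_len(nrow(P))) out[i, ] <- P[i, ] %x% R[i, ]
  out
}

ridged_solve <- function(S, b, ridge) {
  d <- length(b)
  lambda <- ridge * sum(diag(S)) / d
  as.numeric(solve(S + diag(lambda, d), b))
}

#' Planted-rule pair dataset
#'
#' Generates a labeled (protein, RNA) pair dataset whose labels follow a
#' hidden linear rule in the outer-product feature space of the
#' Grantham x RNA-hydrogen-bonding channel, realized at the sequence level:
#' positive-pair sequences are sampled with residue composition tilted up
#' the two propensity scales and negative pairs tilted down, with the tilt
#' strength calibrated so the class means are `separation` pooled standard
#' deviations apart along the planted direction. Labels are then assigned
#' by ranking the noisy projection `w . x + noise * sd * eps` and taking
#' the top half as interactive, so the class split is exactly even and the
#' labels follow the stated rule.
#'
#' The returned `hidden_direction` is the population ridged Fisher
#' direction of the generative model (analytic class means combined with a
#' large seeded covariance sample) -- i.e. the direction an ideal trainer
#' of the same model family should recover; see the methods vignette for
#' why the planted direction is defined this way.
#'
#' @param n_pairs total pairs (even, >= 4).
#' @param separation class-mean distance along the planted direction, in
#'   pooled-SD units.
#' @param noise relative noise level on the labeling projection.
#' @param seed RNG seed (required).
#' @param rna_len,protein_len sequence length ranges.
#' @param config [model_config()] (controls the compressed dimension).
#' @param scales scale set.
#' @return List with `pairs`, `rna`, `protein`, `hidden_direction` (length
#'   `n_terms^2`, unit norm, `NA` when `separation = 0`), `beta` (the
#'   calibrated tilt), and `separation_realized`.
#' @export
planted_pair_dataset <- function(n_pairs = 400L, separation = 4,
                                 noise = 0.1, seed,
                                 rna_len = c(50L, 120L),
                                 protein_len = c(60L, 180L),
                                 config = model_config(),
                                 scales = default_scales()) {
  if (n_pairs < 4L || n_pairs %% 2L != 0L)
    stop("n_pairs must be even and >= 4", call. = FALSE)
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (separation == 0 && noise == 0)
    stop("degenerate spec: separation 0 with noise 0 defines no labels",
         call. = FALSE)
  n_terms <- config$n_terms
  d <- n_terms^2
  half <- n_pairs %/% 2L
  p_scale <- scales$grantham
  r_scale <- scales$rna_hbond

  # Untilted covariance of the signal-channel pair feature, from a large
  # seeded reference sample (propensity channels only -- cheap).
  n_ref <- max(800L, 2L * n_pairs)
  ref_p <- compress_collection(
    random_sequences(n_ref, protein_len, "protein", seed = seed + 1L),
    p_scale, n_terms)
  ref_r <- compress_collection(
    random_sequences(n_ref, rna_len, "rna", seed = seed + 2L),
    r_scale, n_terms)
  Sigma <- stats::cov(row_kronecker(ref_p, ref_r))

  # Analytic class-mean difference as a function of the tilt beta: an
  # i.i.d. sequence's expected channel vector is its expected per-residue
  # value times a fixed length-averaged compression pattern.
  cbar_p <- unit_compression_pattern(protein_len, n_terms)
  cbar_r <- unit_compression_pattern(rna_len, n_terms)
  delta_fun <- function(beta) {
    mu <- function(t) (tilted_mean_value(p_scale, t) * cbar_p) %x%
                      (tilted_mean_value(r_scale, t) * cbar_r)
    mu(beta) - mu(-beta)
  }
  sep_fun <- function(beta) {
    if (beta == 0) return(0)
    delta <- delta_fun(beta)
    w <- ridged_solve(Sigma, delta, config$ridge)
    w <- w / sqrt(sum(w^2))
    sum(delta * w) / sqrt(max(as.numeric(t(w) %*% Sigma %*% w), 1e-300))
  }

  if (separation == 0) {
    beta <- 0
    w <- rep(NA_real_, d)
  } else {
    beta_max <- 4
    if (sep_fun(beta_max) < separation) {
      warning("requested separation ", separation,
              " unattainable; using maximal tilt", call. = FALSE)
      beta <- beta_max
    } else {
      beta <- stats::uniroot(function(b) sep_fun(b) - separation,
                             c(1e-4, beta_max), tol = 1e-6)$root
    }
    delta <- delta_fun(beta)
    w <- ridged_solve(Sigma, delta, config$ridge)
    w <- w / sqrt(sum(w^2))
  }

  # Two tilted groups of sequences (the intended classes), then labels by
  # the noisy-projection ranking for an exact even split.
  pos_p <- random_sequences(half, protein_len, "protein", seed = seed + 3L,
                            tilt = beta, scale = p_scale, prefix = "pp")
  pos_r <- random_sequences(half, rna_len, "rna", seed = seed + 4L,
                            tilt = beta, scale = r_scale, prefix = "pr")
  neg_p <- random_sequences(half, protein_len, "protein", seed = seed + 5L,
                            tilt = -beta, scale = p_scale, prefix = "np")
  neg_r <- random_sequences(half, rna_len, "rna", seed = seed + 6L,
                            tilt = -beta, scale = r_scale, prefix = "nr")
  protein <- rpi_seqs(c(unclass(pos_p), unclass(neg_p)), "protein")
  rna <- rpi_seqs(c(unclass(pos_r), unclass(neg_r)), "rna")

  if (separation == 0) {
    labels <- with_seed(seed + 7L,
                        sample(rep(c(TRUE, FALSE), each = half)))
    sep_real <- 0
  } else {
    X <- row_kronecker(compress_collection(protein, p_scale, n_terms),
                       compress_collection(rna, r_scale, n_terms))
    proj <- as.numeric(X %*% w)
    sd_w <- sqrt(max(as.numeric(t(w) %*% Sigma %*% w), 1e-300))
    noisy <- proj + noise * sd_w * with_seed(seed + 7L, rnorm(n_pairs))
    labels <- rank(noisy, ties.method = "first") > n_pairs - half
    m1 <- mean(proj[labels]); m2 <- mean(proj[!labels])
    pooled <- sqrt((stats::var(proj[labels]) +
                    stats::var(proj[!labels])) / 2)
    sep_real <- (m1 - m2) / pooled
  }

  pairs <- rpi_pairs(names(rna), names(protein),
                     ifelse(labels, "interactive", "non-interactive"),
                     provenance = rep("planted", n_pairs))
  list(pairs = pairs, rna = rna, protein = protein, hidden_direction = w,
       beta = beta, separation_requested = separation,
       separation_realized = sep_real)
}
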