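#' Outer-product pair feature
#'
#' Flattens the outer product of a protein channel vector `p` (length
#' \eqn{d_p}) and an RNA channel vector `r` (length \eqn{d_r}) into the
#' vector \eqn{x = (p_1 r_1, p_1 r_2, \dots, p_{d_p} r_{d_r})}, i.e.
#' `x[(a-1)*d_r + b] = p[a] * r[b]`. A bilinear score \eqn{p^T M r} is then
#' the inner product `k . x` with `k` the row-major flattening of `M`.
#'
#' @param p,r numeric channel vectors.
#' @return Numeric vector of length `length(p) * length(r)`.
#' @examples
#' pair_feature(c(1, 2), c(3, 4))  # 3 4 6 8
#' @export
pair_feature <- function(p, r) {
  if (length(p) < 1L || length(r) < 1L)
    stop("empty channel vector", call. = FALSE)
  as.numeric(p %x% r)  # Kronecker product = row-major outer flattening
}

#' Fisher discriminant direction (closed form)
#'
#' Returns the direction `k` maximizing the Fisher criterion
#' \deqn{J(k) = \frac{(m_1 - m_2)^2}{s_1^2 + s_2^2}}
#' of the projected data, where \eqn{m_i} are the projected class means and
#' \eqn{s_i^2} the projected within-class scatters. Computed in closed form
#' as \eqn{(S_W + \lambda I)^{-1}(m_1 - m_2)} with \eqn{S_W} the pooled
#' within-class scatter matrix and \eqn{\lambda = ridge \cdot
#' \mathrm{tr}(S_W)/d} a relative ridge; a pseudo-inverse is used if the
#' ridged system is still singular. The direction is oriented so the first
#' (positive) class projects higher; its scale is irrelevant downstream.
#'
#' @param positives,negatives numeric matrices, one row per observation.
#' @param ridge relative ridge coefficient (0 disables regularization).
#' @return List with `k`, class means `m1`, `m2`, projected scatters `s1sq`,
#'   `s2sq`, criterion value `J` and class sizes.
#' @export
fisher_direction <- function(positives, negatives, ridge = 1) {
  positives <- as_matrix_rows(positives)
  negatives <- as_matrix_rows(negatives)
  if (nrow(positives) == 0L || nrow(negatives) == 0L)
    stop("both classes must be nonempty", call. = FALSE)
  if (ncol(positives) != ncol(negatives))
    stop("class feature dimensions differ", call. = FALSE)
  d <- ncol(positives)
  m1 <- colMeans(positives)
  m2 <- colMeans(negatives)
  diff <- m1 - m2
  scale_ref <- max(1, sqrt(sum(m1^2)), sqrt(sum(m2^2)))
  if (sqrt(sum(diff^2)) <= 1e-12 * scale_ref)
    stop("degenerate training data: identical class means", call. = FALSE)
  S_W <- crossprod(sweep(positives, 2L, m1)) +
         crossprod(sweep(negatives, 2L, m2))
  lambda <- if (ridge > 0) ridge * sum(diag(S_W)) / d else 0
  if (lambda == 0 && ridge > 0) lambda <- ridge  # all-zero scatter
  A <- S_W + diag(lambda, d)
  k <- tryCatch(as.numeric(solve(A, diff)),
                error = function(e) as.numeric(pseudo_solve(A, diff)))
  if (sum(k * diff) < 0) k <- -k  # orient: positive class scores higher
  p1 <- as.numeric(positives %*% k)
  p2 <- as.numeric(negatives %*% k)
  s1sq <- sum((p1 - mean(p1))^2)
  s2sq <- sum((p2 - mean(p2))^2)
  J <- if (s1sq + s2sq > 0) (mean(p1) - mean(p2))^2 / (s1sq + s2sq) else Inf
  list(k = k, m1 = m1, m2 = m2, s1sq = s1sq, s2sq = s2sq, J = J,
       n1 = nrow(positives), n2 = nrow(negatives), lambda = lambda)
}

pseudo_solve <- function(A, b, tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
}

as_matrix_rows <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L)
  else as.matrix(x)
}

# One trained channel: weight vector, class means in x-space, and the
# calibration constants c1 = k.m1, c2 = k.m2, c = (c1+c2)/2.
new_channel_model <- function(pairing, fit) {
  c1 <- sum(fit$k * fit$m1)
  c2 <- sum(fit$k * fit$m2)
  structure(list(pairing = pairing, k = fit$k, m1 = fit$m1, m2 = fit$m2,
                 c1 = c1, c2 = c2, c = (c1 + c2) / 2,
                 diagnostics = fit[c("s1sq", "s2sq", "J", "n1", "n2",
                                     "lambda")]),
            class = "rpi_channel")
}

#' Construct a channel model directly from a weight vector and class means
#'
#' Mostly useful for analytic checks and for replaying published
#' calibration constants; [train_model()] builds channels from data.
#'
#' @param k weight vector (row-major flattening of the bilinear matrix `M`).
#' @param m1,m2 class mean vectors in pair-feature space (interactive,
#'   non-interactive).
#' @param pairing channel pairing tag.
#' @return An `rpi_channel` object with calibration constants `c1 > c2`.
#' @export
channel_model <- function(k, m1, m2, pairing = "custom") {
  stopifnot(length(k) == length(m1), length(m1) == length(m2))
  fit <- list(k = as.numeric(k), m1 = as.numeric(m1), m2 = as.numeric(m2),
              s1sq = NA_real_, s2sq = NA_real_, J = NA_real_,
              n1 = NA_integer_, n2 = NA_integer_, lambda = NA_real_)
  ch <- new_channel_model(pairing, fit)
  if (!ch$c1 > ch$c2)
    stop("channel orientation violated: c1 must exceed c2", call. = FALSE)
  ch
}

#' Raw bilinear channel score
#'
#' `k . x`, identically \eqn{p^T M r} for `M` the row-major reshape of `k`.
#'
#' @param channel an `rpi_channel`.
#' @param x a pair feature vector (see [pair_feature()]).
#' @return A single number.
#' @export
raw_score <- function(channel, x) {
  if (length(x) != length(channel$k))
    stop("feature dimension ", length(x), " does not match channel weight ",
         "dimension ", length(channel$k), call. = FALSE)
  sum(channel$k * x)
}

#' Reshape a channel weight vector into its bilinear matrix
#'
#' @param channel an `rpi_channel`.
#' @param d_p,d_r protein/RNA channel dimensions.
#' @return The matrix `M` with `p %*% M %*% r == raw_score(channel,
#'   pair_feature(p, r))`.
#' @export
channel_matrix <- function(channel, d_p, d_r) {
  stopifnot(d_p * d_r == length(channel$k))
  matrix(channel$k, nrow = d_p, ncol = d_r, byrow = TRUE)
}

#' Calibrate a raw channel score into (0, 100)
#'
#' \deqn{Y = \frac{100}{\pi}\arctan\!\Big(\frac{2(X - c)}{c_1 - c_2}\Big) +
#' 50} with \eqn{c_1 = k \cdot m_1}, \eqn{c_2 = k \cdot m_2} and \eqn{c}
#' their midpoint. Strictly increasing, maps the real line onto the open
#' interval (0, 100); a raw score at the class midpoint gives exactly 50,
#' at the interactive-class mean 75, at the non-interactive-class mean 25.
#'
#' @param channel an `rpi_channel`.
#' @param X raw score(s).
#' @return Calibrated score(s) in (0, 100).
#' @export
transform_score <- function(channel, X) {
  if (!is.finite(channel$c1 - channel$c2) || channel$c1 == channel$c2)
    stop("calibration undefined: c1 == c2", call. = FALSE)
  (100 / pi) * atan(2 * (X - channel$c) / (channel$c1 - channel$c2)) + 50
}

#' Model configuration defaults
#'
#' @param n_struct number of RNA structures summed into the pairedness
#'   channel (default 6).
#' @param n_terms compressed channel dimension (default 10).
#' @param ridge relative ridge for the Fisher fit (default 1, i.e. a
#'   shrinkage term of the size of the average scatter eigenvalue; see the
#'   methods vignette for why heavy shrinkage is the right regime for
#'   100-dimensional features fitted from a few hundred pairs).
#' @param fusion_weights weights of the five calibrated channel scores;
#'   default the arithmetic mean. The alternative weighting that emphasizes
#'   the structure channel (1/3, 1/6, 1/6, 1/6, 1/6) can be set here.
#' @param threshold classification cutoff on the final score (default 50;
#'   a pair is called interactive only when its score is strictly over the
#'   threshold).
#' @param min_loop,max_rna_len,long_rna built-in folder parameters (see
#'   [rna_folder_nussinov()]).
#' @return A named list.
#' @export
model_config <- function(n_struct = 6L, n_terms = 10L, ridge = 1,
                         fusion_weights = rep(1 / 5, 5), threshold = 50,
                         min_loop = 3L, max_rna_len = 4095L,
                         long_rna = c("error", "truncate")) {
  long_rna <- match.arg(long_rna)
  if (length(fusion_weights) != length(CHANNEL_PAIRINGS) ||
      any(fusion_weights < 0) ||
      abs(sum(fusion_weights) - 1) > 1e-8)
    stop("fusion_weights must be ", length(CHANNEL_PAIRINGS),
         " nonnegative values summing to 1", call. = FALSE)
  list(n_struct = as.integer(n_struct), n_terms = as.integer(n_terms),
       ridge = as.numeric(ridge),
       fusion_weights = as.numeric(fusion_weights),
       threshold = as.numeric(threshold), min_loop = as.integer(min_loop),
       max_rna_len = as.integer(max_rna_len), long_rna = long_rna)
}

default_backends <- function(config) {
  list(folder = rna_folder_nussinov(min_loop = config$min_loop,
                                    max_len = config$max_rna_len,
                                    policy = config$long_rna),
       predictor = protein_ss_choufasman())
}

#' Encode a labeled dataset into per-channel pair-feature matrices
#'
#' Encodes every distinct sequence once, then builds, for each of the five
#' channel pairings, the matrix whose rows are the outer-product features of
#' the listed pairs. This is the shared workhorse of [train_model()] and
#' [cross_validate()]; precomputing it lets resampling schemes refit without
#' re-encoding.
#'
#' @param pairs pair table ([rpi_pairs()]).
#' @param rna,protein [rpi_seqs()] collections resolving the pair ids.
#' @param config [model_config()].
#' @param scales scale set ([default_scales()]).
#' @param folder,predictor optional backend overrides.
#' @return List with `features` (named list of n_pairs x n_terms^2
#'   matrices), `labels` (logical, `TRUE` = interactive) and the encodings.
#' @export
encode_dataset <- function(pairs, rna, protein, config = model_config(),
                           scales = default_scales(), folder = NULL,
                           predictor = NULL) {
  pairs <- validate_pairs(pairs)
  resolve_pairs(pairs, rna, protein)
  backends <- default_backends(config)
  folder <- folder %||% backends$folder
  predictor <- predictor %||% backends$predictor
  rna_ids <- unique(pairs$rna_id)
  prot_ids <- unique(pairs$protein_id)
  rna_enc <- lapply(stats::setNames(rna_ids, rna_ids), function(id)
    encode_rna(unclass(rna)[[id]], folder = folder, scales = scales,
               n_struct = config$n_struct, n_terms = config$n_terms))
  prot_enc <- lapply(stats::setNames(prot_ids, prot_ids), function(id)
    encode_protein(unclass(protein)[[id]], predictor = predictor,
                   scales = scales, n_terms = config$n_terms))
  d <- config$n_terms^2
  features <- lapply(CHANNEL_PAIRINGS, function(pairing) {
    m <- matrix(0, nrow = nrow(pairs), ncol = d)
    for (i in seq_len(nrow(pairs))) {
      m[i, ] <- pair_feature(
        prot_enc[[pairs$protein_id[i]]][[pairing[["prot"]]]],
        rna_enc[[pairs$rna_id[i]]][[pairing[["rna"]]]])
    }
    m
  })
  list(features = features, labels = pairs$label == "interactive",
       rna_encodings = rna_enc, protein_encodings = prot_enc)
}

fit_channels <- function(features, labels, config) {
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 pairs per class to train", call. = FALSE)
  channels <- vector("list", length(CHANNEL_PAIRINGS))
  names(channels) <- names(CHANNEL_PAIRINGS)
  for (nm in names(CHANNEL_PAIRINGS)) {
    fit <- tryCatch(
      fisher_direction(features[[nm]][labels, , drop = FALSE],
                       features[[nm]][!labels, , drop = FALSE],
                       ridge = config$ridge),
      error = function(e)
        stop("training failed on channel '", nm, "': ",
             conditionMessage(e), call. = FALSE))
    channels[[nm]] <- new_channel_model(nm, fit)
  }
  channels
}

#' Train the five-channel interaction model
#'
#' For each of the five channel pairings the labeled pairs are encoded into
#' 100-dimensional outer-product features, a Fisher discriminant direction
#' is fitted in closed form, and the calibration constants `c1 > c2`, `c`
#' are fixed from the training-class means. Training is deterministic: the
#' same data give a bit-identical model.
#'
#' @inheritParams encode_dataset
#' @param encoded optional precomputed [encode_dataset()] result.
#' @return An `rpi_model` with exactly five channels, the fusion weights
#'   and a config snapshot (including the scale tables) making the model
#'   self-contained.
#' @export
train_model <- function(pairs, rna, protein, config = model_config(),
                        scales = default_scales(), folder = NULL,
                        predictor = NULL, encoded = NULL) {
  if (is.null(encoded))
    encoded <- encode_dataset(pairs, rna, protein, config, scales,
                              folder, predictor)
  channels <- fit_channels(encoded$features, encoded$labels, config)
  structure(list(version = 1L, channels = channels, config = config,
                 scales = scales),
            class = "rpi_model")
}

#' @export
print.rpi_model <- function(x, ...) {
  cat("<rpi_model> five-channel RNA-protein interaction scorer\n")
  cat(sprintf("  dim %d x %d, %d structures, ridge %g, threshold %g\n",
              x$config$n_terms, x$config$n_terms, x$config$n_struct,
              x$config$ridge, x$config$threshold))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-16s c1 = %.4g, c2 = %.4g, J = %.4g\n", nm, ch$c1,
                ch$c2, ch$diagnostics$J))
  }
  invisible(x)
}

fuse_scores <- function(Y, weights) {
  stopifnot(length(Y) == length(weights))
  sum(weights * Y)
}

#' Score one RNA-protein pair
#'
#' Encodes both sequences, scores the five channel pairings with the trained
#' bilinear forms, calibrates each raw score into (0, 100) and fuses them
#' with the model's weights (arithmetic mean by default). The pair is
#' predicted interactive only when the final score is strictly over the
#' threshold; a score of exactly 50 is non-interactive.
#'
#' @param model an `rpi_model`.
#' @param rna,protein single sequences (strings or 1-element [rpi_seqs()]).
#' @param folder,predictor optional backend overrides (defaults rebuilt
#'   from the model's config snapshot).
#' @return A list with `raw` and `calibrated` per-channel scores, `final`
#'   in (0, 100) and `predicted` label.
#' @export
score_pair <- function(model, rna, protein, folder = NULL,
                       predictor = NULL) {
  stopifnot(inherits(model, "rpi_model"))
  cfg <- model$config
  backends <- default_backends(cfg)
  folder <- folder %||% backends$folder
  predictor <- predictor %||% backends$predictor
  r_enc <- encode_rna(rna, folder = folder, scales = model$scales,
                      n_struct = cfg$n_struct, n_terms = cfg$n_terms)
  p_enc <- encode_protein(protein, predictor = predictor,
                          scales = model$scales, n_terms = cfg$n_terms)
  raw <- numeric(length(model$channels))
  names(raw) <- names(model$channels)
  for (nm in names(model$channels)) {
    pairing <- CHANNEL_PAIRINGS[[nm]]
    x <- pair_feature(p_enc[[pairing[["prot"]]]], r_enc[[pairing[["rna"]]]])
    raw[nm] <- raw_score(model$channels[[nm]], x)
  }
  Y <- vapply(names(raw),
              function(nm) transform_score(model$channels[[nm]], raw[nm]),
              numeric(1))
  final <- fuse_scores(Y, cfg$fusion_weights)
  list(raw = raw, calibrated = Y, final = final,
       predicted = if (final > cfg$threshold) "interactive"
                   else "non-interactive")
}

#' Score every pair in a table
#'
#' @param model an `rpi_model`.
#' @param pairs pair table; the `label` column, if any, is carried through.
#' @param rna,protein sequence collections.
#' @param encoded optional precomputed [encode_dataset()] result for these
#'   pairs.
#' @return A data frame with per-channel calibrated scores, the final score
#'   and the predicted label, one row per pair.
#' @export
score_pairs <- function(model, pairs, rna, protein, encoded = NULL) {
  stopifnot(inherits(model, "rpi_model"))
  if (is.null(encoded))
    encoded <- encode_dataset(pairs, rna, protein, model$config,
                              model$scales)
  score_features(model, encoded$features, pairs)
}

# Score precomputed per-channel feature matrices (rows = pairs).
score_features <- function(model, features, pairs = NULL) {
  cfg <- model$config
  n <- nrow(features[[1L]])
  Y <- matrix(0, nrow = n, ncol = length(model$channels),
              dimnames = list(NULL, names(model$channels)))
  for (nm in names(model$channels)) {
    raws <- as.numeric(features[[nm]] %*% model$channels[[nm]]$k)
    Y[, nm] <- transform_score(model$channels[[nm]], raws)
  }
  final <- as.numeric(Y %*% cfg$fusion_weights)
  out <- data.frame(Y, final = final,
                    predicted = ifelse(final > cfg$threshold, "interactive",
                                       "non-interactive"),
                    stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    out <- cbind(pairs[c("rna_id", "protein_id",
                         intersect("label", names(pairs)))], out)
  }
  out
}

#' Save / load a trained model
#'
#' The archive is a single self-describing JSON file embedding the config,
#' the propensity tables and every per-channel array at full floating-point
#' precision, so `load_model(save_model(m, f))` scores any pair identically
#' to `m`.
#'
#' @param model an `rpi_model`.
#' @param path archive path.
#' @return `path` invisibly (`save_model`); an `rpi_model` (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rpi_model"))
  ser_scale <- function(s) list(values = as.list(unclass(s)),
                                name = attr(s, "scale_name"),
                                alphabet = attr(s, "alphabet"),
                                source = attr(s, "source"))
  payload <- list(
    format = "rpiscore-model", version = model$version,
    config = model$config,
    scales = c(lapply(model$scales[setdiff(names(model$scales),
                                           "chou_fasman")], ser_scale),
               list(chou_fasman = lapply(model$scales$chou_fasman,
                                         ser_scale))),
    channels = lapply(model$channels, function(ch)
      list(pairing = ch$pairing, k = ch$k, m1 = ch$m1, m2 = ch$m2,
           c1 = ch$c1, c2 = ch$c2, c = ch$c, diagnostics = ch$diagnostics))
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path,
                               call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop("corrupted model file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(payload$format, "rpiscore-model") ||
      !identical(as.integer(payload$version), 1L))
    stop("unsupported model file version in '", path, "'", call. = FALSE)
  de_scale <- function(s)
    propensity_scale(unlist(s$values), name = s$name,
                     alphabet = s$alphabet, source = s$source %||% "")
  scales <- lapply(payload$scales[setdiff(names(payload$scales),
                                          "chou_fasman")], de_scale)
  scales$chou_fasman <- lapply(payload$scales$chou_fasman, de_scale)
  cfg <- payload$config
  config <- model_config(n_struct = cfg$n_struct, n_terms = cfg$n_terms,
                         ridge = cfg$ridge,
                         fusion_weights = cfg$fusion_weights,
                         threshold = cfg$threshold, min_loop = cfg$min_loop,
                         max_rna_len = cfg$max_rna_len,
                         long_rna = cfg$long_rna)
  channels <- lapply(payload$channels, function(ch) {
    obj <- list(pairing = ch$pairing, k = as.numeric(ch$k),
                m1 = as.numeric(ch$m1), m2 = as.numeric(ch$m2),
                c1 = ch$c1, c2 = ch$c2, c = ch$c,
                diagnostics = as.list(ch$diagnostics))
    class(obj) <- "rpi_channel"
    obj
  })
  structure(list(version = 1L, channels = channels, config = config,
                 scales = scales),
            class = "rpi_model")
}
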