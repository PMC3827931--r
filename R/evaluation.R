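#' Discriminative power of a score set
#'
#' For interactive scores \eqn{\pi_i} and non-interactive scores
#' \eqn{\pi_n},
#' \deqn{DP = \frac{\sum_i\sum_n \theta(\pi_i-\pi_n)}
#'  {\sum_i\sum_n \theta(\pi_i-\pi_n) + \sum_i\sum_n \theta(\pi_n-\pi_i)}}
#' with \eqn{\theta(x) = 1} for \eqn{x \ge 0} and 0 otherwise. DP is 1 when
#' every interactive pair outscores every non-interactive pair, 0 in the
#' fully inverted case. Note the tie convention: \eqn{\theta(0) = 1} makes a
#' tied comparison count in *both* sums, so DP differs from a rank-based
#' AUC (which splits ties); an all-tied score set gives exactly 0.5, and
#' any strictly increasing transform of the scores leaves DP unchanged.
#'
#' Implemented via sorting in O(n log n); agrees with the quadratic
#' double-loop definition exactly.
#'
#' @param pos_scores,neg_scores numeric score vectors (both nonempty).
#' @return DP in `[0, 1]`.
#' @export
discriminative_power <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L)
    stop("both score sets must be nonempty", call. = FALSE)
  if (any(!is.finite(pos_scores)) || any(!is.finite(neg_scores)))
    stop("scores must be finite", call. = FALSE)
  sneg <- sort(neg_scores)
  n_neg <- length(sneg)
  # per positive score: #neg <= score and #neg < score
  le <- findInterval(pos_scores, sneg)                  # neg <= pos
  lt <- findInterval(pos_scores, sneg, left.open = TRUE) # neg <  pos
  forward <- sum(le)                       # theta(pos - neg) = [neg <= pos]
  backward <- sum(n_neg - lt)              # theta(neg - pos) = [neg >= pos]
  forward / (forward + backward)
}

#' Confusion counts
#'
#' 2x2 cross-tabulation of truth against prediction with `interactive` as
#' the positive class.
#'
#' @param truth,predicted character vectors over
#'   `{interactive, non-interactive}`; equal length.
#' @return Named list `TP`, `FP`, `TN`, `FN`; the four counts sum to the
#'   number of pairs.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  ok <- c(truth, predicted) %in% PAIR_LABELS
  if (!all(ok)) stop("labels must be interactive/non-interactive",
                     call. = FALSE)
  t_pos <- truth == "interactive"
  p_pos <- predicted == "interactive"
  list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
       TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos))
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#' {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the standard convention that a zero factor in the denominator gives
#' MCC = 0. Swapping all predicted labels maps the counts
#' `(TP,FP,TN,FN) -> (FN,TN,FP,TP)` and negates the MCC.
#'
#' @param counts confusion counts as from [confusion_counts()].
#' @return MCC in `[-1, 1]`.
#' @export
matthews_mcc <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (denom == 0) return(0)
  (TP * TN - FP * FN) / sqrt(denom)
}

#' Classification accuracy
#'
#' @param counts confusion counts.
#' @return `(TP + TN) / total`; an empty count set is an error.
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0) stop("no evaluated pairs", call. = FALSE)
  (counts$TP + counts$TN) / total
}

#' Stratified k-fold cross-validation
#'
#' Pairs are split into `k` folds stratified by label with a seeded
#' assignment; for each fold a model is trained on the remaining folds and
#' the held-out pairs are scored. The reported DP is the mean of the
#' per-fold DP values; MCC and accuracy are computed on the pooled held-out
#' predictions at the model threshold. Sequences are encoded once and
#' shared across folds.
#'
#' @param pairs pair table.
#' @param rna,protein sequence collections.
#' @param k number of folds (default 4).
#' @param seed RNG seed for the fold assignment (required).
#' @param config [model_config()].
#' @param scales scale set.
#' @param encoded optional precomputed [encode_dataset()] result; when
#'   supplied (e.g. for label-permutation nulls) the sequences are not
#'   re-encoded.
#' @return List with `dp` (mean over folds), `mcc`, `accuracy`, `counts`,
#'   and a per-fold data frame `folds`.
#' @export
cross_validate <- function(pairs, rna = NULL, protein = NULL, k = 4L,
                           seed, config = model_config(),
                           scales = default_scales(), encoded = NULL) {
  pairs <- validate_pairs(pairs)
  if (is.null(encoded))
    encoded <- encode_dataset(pairs, rna, protein, config, scales)
  labels <- encoded$labels
  if (sum(labels) < k || sum(!labels) < k)
    stop("each class needs at least k = ", k, " members", call. = FALSE)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  per_fold <- data.frame(fold = seq_len(k), dp = NA_real_, n = NA_integer_)
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  for (f in seq_len(k)) {
    test <- fold == f
    train_feat <- lapply(encoded$features,
                         function(m) m[!test, , drop = FALSE])
    test_feat <- lapply(encoded$features,
                        function(m) m[test, , drop = FALSE])
    channels <- fit_channels(train_feat, labels[!test], config)
    model <- structure(list(version = 1L, channels = channels,
                            config = config, scales = scales),
                       class = "rpi_model")
    sc <- score_features(model, test_feat)
    per_fold$dp[f] <- discriminative_power(sc$final[labels[test]],
                                           sc$final[!labels[test]])
    per_fold$n[f] <- sum(test)
    pooled_truth <- c(pooled_truth, ifelse(labels[test], "interactive",
                                           "non-interactive"))
    pooled_pred <- c(pooled_pred, sc$predicted)
  }
  counts <- confusion_counts(pooled_truth, pooled_pred)
  list(dp = mean(per_fold$dp), mcc = matthews_mcc(counts),
       accuracy = accuracy(counts), counts = counts, folds = per_fold)
}
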