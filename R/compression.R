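#' Compress a per-residue profile to fixed-length cosine-series terms
#'
#' Maps a length-`L` numeric profile \eqn{X_0 \dots X_{L-1}} to its first
#' `n_terms` cosine-series coefficients
#' \deqn{X'_k = \frac{2}{L} \sum_{n=0}^{L-1} X_n
#'       \cos\!\Big(\frac{\pi}{L}\big(n+\tfrac12\big)\big(k+\tfrac12\big)\Big),
#'       \quad k = 0, \dots, n_{terms}-1,}
#' the (scaled) type-IV discrete cosine transform. This unifies the
#' dimension of per-residue channels across sequences of different lengths
#' so a fixed bilinear form can score any pair. No normalization beyond the
#' printed `2/L` factor is applied, and profiles shorter than `n_terms` are
#' allowed (the sum is well defined for any `L >= 1`; there is no
#' zero-padding).
#'
#' @param profile numeric vector (a per-residue channel profile); a
#'   `channel` attribute, if present, is propagated.
#' @param n_terms number of leading coefficients to keep (default 10).
#' @return Numeric vector of length `n_terms` with attribute `channel`.
#' @examples
#' compress_profile(c(1, 0, 0), n_terms = 1)  # (2/3) * cos(pi/12)
#' @export
compress_profile <- function(profile, n_terms = 10L) {
  L <- length(profile)
  if (L < 1L) stop("empty profile", call. = FALSE)
  if (n_terms < 1L) stop("n_terms must be >= 1", call. = FALSE)
  if (any(!is.finite(profile)))
    stop("profile contains non-finite values", call. = FALSE)
  k <- seq_len(n_terms) - 1L
  n <- seq_len(L) - 1L
  # n_terms x L cosine matrix; profiles are short so no FFT path is needed
  C <- cos((pi / L) * outer(k + 0.5, n + 0.5))
  out <- as.numeric((2 / L) * (C %*% as.numeric(profile)))
  attr(out, "channel") <- attr(profile, "channel")
  out
}
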