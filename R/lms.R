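# LMS (lambda-mu-sigma) growth-reference transforms.
#
# A reference distribution at a given age is summarised by a Box-Cox power L,
# a median M and a coefficient of variation S.  The z-score of a raw
# measurement x is ((x/M)^L - 1) / (L * S), with the continuous limit
# log(x/M) / S as L -> 0.

.lms_l_eps <- 1e-7

#' Convert a raw measurement to an LMS z-score
#'
#' @param x Raw measurement (cm or g); must be positive.
#' @param L Box-Cox power of the reference at this age.
#' @param M Reference median; must be positive.
#' @param S Reference coefficient of variation; must be positive.
#' @return Numeric vector of z-scores.  Arguments are recycled to a common
#'   length; `NA` measurements give `NA` z-scores.
#' @seealso [lms_inverse()] for the inverse transform.
#' @examples
#' lms_zscore(3360, L = 1, M = 3000, S = 0.12) # (x - M) / (M * S) = 1
#' @export
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(as.numeric(x), n)
  L <- rep_len(as.numeric(L), n)
  M <- rep_len(as.numeric(M), n)
  S <- rep_len(as.numeric(S), n)
  if (any(x <= 0, na.rm = TRUE))
    stop_data("lms_zscore(): measurements must be strictly positive")
  if (any(M <= 0, na.rm = TRUE) || any(S <= 0, na.rm = TRUE))
    stop_data("lms_zscore(): M and S must be strictly positive")
  z <- rep(NA_real_, n)
  ok <- !is.na(x) & !is.na(L) & !is.na(M) & !is.na(S)
  lg <- ok & abs(L) < .lms_l_eps
  pw <- ok & !lg
  z[lg] <- log(x[lg] / M[lg]) / S[lg]
  z[pw] <- ((x[pw] / M[pw])^L[pw] - 1) / (L[pw] * S[pw])
  z
}

#' Convert an LMS z-score back to a raw measurement
#'
#' Inverse of [lms_zscore()]: x = M * (1 + L * S * z)^(1/L), or M * exp(S * z)
#' when L is (numerically) zero.  Used by the synthetic-cohort generator to
#' map latent z-scores onto raw lengths and weights.
#'
#' @inheritParams lms_zscore
#' @param z Z-score to invert.
#' @return Raw measurement on the scale of `M`.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(as.numeric(z), n)
  L <- rep_len(as.numeric(L), n)
  M <- rep_len(as.numeric(M), n)
  S <- rep_len(as.numeric(S), n)
  if (any(M <= 0, na.rm = TRUE) || any(S <= 0, na.rm = TRUE))
    stop_data("lms_inverse(): M and S must be strictly positive")
  base <- 1 + L * S * z
  pw <- abs(L) >= .lms_l_eps
  if (any(base[pw] <= 0, na.rm = TRUE))
    stop_data("lms_inverse(): z outside the invertible range (1 + L*S*z <= 0)")
  x <- rep(NA_real_, n)
  ok <- !is.na(z) & !is.na(L) & !is.na(M) & !is.na(S)
  lg <- ok & !pw
  x[lg] <- M[lg] * exp(S[lg] * z[lg])
  i <- ok & pw
  x[i] <- M[i] * base[i]^(1 / L[i])
  x
}
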