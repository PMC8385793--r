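# Conditional growth variables.
#
# The exposure of interest is growth in an interval, not size itself.
# Regressing the current size z-score on all previous sizes and taking the
# residual yields a variable that is, by construction, uncorrelated with
# everything that came before: 'conditional length' isolates linear growth
# in the interval, and 'conditional relative weight' (current weight
# residualised on current length as well) isolates weight gain net of
# linear growth.  Birth length and weight z-scores act as the conditional
# variables at birth, having nothing previous to condition on.  Residuals
# are standardised to unit variance so downstream relative risks are per
# 1 SD.

# OLS residuals (with intercept) divided by their standard deviation.
.std_residuals <- function(y, X, label = "conditional variable") {
  X <- as.matrix(X)
  n <- length(y)
  if (anyNA(y) || anyNA(X))
    stop_estimation("%s: missing values in the estimation sample", label)
  p <- ncol(X) + 1L
  if (n <= p)
    stop_estimation("%s: estimation sample (%d rows) too small for %d regressors",
                    label, n, ncol(X))
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < p)
    stop_estimation("%s: rank-deficient design (rank %d < %d); a regressor is constant or collinear",
                    label, qrD$rank, p)
  r <- qr.resid(qrD, y)
  s <- stats::sd(r)
  if (s < 1e-10) {
    warning(sprintf("%s: residuals are numerically zero (perfect fit); returning unstandardised residuals", label))
    return(r)
  }
  r / s
}

#' Conditional length
#'
#' Standardised residual of the current length z-score regressed on all
#' previous length and weight z-scores.  Positive values mean faster
#' linear growth than predicted from earlier size.
#'
#' @param current_length_z Numeric vector of current length z-scores.
#' @param previous Data frame or matrix of all earlier length and weight
#'   z-scores (one column each).
#' @return Standardised residuals (mean 0, SD 1 in the estimation sample).
#' @export
conditional_length <- function(current_length_z, previous) {
  .std_residuals(current_length_z, previous, "conditional_length")
}

#' Conditional relative weight
#'
#' Standardised residual of the current weight z-score regressed on the
#' current length z-score plus all earlier sizes: weight gain net of
#' concurrent linear growth.
#'
#' @param current_weight_z Numeric vector of current weight z-scores.
#' @param current_length_z Current length z-scores, entered as a regressor.
#' @param previous Data frame or matrix of all earlier length and weight
#'   z-scores.
#' @return Standardised residuals.
#' @export
conditional_relative_weight <- function(current_weight_z, current_length_z,
                                        previous) {
  .std_residuals(current_weight_z,
                 cbind(current_length = current_length_z, as.matrix(previous)),
                 "conditional_relative_weight")
}

# Timepoints entering each model variant. Variant 0 (birth + 4 months) is
# the exposure set of the 6-month outcome models; variants 1-3 are the
# 12-month model variants defined by data availability.  Variant 3 skips
# the 7-month timepoint entirely, so its 10-month conditionals condition on
# birth and 4 months only.
variant_timepoints <- function(variant) {
  switch(as.character(variant),
         "0" = c("birth", "4m"),
         "1" = c("birth", "4m", "7m", "10m"),
         "2" = c("birth", "4m", "7m"),
         "3" = c("birth", "4m", "10m"),
         stop_config("unknown model variant '%s' (expected 0, 1, 2 or 3)",
                     variant))
}

#' Conditional-variable names for a model variant
#'
#' @param variant Model variant: 0 (birth + 4 m; 6-month models),
#'   1 (birth/4/7/10 m), 2 (birth/4/7 m) or 3 (birth/4/10 m).
#' @return Character vector of exposure names.
#' @export
exposures_for_variant <- function(variant) {
  tp <- variant_timepoints(variant)
  c("length0", "weight0",
    unlist(lapply(setdiff(tp, "birth"), function(t)
      paste0(c("cLength", "crWeight"), sub("m$", "", t)))))
}

#' Build the conditional growth variables for a cohort
#'
#' Fits the sequential residualisations on the complete-case sample of a
#' model variant, separately within each sex stratum, and returns the
#' standardised conditional variables per child.  Birth z-scores are
#' centred and scaled within the same sample so that every exposure is on
#' a per-1-SD scale.
#'
#' @param zscores Tibble from [zscore_anthro()] (`child_id`, `sex`, `z_*`).
#' @param variant Model variant (see [exposures_for_variant()]).
#' @param sex Optional single sex (`"boy"`/`"girl"`) to restrict to; by
#'   default each sex present is fitted and the results stacked.
#' @return Tibble `child_id`, `sex`, `variant`, plus the variant's
#'   conditional-variable columns.
#' @export
build_conditional_set <- function(zscores, variant, sex = NULL) {
  tp <- variant_timepoints(variant)
  need <- as.vector(outer(c("z_length_", "z_weight_"), tp, paste0))
  miss <- setdiff(need, names(zscores))
  if (length(miss))
    stop_data("zscores lack column(s): %s", paste(miss, collapse = ", "))
  sexes <- if (is.null(sex)) unique(zscores$sex) else sex
  res <- lapply(sexes, function(sx) {
    d <- zscores[zscores$sex == sx, c("child_id", need)]
    d <- d[stats::complete.cases(d[need]), , drop = FALSE]
    if (nrow(d) == 0)
      stop_estimation("empty stratum: no complete cases for sex '%s', variant %s",
                      sx, variant)
    std <- function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s < 1e-10)
        stop_estimation("zero variance in birth z-scores for sex '%s'", sx)
      (x - mean(x)) / s
    }
    out <- tibble::tibble(child_id = d$child_id, sex = sx,
                          variant = as.integer(variant),
                          length0 = std(d$z_length_birth),
                          weight0 = std(d$z_weight_birth))
    prev <- c("z_length_birth", "z_weight_birth")
    for (t in setdiff(tp, "birth")) {
      suf <- sub("m$", "", t)
      lcol <- paste0("z_length_", t); wcol <- paste0("z_weight_", t)
      out[[paste0("cLength", suf)]] <-
        conditional_length(d[[lcol]], d[prev])
      out[[paste0("crWeight", suf)]] <-
        conditional_relative_weight(d[[wcol]], d[[lcol]], d[prev])
      prev <- c(prev, lcol, wcol)
    }
    out
  })
  dplyr::bind_rows(res)
}
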