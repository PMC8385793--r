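# Quasi-Poisson relative-risk regression.
#
# A log-link Poisson-family GLM on a binary outcome yields exponentiated
# coefficients that are relative risks; the quasi-likelihood dispersion
# (Pearson chi-square / residual df) rescales the standard errors, which
# for a binary outcome corrects the Poisson variance overstatement.  Point
# estimates equal the Poisson maximum likelihood ones; only confidence
# intervals are affected.

#' The fixed covariate set of the delay models
#'
#' Maternal age (years, linear), maternal smoking during pregnancy,
#' maternal and paternal education, annual family income, and home speech
#' stimulation at one month.
#'
#' @return Character vector of column names.
#' @export
delay_covariates <- function() {
  c("maternal_age", "maternal_smoking", "maternal_education",
    "paternal_education", "family_income", "home_speech_stimulation")
}

# Reference levels: lowest education, lowest income; logicals keep FALSE
# as reference.
.factor_levels <- list(
  maternal_education = c("junior_high", "high_school", "university_or_grad"),
  paternal_education = c("junior_high", "high_school", "university_or_grad"),
  family_income = c("low", "mid", "high"))

.prep_model_frame <- function(d) {
  for (cl in intersect(names(.factor_levels), names(d))) {
    f <- factor(d[[cl]], levels = .factor_levels[[cl]])
    if (anyNA(f) && !anyNA(d[[cl]]))
      stop_data("column '%s' has levels outside %s", cl,
                paste(.factor_levels[[cl]], collapse = "/"))
    present <- levels(f) %in% unique(as.character(f))
    if (!all(present)) {
      warning(sprintf("column '%s': dropping empty level(s) %s", cl,
                      paste(levels(f)[!present], collapse = ", ")))
      f <- droplevels(f)
    }
    d[[cl]] <- f
  }
  d
}

#' Fit a quasi-Poisson relative-risk model
#'
#' Complete cases on the outcome, exposures and covariates are used; the
#' fit is a log-link quasi-Poisson GLM, with 95 % Wald confidence
#' intervals exp(beta +/- 1.96 * SE), the SE carrying the sqrt(dispersion)
#' scaling.
#'
#' @param data Analysis tibble.
#' @param outcome Name of a 0/1 (or logical) outcome column.
#' @param exposures Character vector of exposure columns (per-1-SD
#'   conditional growth variables).
#' @param covariates Covariate columns; defaults to [delay_covariates()].
#'   Use `character(0)` for an unadjusted model.
#' @return Tibble with one row per model term (intercept excluded):
#'   `term`, `aRR`, `ci_low`, `ci_high`, `dispersion`, `n_used`, `events`.
#' @export
fit_rr_model <- function(data, outcome, exposures,
                         covariates = delay_covariates()) {
  vars <- c(outcome, exposures, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop_data("analysis table lacks column(s): %s", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  y <- d[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1)))
    stop_data("outcome '%s' must be binary 0/1", outcome)
  d[[outcome]] <- y
  if (nrow(d) <= length(vars))
    stop_estimation("too few complete cases (%d) to fit the model", nrow(d))
  d <- .prep_model_frame(d)
  f <- stats::reformulate(c(exposures, covariates), response = outcome)
  fit <- stats::glm(f, family = stats::quasipoisson(link = "log"), data = d,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop_estimation("quasi-Poisson IRLS did not converge in 100 iterations for outcome '%s'",
                    outcome)
  sm <- summary(fit)
  co <- sm$coefficients
  keep <- rownames(co) != "(Intercept)"
  est <- co[keep, "Estimate"]
  se <- co[keep, "Std. Error"]
  tibble::tibble(
    term = rownames(co)[keep],
    aRR = exp(est),
    ci_low = exp(est - 1.96 * se),
    ci_high = exp(est + 1.96 * se),
    dispersion = sm$dispersion,
    n_used = nrow(d),
    events = sum(y))
}

#' Fit the full grid of sex-stratified delay models
#'
#' Per sex: the 6-month models (exposures from birth and 4 months,
#' variant 0) and the 12-month models for variants 1 (birth/4/7/10 m),
#' 2 (birth/4/7 m) and 3 (birth/4/10 m), each for the any-domain outcome
#' and the five per-domain outcomes -- eight tables of six outcome columns,
#' mirroring the reporting layout of conditional-growth studies.
#'
#' @param cohort Cohort tibble carrying the covariate columns.
#' @param zscores Z-score tibble from [zscore_anthro()].
#' @param flags6,flags12 Delay-flag tibbles from [flag_delay()] at 6 and
#'   12 months.
#' @param covariates Covariate set (default [delay_covariates()]).
#' @return Tibble of stacked [fit_rr_model()] results with `sex`,
#'   `outcome_age`, `variant` and `outcome` identifier columns.
#' @export
run_delay_models <- function(cohort, zscores, flags6, flags12,
                             covariates = delay_covariates()) {
  outcomes <- c(total = "any_delay",
                stats::setNames(paste0("delayed_", asq_domains()),
                                asq_domains()))
  blocks <- list(list(outcome_age = 6, variant = 0, flags = flags6),
                 list(outcome_age = 12, variant = 1, flags = flags12),
                 list(outcome_age = 12, variant = 2, flags = flags12),
                 list(outcome_age = 12, variant = 3, flags = flags12))
  res <- list()
  for (sx in intersect(c("boy", "girl"), unique(cohort$sex))) {
    for (bl in blocks) {
      cs <- build_conditional_set(zscores, bl$variant, sex = sx)
      tab <- cs |>
        dplyr::inner_join(cohort[c("child_id", covariates)], by = "child_id") |>
        dplyr::left_join(bl$flags[c("child_id", unname(outcomes))],
                         by = "child_id")
      expo <- exposures_for_variant(bl$variant)
      for (oc in names(outcomes)) {
        r <- fit_rr_model(tab, outcomes[[oc]], expo, covariates)
        r$sex <- sx; r$outcome_age <- bl$outcome_age
        r$variant <- bl$variant; r$outcome <- oc
        res[[length(res) + 1]] <- r
      }
    }
  }
  dplyr::bind_rows(res) |>
    dplyr::relocate("sex", "outcome_age", "variant", "outcome")
}

#' Format relative risks as "aRR (low-high)" strings
#'
#' @param results Tibble from [fit_rr_model()] or [run_delay_models()].
#' @param digits Decimal places (2 matches the usual reporting style).
#' @return The input with a `formatted` column appended.
#' @export
format_rr <- function(results, digits = 2) {
  fmt <- sprintf("%%.%df (%%.%df-%%.%df)", digits, digits, digits)
  results$formatted <- sprintf(fmt, results$aRR, results$ci_low,
                               results$ci_high)
  results
}
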