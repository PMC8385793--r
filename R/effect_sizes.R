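# Balance diagnostics: chi-square based effect sizes for categorical
# variables and the point-biserial r from a Student's t-test for numeric
# ones, comparing children with and without complete anthropometry.

#' Phi coefficient from a 2x2 table
#'
#' phi = |ad - bc| / sqrt((a+b)(c+d)(a+c)(b+d)), identical to
#' sqrt(chi-square / n) for the uncorrected Pearson chi-square.
#'
#' @param a,b,c,d Cell counts (first row a, b; second row c, d).
#' @return Nonnegative phi in `[0, 1]`.
#' @examples
#' phi_from_2x2(5179, 4837, 21291, 12957) # ~0.09
#' @export
phi_from_2x2 <- function(a, b, c, d) {
  cnt <- as.numeric(c(a, b, c, d))
  if (any(cnt < 0) || anyNA(cnt))
    stop_data("phi_from_2x2(): counts must be nonnegative")
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0))
    stop_data("phi_from_2x2(): zero margin")
  abs(cnt[1] * cnt[4] - cnt[2] * cnt[3]) / sqrt(prod(as.numeric(m)))
}

#' Cramer's V from an r x c contingency table
#'
#' sqrt(chi-square / (n * min(r - 1, c - 1))) with the uncorrected Pearson
#' chi-square; reduces to [phi_from_2x2()] for 2x2 tables.
#'
#' @param tab Matrix of counts, at least 2x2.
#' @return Cramer's V in `[0, 1]`.
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_data("cramers_v(): table must be at least 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_data("cramers_v(): zero margin")
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  sqrt(as.numeric(chi2) / (sum(tab) * min(dim(tab) - 1)))
}

#' Point-biserial r from group summaries
#'
#' Pooled-variance Student's t between two groups, converted to an effect
#' size: r = sqrt(t^2 / (t^2 + df)), df = n1 + n2 - 2.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return Nonnegative r in `[0, 1]`.
#' @examples
#' r_from_summaries(3088, 371, 10016, 3117, 367, 34248) # ~0.03
#' @export
r_from_summaries <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2)
    stop_data("r_from_summaries(): both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0)
    stop_data("r_from_summaries(): negative SD")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0)
    stop_data("r_from_summaries(): zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  sqrt(t^2 / (t^2 + df))
}

# Variable -> (kind, accessor) used by balance_table(). Binary variables
# name the level counted in the 2x2's first column.
.balance_vars <- function() {
  list(
    gestational_age = list(kind = "r"),
    birth_length = list(kind = "r", col = "birth_length_cm"),
    birth_weight = list(kind = "r", col = "birth_weight_g"),
    multipara = list(kind = "phi", col = "parity", level = "multipara"),
    maternal_age = list(kind = "r"),
    maternal_smoking = list(kind = "phi", level = "TRUE"),
    maternal_education = list(kind = "cramers_v"),
    paternal_education = list(kind = "cramers_v"),
    family_income = list(kind = "cramers_v"),
    home_speech_stimulation = list(kind = "phi", level = "TRUE"),
    delay_6m = list(kind = "phi", col = "delay6", level = "TRUE"),
    delay_12m = list(kind = "phi", col = "delay12", level = "TRUE"))
}

#' Paper-style balance table with effect sizes
#'
#' Compares children with and without complete anthropometry at the three
#' postnatal target ages, per sex.  Missing values of a variable are
#' excluded from both groups (per-variable denominators); effect sizes are
#' reported rounded half-up to two decimals.
#'
#' @param cohort Cohort tibble; if columns `delay6` / `delay12` (logical)
#'   are present, delay rows are included.
#' @param complete Logical vector: complete-anthropometry flag per row
#'   (see [has_complete_anthro()]).
#' @return Tibble `sex`, `variable`, `kind`, `effect_size`, `n_with`,
#'   `n_without`, `missing_with`, `missing_without`.
#' @export
balance_table <- function(cohort, complete) {
  if (length(complete) != nrow(cohort))
    stop_data("balance_table(): 'complete' must align with the cohort rows")
  vars <- .balance_vars()
  rows <- list()
  for (sx in intersect(c("boy", "girl"), unique(cohort$sex))) {
    d <- cohort[cohort$sex == sx, , drop = FALSE]
    cf <- complete[cohort$sex == sx]
    for (vn in names(vars)) {
      spec <- vars[[vn]]
      col <- spec$col %||% vn
      if (!col %in% names(d)) next
      x <- d[[col]]
      if (is.logical(x)) x <- as.character(x)
      ok <- !is.na(x)
      x1 <- x[ok & cf]; x2 <- x[ok & !cf]
      if (length(x1) < 2 || length(x2) < 2) next
      es <- switch(spec$kind,
        r = r_from_summaries(mean(as.numeric(x1)), stats::sd(as.numeric(x1)),
                             length(x1),
                             mean(as.numeric(x2)), stats::sd(as.numeric(x2)),
                             length(x2)),
        phi = {
          a <- sum(x1 == spec$level); c2 <- sum(x2 == spec$level)
          phi_from_2x2(a, length(x1) - a, c2, length(x2) - c2)
        },
        cramers_v = {
          lev <- sort(unique(c(x1, x2)))
          cramers_v(rbind(table(factor(x1, levels = lev)),
                          table(factor(x2, levels = lev))))
        })
      rows[[length(rows) + 1]] <- tibble::tibble(
        sex = sx, variable = vn, kind = spec$kind,
        effect_size = round_half_up(es, 2),
        n_with = length(x1), n_without = length(x2),
        missing_with = sum(is.na(x[cf])), missing_without = sum(is.na(x[!cf])))
    }
  }
  dplyr::bind_rows(rows)
}
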