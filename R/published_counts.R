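# Published summary statistics used as worked-example inputs.
#
# The underlying individual-level cohort data (Japan Environment and
# Children's Study, term singleton births followed to 12 months) are not
# publicly available, but the published baseline table and participant
# flow provide group counts, means and SDs that the effect-size routines
# can be checked against exactly.  Only summary-level numbers are stored.

#' Published baseline summary statistics
#'
#' Baseline characteristics of children with versus without complete
#' anthropometry at 4, 7 and 10 months, per sex, as published for the JECS
#' term-singleton subcohort: group counts (categorical rows), means and
#' SDs (numeric rows), per-variable missing counts, and the published
#' two-decimal effect size.
#'
#' @return Tibble with columns `sex`, `variable`, `kind`
#'   (`phi`/`cramers_v`/`r`), `level`, `n_with`, `n_without` (level counts),
#'   `mean_with`, `sd_with`, `mean_without`, `sd_without` (numeric rows),
#'   `missing_with`, `missing_without`, `published`.  The group sizes are
#'   in `attr(x, "group_n")`.
#' @export
published_balance_summaries <- function() {
  num <- function(sex, variable, mw, sw, mwo, swo, misw, miswo, pub)
    tibble::tibble(sex = sex, variable = variable, kind = "r",
                   level = NA_character_, n_with = NA_real_,
                   n_without = NA_real_, mean_with = mw, sd_with = sw,
                   mean_without = mwo, sd_without = swo,
                   missing_with = misw, missing_without = miswo,
                   published = pub)
  bin <- function(sex, variable, nw, nwo, misw, miswo, pub)
    tibble::tibble(sex = sex, variable = variable, kind = "phi",
                   level = "yes", n_with = nw, n_without = nwo,
                   mean_with = NA_real_, sd_with = NA_real_,
                   mean_without = NA_real_, sd_without = NA_real_,
                   missing_with = misw, missing_without = miswo,
                   published = pub)
  cat3 <- function(sex, variable, lev, nw, nwo, misw, miswo, pub)
    tibble::tibble(sex = sex, variable = variable, kind = "cramers_v",
                   level = lev, n_with = nw, n_without = nwo,
                   mean_with = NA_real_, sd_with = NA_real_,
                   mean_without = NA_real_, sd_without = NA_real_,
                   missing_with = misw, missing_without = miswo,
                   published = pub)
  edu <- c("junior_high", "high_school", "university_or_grad")
  inc <- c("low", "mid", "high")
  out <- dplyr::bind_rows(
    num("boy", "gestational_age", 39.4, 1.1, 39.4, 1.1, 0, 0, 0.00),
    num("boy", "birth_length", 49.4, 2.0, 49.4, 1.9, 0, 0, 0.01),
    num("boy", "birth_weight", 3088, 371, 3117, 367, 0, 0, 0.03),
    bin("boy", "multipara", 5179, 21291, 0, 0, 0.09),
    num("boy", "maternal_age", 31.4, 4.8, 31.1, 5.1, 1, 4, 0.03),
    bin("boy", "maternal_smoking", 1435, 6418, 112, 948, 0.05),
    cat3("boy", "maternal_education", edu, c(321, 7233, 2379),
         c(1798, 24661, 6933), 83, 856, 0.05),
    cat3("boy", "paternal_education", edu, c(520, 5887, 3472),
         c(2619, 19713, 10843), 137, 1073, 0.04),
    cat3("boy", "family_income", inc, c(3428, 3162, 2703),
         c(12719, 10242, 8080), 723, 3207, 0.04),
    bin("boy", "home_speech_stimulation", 8115, 26998, 50, 950, 0.00),
    bin("boy", "delay_6m", 841, 2439, 599, 5636, 0.01),
    bin("boy", "delay_12m", 1576, 4253, 712, 7324, 0.01),
    num("girl", "gestational_age", 39.5, 1.1, 39.5, 1.1, 0, 0, 0.00),
    num("girl", "birth_length", 48.8, 1.9, 48.8, 1.9, 0, 0, 0.01),
    num("girl", "birth_weight", 2993, 356, 3021, 357, 0, 0, 0.03),
    bin("girl", "multipara", 5040, 20455, 0, 0, 0.09),
    num("girl", "maternal_age", 31.4, 4.9, 31.0, 5.1, 0, 1, 0.03),
    bin("girl", "maternal_smoking", 1429, 6167, 109, 891, 0.05),
    cat3("girl", "maternal_education", edu, c(282, 7082, 2349),
         c(1690, 23732, 6519), 88, 799, 0.06),
    cat3("girl", "paternal_education", edu, c(545, 5748, 3371),
         c(2527, 18882, 10321), 137, 1010, 0.04),
    cat3("girl", "family_income", inc, c(3453, 2998, 2663),
         c(12232, 9837, 7789), 687, 2882, 0.03),
    bin("girl", "home_speech_stimulation", 7916, 25879, 75, 901, 0.00),
    bin("girl", "delay_6m", 782, 2169, 595, 5215, 0.01),
    bin("girl", "delay_12m", 1221, 3247, 819, 6945, 0.01))
  attr(out, "group_n") <- c(boy_with = 10016, boy_without = 34248,
                            girl_with = 9801, girl_without = 32740)
  out
}

#' Published participant-flow and data-availability counts
#'
#' @return Tibble per sex: analyzed children and counts with
#'   anthropometry at 4, 7, 10 months and at all timepoints.  Overall flow
#'   counts (eligible, excluded for malformation/severe disease, analyzed)
#'   are in `attr(x, "flow")`.
#' @export
published_flow_counts <- function() {
  out <- tibble::tibble(
    sex = c("boy", "girl"),
    n_analyzed = c(44264, 42541),
    n_4m = c(37136, 35732),
    n_7m = c(16231, 15758),
    n_10m = c(25616, 24570),
    n_complete = c(10016, 9801))
  attr(out, "flow") <- c(eligible = 89953, excluded_malformation = 3148,
                         analyzed = 86805)
  out
}

#' Recompute published effect sizes from the summary counts
#'
#' Runs the package's effect-size routines on the published group counts
#' and summaries: the uncorrected chi-square phi / Cramer's V for
#' categorical rows and the pooled-variance point-biserial r for numeric
#' rows, each on the per-variable denominators implied by the missing
#' counts.
#'
#' @return The [published_balance_summaries()] tibble, one row per
#'   variable, with a `recomputed` column (rounded half-up to 2 decimals)
#'   alongside `published`.
#' @export
published_effect_sizes <- function() {
  tab <- published_balance_summaries()
  gn <- attr(tab, "group_n")
  res <- tab |>
    dplyr::group_by(.data$sex, .data$variable, .data$kind) |>
    dplyr::summarise(
      published = .data$published[1],
      recomputed = {
        N1 <- gn[paste0(.data$sex[1], "_with")] - .data$missing_with[1]
        N2 <- gn[paste0(.data$sex[1], "_without")] - .data$missing_without[1]
        v <- switch(.data$kind[1],
          r = r_from_summaries(.data$mean_with[1], .data$sd_with[1], N1,
                               .data$mean_without[1], .data$sd_without[1], N2),
          phi = phi_from_2x2(.data$n_with[1], N1 - .data$n_with[1],
                             .data$n_without[1], N2 - .data$n_without[1]),
          cramers_v = cramers_v(cbind(.data$n_with, .data$n_without)))
        unname(round_half_up(v, 2))
      },
      .groups = "drop")
  res
}
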