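# ASQ-3 scoring, normative cutoffs and delay flags.
#
# The Ages & Stages Questionnaires (3rd edition) screen five developmental
# domains -- Communication, Gross Motor, Fine Motor, Problem Solving and
# Personal-Social -- with six parent-reported items each.  Items score
# "yes" = 10, "sometimes" = 5, "not yet" = 0, so a domain score is a
# multiple of 5 in [0, 60].  A domain cutoff is two standard deviations
# below the mean of a large reference sample, and a child is flagged as
# having a neurodevelopmental delay when any domain score is at or below
# its cutoff.

.asq_points <- c(yes = 10, sometimes = 5, not_yet = 0)

#' ASQ-3 developmental domains
#' @return Character vector of the five domain names used in column names.
#' @export
asq_domains <- function() {
  c("communication", "gross_motor", "fine_motor", "problem_solving",
    "personal_social")
}

.check_tokens <- function(x) {
  bad <- !is.na(x) & !(x %in% names(.asq_points))
  if (any(bad))
    stop_data("unknown ASQ response token(s): %s (expected yes/sometimes/not_yet)",
              paste(unique(x[bad]), collapse = ", "))
}

#' Score one ASQ-3 domain
#'
#' @param responses Character vector of exactly six responses in
#'   `"yes"`, `"sometimes"`, `"not_yet"`; `NA` marks an unanswered item.
#' @param prorate If `FALSE` (default) a domain with any missing item is
#'   treated as absent (`NA`).  If `TRUE`, the instrument-manual style
#'   adjustment is applied: mean of the answered items times six.
#' @return Domain score (0-60), or `NA`.
#' @examples
#' score_domain(rep("yes", 6)) # 60
#' @export
score_domain <- function(responses, prorate = FALSE) {
  if (length(responses) != 6)
    stop_data("a domain has exactly six items (got %d)", length(responses))
  .check_tokens(responses)
  pts <- .asq_points[responses]
  n_ans <- sum(!is.na(pts))
  if (n_ans == 6) return(sum(pts))
  if (n_ans == 0) return(NA_real_)
  if (prorate) mean(pts, na.rm = TRUE) * 6 else NA_real_
}

#' Score ASQ-3 questionnaires across a cohort
#'
#' Expects item columns named `asq<age>_<domain>_i<1..6>`, e.g.
#' `asq6_gross_motor_i3`.
#'
#' @param cohort Cohort tibble.
#' @param outcome_age Outcome age in months (6 or 12).
#' @param prorate Passed to the missing-item rule of [score_domain()].
#' @return Long tibble `child_id`, `outcome_age`, `domain`, `points`,
#'   `n_answered`.
#' @export
score_asq <- function(cohort, outcome_age, prorate = FALSE) {
  stopifnot(outcome_age %in% c(6, 12))
  res <- lapply(asq_domains(), function(dm) {
    cols <- paste0("asq", outcome_age, "_", dm, "_i", 1:6)
    miss <- setdiff(cols, names(cohort))
    if (length(miss))
      stop_data("cohort lacks ASQ item column(s): %s",
                paste(miss, collapse = ", "))
    M <- as.matrix(cohort[cols])
    .check_tokens(M)
    P <- matrix(.asq_points[M], nrow = nrow(M))
    n_ans <- rowSums(!is.na(P))
    pts <- rowSums(P, na.rm = TRUE)
    pts[n_ans == 0] <- NA_real_
    if (prorate) {
      part <- n_ans > 0 & n_ans < 6
      pts[part] <- pts[part] / n_ans[part] * 6
    } else {
      pts[n_ans < 6] <- NA_real_
    }
    tibble::tibble(child_id = cohort$child_id, outcome_age = outcome_age,
                   domain = dm, points = pts, n_answered = n_ans)
  })
  dplyr::bind_rows(res)
}

#' Derive normative domain cutoffs from a reference sample
#'
#' Cutoff = mean - 2 * SD of the non-missing domain scores (sample SD,
#' n - 1 denominator), with no flooring at zero.  A zero-variance domain
#' yields its mean as the cutoff, with a warning.
#'
#' @param scores Long score tibble from [score_asq()].
#' @return Tibble `outcome_age`, `domain`, `cutoff`, `reference_n`.
#' @export
derive_cutoffs <- function(scores) {
  scores |>
    dplyr::filter(!is.na(.data$points)) |>
    dplyr::group_by(.data$outcome_age, .data$domain) |>
    dplyr::summarise(
      cutoff = {
        if (dplyr::n() < 2)
          stop_data("fewer than two reference scores for domain '%s'",
                    .data$domain[1])
        s <- stats::sd(.data$points)
        if (s == 0) {
          warning(sprintf("domain '%s': zero variance in the reference sample; cutoff set to the mean",
                          .data$domain[1]))
          mean(.data$points)
        } else mean(.data$points) - 2 * s
      },
      reference_n = dplyr::n(), .groups = "drop")
}

#' Flag neurodevelopmental delay
#'
#' A domain is delayed when its score is at or below the domain cutoff
#' ("at or below": equality counts).  `any_delay` is the OR over scored
#' domains; it is `NA` only when all five domains are absent.
#'
#' @param scores Long score tibble from [score_asq()].
#' @param cutoffs Cutoff tibble from [derive_cutoffs()].
#' @return Wide tibble `child_id`, `outcome_age`, `delayed_<domain>` (five
#'   logical columns) and `any_delay`.
#' @export
flag_delay <- function(scores, cutoffs) {
  x <- dplyr::left_join(scores, cutoffs, by = c("outcome_age", "domain"))
  if (anyNA(x$cutoff))
    stop_data("missing cutoff for some (outcome_age, domain)")
  x$delayed <- x$points <= x$cutoff
  wide <- x |>
    dplyr::select("child_id", "outcome_age", "domain", "delayed") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "delayed",
                       names_prefix = "delayed_")
  flags <- as.matrix(wide[paste0("delayed_", asq_domains())])
  n_scored <- rowSums(!is.na(flags))
  any_delay <- rowSums(flags, na.rm = TRUE) > 0
  any_delay[n_scored == 0] <- NA
  wide$any_delay <- any_delay
  wide
}
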