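# Growth-reference tables and z-scoring of a cohort.
#
# A reference table holds one LMS row per (sex, measure, age, parity,
# gestational week).  Postnatal rows are stratified by sex and age only
# (parity and gestational_week carry the literal "any"); birth rows (age 0)
# are additionally stratified by the mother's parity and the completed
# gestational week, as national newborn standards are.

.cg_sexes <- c("boy", "girl")
.cg_parities <- c("primipara", "multipara")
.cg_measures <- c("length", "weight")

# Smooth postnatal median/variability curves used by the synthetic reference.
# Parameter values emulate Japanese infant growth (birth ~49 cm / ~3 kg,
# decelerating gains to ~74 cm / ~9.3 kg at 12 months); they are synthetic
# stand-ins, not the published national standards.
.lms_curve <- function(sex, measure, age) {
  if (measure == "length") {
    b <- if (sex == "boy") c(49.2, 18.5, 0.020) else c(48.6, 18.0, 0.019)
    list(L = rep(1, length(age)),
         M = b[1] + b[2] * (1 - exp(-age / 110)) + b[3] * age,
         S = 0.038 - 1e-5 * age)
  } else {
    b <- if (sex == "boy") c(3020, 5600, 2.6) else c(2960, 5200, 2.5)
    list(L = rep(0.45, length(age)),
         M = b[1] + b[2] * (1 - exp(-age / 115)) + b[3] * age,
         S = 0.118 - 4e-5 * age)
  }
}

# Birth LMS per parity x completed gestational week; tighter S than the
# unstratified curves because week and parity soak up part of the variation.
.birth_lms <- function(sex, measure, parity, gw) {
  mid <- gw + 0.5 - 39.5
  multi <- as.numeric(parity == "multipara")
  if (measure == "length") {
    m0 <- if (sex == "boy") 49.2 else 48.6
    list(L = 1, M = m0 + 0.55 * mid + 0.15 * multi, S = 0.033)
  } else {
    m0 <- if (sex == "boy") 3020 else 2960
    list(L = 0.45, M = m0 + 135 * mid + 55 * multi, S = 0.105)
  }
}

#' Synthetic LMS growth-reference table
#'
#' Builds a reference table with the schema expected by [zscore_anthro()]:
#' daily postnatal rows per sex and measure, plus birth rows stratified by
#' parity and completed gestational week.  The values are a synthetic
#' emulation of Japanese infant growth; national standards are not
#' redistributable, so users with access to a real reference should load it
#' with [read_lms_reference()] instead.
#'
#' @param ages Integer vector of postnatal ages (days) to tabulate.
#' @param gestational_weeks Completed gestational weeks for the birth strata.
#' @return A tibble with columns `sex`, `measure`, `age_days`, `parity`,
#'   `gestational_week` (character; `"any"` for unstratified rows), `L`,
#'   `M`, `S`.
#' @export
synthetic_lms_reference <- function(ages = 1:400, gestational_weeks = 33:43) {
  post <- lapply(.cg_sexes, function(sx) {
    lapply(.cg_measures, function(ms) {
      p <- .lms_curve(sx, ms, ages)
      tibble::tibble(sex = sx, measure = ms, age_days = as.numeric(ages),
                     parity = "any", gestational_week = "any",
                     L = p$L, M = p$M, S = p$S)
    })
  })
  birth <- expand.grid(sex = .cg_sexes, measure = .cg_measures,
                       parity = .cg_parities, gw = gestational_weeks,
                       stringsAsFactors = FALSE)
  bl <- Map(function(sx, ms, pa, gw) {
    p <- .birth_lms(sx, ms, pa, gw)
    tibble::tibble(sex = sx, measure = ms, age_days = 0, parity = pa,
                   gestational_week = as.character(gw),
                   L = p$L, M = p$M, S = p$S)
  }, birth$sex, birth$measure, birth$parity, birth$gw)
  dplyr::bind_rows(dplyr::bind_rows(bl),
                   dplyr::bind_rows(unlist(post, recursive = FALSE)))
}

.validate_reference <- function(ref) {
  need <- c("sex", "measure", "age_days", "parity", "gestational_week",
            "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss))
    stop_data("reference table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop_data("reference table: M and S must be strictly positive")
  strat <- ref$parity != "any" | ref$gestational_week != "any"
  if (any(strat & ref$age_days != 0))
    stop_data("reference table: parity/gestational_week strata are only allowed at age 0")
  key <- paste(ref$sex, ref$measure, ref$age_days, ref$parity,
               ref$gestational_week)
  if (anyDuplicated(key))
    stop_data("reference table: duplicate (sex, measure, age, parity, week) rows")
  invisible(ref)
}

#' Read / write an LMS reference table
#'
#' CSV schema: header `sex,measure,age_days,parity,gestational_week,L,M,S`
#' with the literal `any` marking unstratified parity/week.
#'
#' @param path File path.
#' @return `read_lms_reference()` returns a validated tibble.
#' @export
read_lms_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    sex = "c", measure = "c", age_days = "d", parity = "c",
    gestational_week = "c", L = "d", M = "d", S = "d"))
  .validate_reference(ref)
  ref
}

#' @rdname read_lms_reference
#' @param ref Reference tibble as returned by [synthetic_lms_reference()].
#' @export
write_lms_reference <- function(ref, path) {
  .validate_reference(ref)
  readr::write_csv(ref, path)
  invisible(path)
}

#' Look up LMS parameters at given ages
#'
#' Uses the reference row nearest in age when it lies within `tol` days of
#' the requested age, and linear interpolation of L, M and S between the
#' flanking rows otherwise.  Vectorised over all query arguments.
#'
#' @param ref Reference table.
#' @param sex,measure,parity,gestational_week Stratum of each query
#'   (character, recycled).
#' @param age_days Ages to look up, in days.
#' @param tol Nearest-row tolerance in days.
#' @return Tibble with columns `L`, `M`, `S`, one row per query.
#' @export
lms_at <- function(ref, sex, measure, age_days, parity = "any",
                   gestational_week = "any", tol = 15) {
  n <- max(length(sex), length(measure), length(age_days), length(parity),
           length(gestational_week))
  sex <- rep_len(sex, n); measure <- rep_len(measure, n)
  age_days <- rep_len(as.numeric(age_days), n)
  parity <- rep_len(parity, n)
  gestational_week <- rep_len(as.character(gestational_week), n)

  out_L <- rep(NA_real_, n); out_M <- rep(NA_real_, n); out_S <- rep(NA_real_, n)
  key <- paste(sex, measure, parity, gestational_week, sep = "|")
  refkey <- paste(ref$sex, ref$measure, ref$parity, ref$gestational_week,
                  sep = "|")
  for (k in unique(key[!is.na(age_days)])) {
    idx <- which(key == k & !is.na(age_days))
    sub <- ref[refkey == k, , drop = FALSE]
    if (nrow(sub) == 0)
      stop_data("no reference rows for stratum (sex=%s, measure=%s, parity=%s, gestational_week=%s)",
                sex[idx[1]], measure[idx[1]], parity[idx[1]],
                gestational_week[idx[1]])
    sub <- sub[order(sub$age_days), , drop = FALSE]
    a <- age_days[idx]
    lo <- findInterval(a, sub$age_days)
    lo_c <- pmax(pmin(lo, nrow(sub)), 1L)
    hi_c <- pmax(pmin(lo + 1L, nrow(sub)), 1L)
    d_lo <- abs(a - sub$age_days[lo_c])
    d_hi <- abs(a - sub$age_days[hi_c])
    nearest <- ifelse(d_lo <= d_hi, lo_c, hi_c)
    d_near <- pmin(d_lo, d_hi)
    use_near <- d_near <= tol
    if (any(!use_near)) {
      bad <- !use_near & (lo < 1 | lo >= nrow(sub))
      if (any(bad))
        stop_data("age %s d outside the reference range for stratum %s",
                  paste(unique(a[bad]), collapse = ", "), k)
      w <- (a - sub$age_days[lo_c]) / (sub$age_days[hi_c] - sub$age_days[lo_c])
      ii <- idx[!use_near]; wn <- w[!use_near]
      out_L[ii] <- (1 - wn) * sub$L[lo_c[!use_near]] + wn * sub$L[hi_c[!use_near]]
      out_M[ii] <- (1 - wn) * sub$M[lo_c[!use_near]] + wn * sub$M[hi_c[!use_near]]
      out_S[ii] <- (1 - wn) * sub$S[lo_c[!use_near]] + wn * sub$S[hi_c[!use_near]]
    }
    ii <- idx[use_near]
    out_L[ii] <- sub$L[nearest[use_near]]
    out_M[ii] <- sub$M[nearest[use_near]]
    out_S[ii] <- sub$S[nearest[use_near]]
  }
  tibble::tibble(L = out_L, M = out_M, S = out_S)
}

#' Z-score a cohort's anthropometric timeline
#'
#' Converts raw length/weight at birth and the target ages into
#' reference-based z-scores.  Birth z-scores use the parity x completed
#' gestational week stratum of the reference; later ages use sex and age
#' only.  Missing measurements yield missing z-scores.
#'
#' @param timeline Tibble with columns `child_id`, `sex`, `parity`,
#'   `gestational_age`, and the measurement columns produced by
#'   [build_timeline()] (`length_birth`, `weight_birth`, `length_4m`, ...,
#'   `weight_10m`).
#' @param ref Reference table (default: [synthetic_lms_reference()]).
#' @param target_ages Ages in days matching the `4m`, `7m`, `10m` columns.
#' @param tol Nearest-row tolerance passed to [lms_at()].
#' @return Tibble `child_id`, `sex`, and eight z-score columns
#'   (`z_length_birth`, ..., `z_weight_10m`).
#' @export
zscore_anthro <- function(timeline, ref = synthetic_lms_reference(),
                          target_ages = c(122, 213, 304), tol = 15) {
  stopifnot(length(target_ages) == 3)
  gw <- as.character(floor(timeline$gestational_age))
  out <- tibble::tibble(child_id = timeline$child_id, sex = timeline$sex)
  zcol <- function(values, measure, age, parity, week) {
    z <- rep(NA_real_, length(values))
    # children with unknown parity or gestational week cannot be referenced
    # to a birth stratum; their z stays absent (eligibility filters them)
    has <- !is.na(values) & !is.na(parity) & parity != "NA" &
      !is.na(week) & week != "NA"
    if (any(has)) {
      p <- lms_at(ref, timeline$sex[has], measure, age,
                  parity = parity[has], gestational_week = week[has],
                  tol = tol)
      z[has] <- lms_zscore(values[has], p$L, p$M, p$S)
    }
    z
  }
  anyv <- rep("any", nrow(timeline))
  out$z_length_birth <- zcol(timeline$length_birth, "length", 0,
                             timeline$parity, gw)
  out$z_weight_birth <- zcol(timeline$weight_birth, "weight", 0,
                             timeline$parity, gw)
  labs <- c("4m", "7m", "10m")
  for (i in seq_along(labs)) {
    out[[paste0("z_length_", labs[i])]] <-
      zcol(timeline[[paste0("length_", labs[i])]], "length", target_ages[i],
           anyv, anyv)
    out[[paste0("z_weight_", labs[i])]] <-
      zcol(timeline[[paste0("weight_", labs[i])]], "weight", target_ages[i],
           anyv, anyv)
  }
  out
}
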