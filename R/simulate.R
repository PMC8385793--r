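# Seeded synthetic-cohort generator.
#
# The restricted cohort data cannot be shipped, so every downstream stage
# is exercised on synthetic cohorts that reproduce the statistical
# structure the analysis assumes: correlated latent length/weight z-scores
# at birth and 4/7/10 months, raw measurements obtained through the
# inverse LMS transform at jittered checkup ages, covariates with
# realistic marginals, delay indicators generated on the log-risk scale
# from the *true* conditional growth variables (so the quasi-Poisson
# estimand equals the configured relative risk), ASQ item responses
# sampled backwards from the drawn delay flag, and missing-at-random
# checkup attendance that skews multiparous/smoking families.

.z_cols <- paste0("z_", rep(c("length", "weight"), 4), "_",
                  rep(c("birth", "4m", "7m", "10m"), each = 2))

.cond_defs <- list(
  length0    = list(cur = "z_length_birth", prev = character()),
  weight0    = list(cur = "z_weight_birth", prev = character()),
  cLength4   = list(cur = "z_length_4m",
                    prev = c("z_length_birth", "z_weight_birth")),
  crWeight4  = list(cur = "z_weight_4m",
                    prev = c("z_length_4m", "z_length_birth", "z_weight_birth")),
  cLength7   = list(cur = "z_length_7m",
                    prev = c("z_length_birth", "z_weight_birth",
                             "z_length_4m", "z_weight_4m")),
  crWeight7  = list(cur = "z_weight_7m",
                    prev = c("z_length_7m", "z_length_birth", "z_weight_birth",
                             "z_length_4m", "z_weight_4m")),
  cLength10  = list(cur = "z_length_10m",
                    prev = c("z_length_birth", "z_weight_birth",
                             "z_length_4m", "z_weight_4m",
                             "z_length_7m", "z_weight_7m")),
  crWeight10 = list(cur = "z_weight_10m",
                    prev = c("z_length_10m", "z_length_birth", "z_weight_birth",
                             "z_length_4m", "z_weight_4m",
                             "z_length_7m", "z_weight_7m")))

#' Default latent growth correlation matrix
#'
#' Correlation over the eight latent z-scores, built as the Kronecker
#' product of an AR(1) correlation across the four timepoints and a 2x2
#' length-weight correlation, which guarantees a symmetric positive
#' definite matrix with unit diagonal.
#'
#' @param rho_time Adjacent-timepoint correlation (AR(1) base).
#' @param rho_measure Within-timepoint length-weight correlation.
#' @return 8x8 named correlation matrix.
#' @export
default_growth_corr <- function(rho_time = 0.7, rho_measure = 0.6) {
  Rt <- rho_time^abs(outer(1:4, 1:4, "-"))
  Rm <- matrix(c(1, rho_measure, rho_measure, 1), 2)
  R <- kronecker(Rt, Rm)
  dimnames(R) <- list(.z_cols, .z_cols)
  R
}

#' Default simulation configuration
#'
#' Marginal distributions follow the published baseline characteristics of
#' the complete-data column of the reference cohort: 51.7 % multipara,
#' 14.5 % maternal smoking, the education/income/speech-stimulation
#' splits, gestational age ~ N(39.5, 1.1) truncated to term, and baseline
#' any-domain delay probabilities of 8.9 % (boys) / 8.5 % (girls) at
#' 6 months and 16.9 % / 12.6 % at 12 months.  Checkup missingness
#' marginals (16.1 / 63.3 / 42.1 %) mirror the published data-availability
#' accounting.  The default log relative risks give a protective effect of
#' birth weight and of conditional length at 4 months, the magnitudes the
#' method is designed to detect.
#'
#' @return A named list; see the package vignette for every knob.
#' @export
default_config <- function() {
  list(
    n_children = 10000,
    seed = 1L,
    sex_ratio = 0.51,
    gestational_age = list(mean = 39.5, sd = 1.1, min = 37, max = 41.9),
    p_multipara = 0.517,
    p_non_singleton = 0.005,
    p_malformation = 0.035,
    p_missing_basic = 0.003,
    covariates = list(
      maternal_age = c(mean = 31.4, sd = 4.9),
      p_smoking = 0.145,
      maternal_education = c(junior_high = 0.032, high_school = 0.728,
                             university_or_grad = 0.240),
      paternal_education = c(junior_high = 0.053, high_school = 0.596,
                             university_or_grad = 0.351),
      family_income = c(low = 0.369, mid = 0.340, high = 0.291),
      p_speech = 0.814),
    covariate_missing = list(
      maternal_age = 0.0001, maternal_smoking = 0.024,
      maternal_education = 0.021, paternal_education = 0.027,
      family_income = 0.089, home_speech_stimulation = 0.023),
    growth_corr = default_growth_corr(),
    true_log_rr = c(length0 = 0, weight0 = log(0.92), cLength4 = log(0.86),
                    crWeight4 = 0, cLength7 = 0, crWeight7 = 0,
                    cLength10 = 0, crWeight10 = 0),
    baseline_delay_prob = list(
      "6" = c(boy = 0.089, girl = 0.085),
      "12" = c(boy = 0.169, girl = 0.126)),
    missingness = list(
      checkup_miss = c(m4 = 0.161, m7 = 0.633, m10 = 0.421),
      attendance_sd = 1.2, beta_multipara = 0.45, beta_smoking = 0.35,
      asq_miss = c("6" = 0.139, "12" = 0.182), asq_item_miss = 0),
    checkup_age_jitter = 10,
    round_measurements = TRUE,
    asq = list(
      domain_weights = list(
        "6" = c(communication = 1.8, gross_motor = 1.7, fine_motor = 2.6,
                problem_solving = 3.8, personal_social = 1.6),
        "12" = c(communication = 4.6, gross_motor = 5.4, fine_motor = 4.4,
                 problem_solving = 6.0, personal_social = 3.6)),
      n_low_domains_prob = c(0.7, 0.2, 0.1),
      high_score_prob = c("60" = 0.60, "55" = 0.22, "50" = 0.12, "45" = 0.06),
      low_score_prob = c("0" = 0.25, "5" = 0.30, "10" = 0.30, "15" = 0.15)))
}

.chk_prob <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_config("configuration: %s must lie in [0, 1]", what)
}

#' Validate a simulation configuration
#'
#' @param config Configuration list as from [default_config()].
#' @return The config, invisibly, or a configuration error.
#' @export
validate_config <- function(config) {
  if (!is.numeric(config$n_children) || config$n_children < 1)
    stop_config("configuration: n_children must be >= 1")
  R <- config$growth_corr
  if (!is.matrix(R) || nrow(R) != 8 || ncol(R) != 8)
    stop_config("configuration: growth_corr must be an 8x8 matrix")
  if (max(abs(R - t(R))) > 1e-8)
    stop_config("configuration: growth_corr must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop_config("configuration: growth_corr must have unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop_config("configuration: growth_corr must be positive definite")
  .chk_prob(config$sex_ratio, "sex_ratio")
  .chk_prob(config$p_multipara, "p_multipara")
  .chk_prob(unlist(config$baseline_delay_prob), "baseline_delay_prob")
  .chk_prob(config$missingness$checkup_miss, "missingness$checkup_miss")
  .chk_prob(config$missingness$asq_miss, "missingness$asq_miss")
  extra <- setdiff(names(config$true_log_rr), names(.cond_defs))
  if (length(extra))
    stop_config("configuration: unknown true_log_rr name(s): %s",
                paste(extra, collapse = ", "))
  invisible(config)
}

# Population conditional variables: for latent MVN z with known
# correlation Sigma, the residual of the current size on the previous
# sizes is an exact linear map, so the generator's "true" exposures do not
# depend on sample size.
.population_conditionals <- function(Z, Sigma) {
  out <- matrix(NA_real_, nrow(Z), length(.cond_defs),
                dimnames = list(NULL, names(.cond_defs)))
  for (v in names(.cond_defs)) {
    def <- .cond_defs[[v]]
    if (!length(def$prev)) {
      out[, v] <- Z[, def$cur]
    } else {
      b <- solve(Sigma[def$prev, def$prev], Sigma[def$prev, def$cur])
      res <- Z[, def$cur] - Z[, def$prev, drop = FALSE] %*% b
      sdv <- sqrt(Sigma[def$cur, def$cur] -
                    sum(Sigma[def$cur, def$prev] * b))
      out[, v] <- res / sdv
    }
  }
  out
}

# Latent z linearly interpolated along the knot ages (0/122/213/304 d);
# the last segment extrapolates, covering jittered 10-month visits.
.z_path_at <- function(Z, t, measure) {
  knots <- c(0, 122, 213, 304)
  cols <- paste0("z_", measure, "_", c("birth", "4m", "7m", "10m"))
  seg <- pmin(pmax(findInterval(t, knots), 1L), 3L)
  w <- (t - knots[seg]) / (knots[seg + 1] - knots[seg])
  i <- seq_len(nrow(Z))
  (1 - w) * Z[cbind(i, match(cols[seg], colnames(Z)))] +
    w * Z[cbind(i, match(cols[seg + 1], colnames(Z)))]
}

# Compose six item responses realising a given domain score.
.items_from_scores <- function(S) {
  n_yes <- S %/% 10
  n_some <- (S %% 10) / 5
  lapply(1:6, function(i)
    ifelse(i <= n_yes, "yes",
           ifelse(i <= n_yes + n_some, "sometimes", "not_yet")))
}

# Domain scores + items for one outcome age, sampled backwards from the
# drawn delay indicator: non-delayed children score >= 45 in every domain,
# delayed children get 1-3 domains forced to <= 15, so the scored flag
# reproduces the indicator whenever the derived cutoffs fall in (15, 45).
.simulate_asq <- function(delayed, outcome_age, asq_cfg) {
  n <- length(delayed)
  hs <- asq_cfg$high_score_prob
  ls <- asq_cfg$low_score_prob
  S <- matrix(sample(as.numeric(names(hs)), n * 5, TRUE, hs), n, 5,
              dimnames = list(NULL, asq_domains()))
  idx <- which(delayed)
  if (length(idx)) {
    nd <- length(idx)
    k <- sample.int(3, nd, TRUE, prob = asq_cfg$n_low_domains_prob)
    w <- asq_cfg$domain_weights[[as.character(outcome_age)]][asq_domains()]
    # weighted sampling without replacement per child via Gumbel keys
    G <- matrix(rep(log(w), each = nd), nd, 5) -
      log(-log(matrix(stats::runif(nd * 5), nd, 5)))
    rk <- matrix(0L, nd, 5)
    for (j in 1:5) rk[, j] <- rowSums(G > G[, j])
    low <- rk < k
    S[idx, ][low] <- sample(as.numeric(names(ls)), sum(low), TRUE, ls)
  }
  items <- list()
  for (d in seq_along(asq_domains())) {
    it <- .items_from_scores(S[, d])
    for (i in 1:6)
      items[[paste0("asq", outcome_age, "_", asq_domains()[d], "_i", i)]] <-
        it[[i]]
  }
  list(items = items, scores = S)
}

# Truncated-normal draw via inverse CDF.
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a synthetic cohort
#'
#' Deterministic given the seed: a single seed governs one random stream,
#' with draws taken in a fixed, documented order (sex, gestational age,
#' parity, covariates, latent growth, delay indicators, checkup ages, ASQ
#' responses, missingness masks).  The true conditional growth variables
#' and the drawn delay indicators are attached as attributes for
#' validation (see [sim_truth()]).
#'
#' @param config Simulation configuration, see [default_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param reference LMS reference used for the inverse z transform.
#' @return Cohort tibble, one row per child, wide format (checkups as
#'   `age_d_k` / `length_cm_k` / `weight_g_k`, ASQ items as
#'   `asq<age>_<domain>_i<k>` columns).
#' @export
simulate_cohort <- function(config = default_config(), seed = config$seed,
                            reference = synthetic_lms_reference()) {
  validate_config(config)
  set.seed(as.integer(seed))
  n <- as.integer(config$n_children)

  sex <- sample(c("boy", "girl"), n, TRUE,
                prob = c(config$sex_ratio, 1 - config$sex_ratio))
  ga_cfg <- config$gestational_age
  ga <- round(.rtruncnorm(n, ga_cfg$mean, ga_cfg$sd, ga_cfg$min, ga_cfg$max), 1)
  parity <- sample(c("multipara", "primipara"), n, TRUE,
                   prob = c(config$p_multipara, 1 - config$p_multipara))
  singleton <- stats::runif(n) >= config$p_non_singleton
  malformation <- stats::runif(n) < config$p_malformation

  cv <- config$covariates
  maternal_age <- round(stats::rnorm(n, cv$maternal_age["mean"],
                                     cv$maternal_age["sd"]), 1)
  maternal_smoking <- stats::runif(n) < cv$p_smoking
  maternal_education <- sample(names(cv$maternal_education), n, TRUE,
                               prob = cv$maternal_education)
  paternal_education <- sample(names(cv$paternal_education), n, TRUE,
                               prob = cv$paternal_education)
  family_income <- sample(names(cv$family_income), n, TRUE,
                          prob = cv$family_income)
  home_speech <- stats::runif(n) < cv$p_speech

  R <- config$growth_corr
  Z <- MASS::mvrnorm(n, mu = rep(0, 8), Sigma = R)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  colnames(Z) <- .z_cols
  tc <- .population_conditionals(Z, R)

  beta <- rep(0, length(.cond_defs))
  names(beta) <- names(.cond_defs)
  beta[names(config$true_log_rr)] <- config$true_log_rr
  lp <- as.vector(tc %*% beta)
  delay <- list()
  for (age in c("6", "12")) {
    base <- config$baseline_delay_prob[[age]]
    p <- unname(base[sex]) * exp(lp)
    if (any(p > 1)) {
      i <- which.max(p)
      stop_config("configuration: delay probability %.3f > 1 at outcome age %s months for sex %s; true_log_rr effects too large for the baseline",
                  p[i], age, sex[i])
    }
    delay[[age]] <- stats::rbinom(n, 1, p) == 1
  }

  j <- config$checkup_age_jitter
  jit <- function() if (j > 0) sample(seq(-j, j), n, TRUE) else integer(n)
  ages <- cbind(122 + jit(), 213 + jit(), 304 + jit())
  raw_len <- matrix(NA_real_, n, 3)
  raw_wt <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    pl <- lms_at(reference, sex, "length", ages[, k])
    raw_len[, k] <- lms_inverse(.z_path_at(Z, ages[, k], "length"),
                                pl$L, pl$M, pl$S)
    pw <- lms_at(reference, sex, "weight", ages[, k])
    raw_wt[, k] <- lms_inverse(.z_path_at(Z, ages[, k], "weight"),
                               pw$L, pw$M, pw$S)
  }
  gw <- as.character(floor(ga))
  pbl <- lms_at(reference, sex, "length", 0, parity, gw)
  birth_len <- lms_inverse(Z[, "z_length_birth"], pbl$L, pbl$M, pbl$S)
  pbw <- lms_at(reference, sex, "weight", 0, parity, gw)
  birth_wt <- lms_inverse(Z[, "z_weight_birth"], pbw$L, pbw$M, pbw$S)
  if (isTRUE(config$round_measurements)) {
    birth_len <- round(birth_len, 1); birth_wt <- round(birth_wt)
    raw_len <- round(raw_len, 1); raw_wt <- round(raw_wt)
  }

  asq6 <- .simulate_asq(delay[["6"]], 6, config$asq)
  asq12 <- .simulate_asq(delay[["12"]], 12, config$asq)

  # Missing-at-random attendance: a shared propensity plus multipara and
  # smoking effects; intercepts calibrated (logit-normal approximation) to
  # the configured marginal missingness.
  ms <- config$missingness
  u <- stats::rnorm(n)
  infl <- sqrt(1 + 0.346 * ms$attendance_sd^2)
  multi <- parity == "multipara"
  miss_chk <- matrix(FALSE, n, 3)
  for (k in 1:3) {
    alpha <- stats::qlogis(ms$checkup_miss[k]) * infl -
      ms$beta_multipara * config$p_multipara -
      ms$beta_smoking * cv$p_smoking
    eta <- alpha + ms$beta_multipara * multi +
      ms$beta_smoking * maternal_smoking + ms$attendance_sd * u
    miss_chk[, k] <- stats::runif(n) < stats::plogis(eta)
  }
  miss_asq6 <- stats::runif(n) < ms$asq_miss[["6"]]
  miss_asq12 <- stats::runif(n) < ms$asq_miss[["12"]]

  cohort <- tibble::tibble(
    child_id = sprintf("C%06d", seq_len(n)),
    sex = sex, gestational_age = ga, parity = parity,
    singleton = singleton, malformation = malformation,
    birth_length_cm = birth_len, birth_weight_g = birth_wt,
    age_d_1 = ages[, 1], length_cm_1 = raw_len[, 1], weight_g_1 = raw_wt[, 1],
    age_d_2 = ages[, 2], length_cm_2 = raw_len[, 2], weight_g_2 = raw_wt[, 2],
    age_d_3 = ages[, 3], length_cm_3 = raw_len[, 3], weight_g_3 = raw_wt[, 3],
    maternal_age = maternal_age, maternal_smoking = maternal_smoking,
    maternal_education = maternal_education,
    paternal_education = paternal_education,
    family_income = family_income,
    home_speech_stimulation = home_speech)
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(asq6$items),
                             tibble::as_tibble(asq12$items))

  for (k in 1:3) {
    cols <- paste0(c("age_d_", "length_cm_", "weight_g_"), k)
    for (cl in cols) cohort[[cl]][miss_chk[, k]] <- NA
  }
  for (cl in grep("^asq6_", names(cohort), value = TRUE))
    cohort[[cl]][miss_asq6] <- NA
  for (cl in grep("^asq12_", names(cohort), value = TRUE))
    cohort[[cl]][miss_asq12] <- NA
  if (ms$asq_item_miss > 0) {
    for (cl in grep("^asq", names(cohort), value = TRUE)) {
      hit <- stats::runif(n) < ms$asq_item_miss
      cohort[[cl]][hit] <- NA
    }
  }
  cm <- config$covariate_missing
  for (cl in names(cm)) {
    hit <- stats::runif(n) < cm[[cl]]
    cohort[[cl]][hit] <- NA
  }
  if (config$p_missing_basic > 0) {
    hit <- which(stats::runif(n) < config$p_missing_basic)
    which_col <- sample(c("parity", "birth_length_cm", "birth_weight_g"),
                        length(hit), TRUE)
    for (i in seq_along(hit)) cohort[[which_col[i]]][hit[i]] <- NA
  }

  attr(cohort, "latent_z") <- Z
  attr(cohort, "true_conditionals") <-
    dplyr::bind_cols(tibble::tibble(child_id = cohort$child_id),
                     tibble::as_tibble(tc))
  attr(cohort, "true_delay") <- tibble::tibble(
    child_id = cohort$child_id, delay6 = delay[["6"]], delay12 = delay[["12"]])
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "sim_config") <- config
  cohort
}

#' Generator ground truth attached to a simulated cohort
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @return List with `latent_z` (matrix), `conditionals` (tibble of the
#'   true conditional variables) and `delay` (drawn indicators).
#' @export
sim_truth <- function(cohort) {
  list(latent_z = attr(cohort, "latent_z"),
       conditionals = attr(cohort, "true_conditionals"),
       delay = attr(cohort, "true_delay"))
}

#' Read / write a cohort CSV
#'
#' Wide format, one row per child, missing values as empty fields.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort()` returns the cohort tibble with canonical column
#'   types.
#' @export
read_cohort <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       na = c("", "NA"))
  num <- c("gestational_age", "birth_length_cm", "birth_weight_g",
           paste0("age_d_", 1:3), paste0("length_cm_", 1:3),
           paste0("weight_g_", 1:3), "maternal_age")
  lgl <- c("singleton", "malformation", "maternal_smoking",
           "home_speech_stimulation")
  for (cl in intersect(num, names(x))) x[[cl]] <- as.numeric(x[[cl]])
  for (cl in intersect(lgl, names(x))) x[[cl]] <- as.logical(x[[cl]])
  x
}
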