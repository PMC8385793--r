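test_that("a single binary exposure reproduces the closed-form risk ratio", {
  # 20-row hand dataset: exposed 4/8 events, unexposed 3/12
  d <- tibble::tibble(
    y = c(rep(1, 4), rep(0, 4), rep(1, 3), rep(0, 9)),
    x = c(rep(1, 8), rep(0, 12)))
  r <- fit_rr_model(d, "y", "x", covariates = character(0))
  expect_equal(r$aRR, (4 / 8) / (3 / 12), tolerance = 1e-12)
  expect_equal(r$n_used, 20)
  expect_equal(r$events, 7)
  expect_gt(r$dispersion, 0)
  expect_true(r$ci_low <= r$aRR && r$aRR <= r$ci_high)
})

test_that("quasi-Poisson point estimates equal Poisson maximum likelihood", {
  set.seed(61)
  n <- 2000
  d <- tibble::tibble(x1 = rnorm(n), x2 = rbinom(n, 1, 0.3))
  d$y <- rbinom(n, 1, 0.1 * exp(-0.2 * d$x1 + 0.1 * d$x2))
  ours <- fit_rr_model(d, "y", c("x1", "x2"), covariates = character(0))
  pois <- glm(y ~ x1 + x2, family = poisson(link = "log"), data = d)
  expect_equal(unname(log(ours$aRR)), unname(coef(pois)[-1]),
               tolerance = 1e-8)
  # CIs differ exactly by the sqrt(dispersion) factor
  se_pois <- summary(pois)$coefficients[-1, "Std. Error"]
  width_ours <- log(ours$ci_high) - log(ours$ci_low)
  expect_equal(unname(width_ours),
               unname(2 * 1.96 * se_pois * sqrt(ours$dispersion[1])),
               tolerance = 1e-8)
})

test_that("a null exposure at moderate n gives an estimate near 1 with coverage", {
  set.seed(71)
  n <- 20000
  d <- tibble::tibble(x = rnorm(n))
  d$y <- rbinom(n, 1, 0.09)
  r <- fit_rr_model(d, "y", "x", covariates = character(0))
  expect_lt(abs(log(r$aRR)), 4 * (log(r$ci_high) - log(r$aRR)) / 1.96)
  expect_true(r$ci_low < 1.1 && r$ci_high > 0.9)
})

test_that("categorical covariates are dummy-coded against the declared references", {
  cfg <- tiny_config(4000)
  co <- simulate_cohort(cfg, seed = 19)
  s6 <- score_asq(co, 6)
  f6 <- flag_delay(s6, derive_cutoffs(s6))
  tl <- build_timeline(co)
  zs <- zscore_anthro(tl)
  cs <- build_conditional_set(zs, 0, sex = "boy")
  tab <- dplyr::inner_join(cs, co[c("child_id", delay_covariates())],
                           by = "child_id")
  tab <- dplyr::left_join(tab, f6[c("child_id", "any_delay")], by = "child_id")
  r <- fit_rr_model(tab, "any_delay", exposures_for_variant(0))
  expect_true(all(c("maternal_educationhigh_school",
                    "family_incomemid", "family_incomehigh",
                    "maternal_smokingTRUE") %in% r$term))
  expect_false(any(grepl("junior_high|incomelow", r$term)))
  # empty level is dropped with a warning
  tab2 <- tab[tab$family_income != "high" | is.na(tab$family_income), ]
  expect_warning(fit_rr_model(tab2, "any_delay", exposures_for_variant(0)),
                 "empty level")
})

test_that("fit_rr_model validates inputs", {
  d <- tibble::tibble(y = c(0, 1, 2, 0), x = rnorm(4))
  expect_error(fit_rr_model(d, "y", "x", covariates = character(0)),
               class = "cg_data_error")
  expect_error(fit_rr_model(d, "missing_outcome", "x"),
               class = "cg_data_error")
})

test_that("the model grid has the published table structure", {
  cfg <- tiny_config(6000)
  co <- simulate_cohort(cfg, seed = 23)
  tl <- build_timeline(co)
  zs <- zscore_anthro(tl)
  s6 <- score_asq(co, 6); f6 <- flag_delay(s6, derive_cutoffs(s6))
  s12 <- score_asq(co, 12); f12 <- flag_delay(s12, derive_cutoffs(s12))
  m <- run_delay_models(co, zs, f6, f12)
  # 2 sexes x (6-month + three 12-month variants) tables x 6 outcomes
  tabs <- unique(m[c("sex", "outcome_age", "variant")])
  expect_equal(nrow(tabs), 8)
  expect_equal(nrow(unique(m[c("sex", "outcome_age", "variant", "outcome")])),
               48)
  # 6-month models carry only birth + 4-month conditionals
  m6 <- m[m$outcome_age == 6, ]
  expect_false(any(grepl("7|10", m6$term)))
  # variant 2 has no 10-month terms; variant 1 has the full chain
  expect_false(any(grepl("10", m$term[m$variant == 2])))
  expect_true(all(c("cLength10", "crWeight10") %in% m$term[m$variant == 1]))
  # events/n consistent with the configured 12-month girl rate
  g12 <- m[m$sex == "girl" & m$variant == 1 & m$outcome == "total", ]
  rate <- g12$events[1] / g12$n_used[1]
  expect_equal(rate, 0.126, tolerance = 0.035)
  # formatted output
  fm <- format_rr(m)
  expect_match(fm$formatted[1], "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}-\\d+\\.\\d{2}\\)$")
})
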