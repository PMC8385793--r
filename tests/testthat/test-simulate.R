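test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config(400)
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # and written cohorts are byte-identical
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_cohort(a, fa); write_cohort(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$birth_weight_g, c$birth_weight_g))
})

test_that("a minimal cohort of one complete child is generated", {
  cfg <- tiny_config(1)
  cfg$missingness$checkup_miss <- c(m4 = 0, m7 = 0, m10 = 0)
  cfg$missingness$asq_miss <- c("6" = 0, "12" = 0)
  cfg$covariate_missing <- lapply(cfg$covariate_missing, function(x) 0)
  co <- simulate_cohort(cfg, seed = 1)
  expect_equal(nrow(co), 1)
  expect_false(anyNA(co))
  expect_true(co$gestational_age >= 37 && co$gestational_age < 42)
  expect_true(co$birth_length_cm > 0 && co$birth_weight_g > 0)
  expect_true(all(diff(c(0, co$age_d_1, co$age_d_2, co$age_d_3)) > 0))
})

test_that("invalid configurations are rejected with configuration errors", {
  cfg <- default_config()
  cfg$growth_corr[1, 2] <- 0.99  # asymmetric
  expect_error(validate_config(cfg), class = "cg_config_error")
  cfg <- default_config()
  cfg$growth_corr[] <- 0.99; diag(cfg$growth_corr) <- 1
  cfg$growth_corr[1, 2] <- cfg$growth_corr[2, 1] <- -0.99  # not PD
  expect_error(validate_config(cfg), class = "cg_config_error")
  cfg <- default_config()
  cfg$baseline_delay_prob[["6"]]["boy"] <- 1.2
  expect_error(validate_config(cfg), class = "cg_config_error")
  cfg <- default_config()
  cfg$true_log_rr <- c(nonsense = 0.1)
  expect_error(validate_config(cfg), class = "cg_config_error")
  # effects so large the log-link probability exceeds one
  cfg <- tiny_config(500)
  cfg$true_log_rr <- c(cLength4 = log(30))
  expect_error(simulate_cohort(cfg, seed = 1),
               class = "cg_config_error")
})

test_that("delay rates match the configured baseline under the null", {
  cfg <- default_config()
  cfg$n_children <- 50000
  cfg$true_log_rr <- c(cLength4 = 0)
  co <- simulate_cohort(cfg, seed = 31)
  tr <- sim_truth(co)
  p0 <- 0.089
  boys <- co$sex == "boy"
  se <- sqrt(p0 * (1 - p0) / sum(boys))
  expect_lt(abs(mean(tr$delay$delay6[boys]) - p0), 3 * se)
  # girls at 12 months too
  p1 <- 0.126
  se1 <- sqrt(p1 * (1 - p1) / sum(!boys))
  expect_lt(abs(mean(tr$delay$delay12[!boys]) - p1), 3 * se1)
})

test_that("latent correlations converge to the configured matrix", {
  cfg <- tiny_config(100000)
  co <- simulate_cohort(cfg, seed = 8)
  Z <- sim_truth(co)$latent_z
  expect_lt(norm(cor(Z) - cfg$growth_corr, "F"), 0.05)
})

test_that("scored delay equals the drawn indicator", {
  cfg <- tiny_config(6000)
  co <- simulate_cohort(cfg, seed = 12)
  tr <- sim_truth(co)
  for (age in c(6, 12)) {
    sc <- score_asq(co, age)
    fl <- flag_delay(sc, derive_cutoffs(sc))
    drawn <- tr$delay[[paste0("delay", age)]][match(fl$child_id,
                                                    tr$delay$child_id)]
    scored <- fl$any_delay
    expect_identical(scored[!is.na(scored)], drawn[!is.na(scored)])
  }
})

test_that("generated measurements round-trip to the latent z-scores", {
  cfg <- tiny_config(300)
  cfg$checkup_age_jitter <- 0
  cfg$round_measurements <- FALSE
  cfg$missingness$checkup_miss <- c(m4 = 0, m7 = 0, m10 = 0)
  co <- simulate_cohort(cfg, seed = 44)
  tl <- build_timeline(co)
  zs <- zscore_anthro(tl)
  Z <- sim_truth(co)$latent_z
  for (cl in colnames(Z))
    expect_equal(zs[[cl]], unname(Z[, cl]), tolerance = 1e-8)
})

test_that("missingness skews toward multiparous and smoking families", {
  cfg <- default_config(); cfg$n_children <- 30000
  co <- simulate_cohort(cfg, seed = 55)
  m4 <- is.na(co$age_d_1)
  expect_gt(mean(co$parity[m4] == "multipara", na.rm = TRUE),
            mean(co$parity[!m4] == "multipara", na.rm = TRUE))
  expect_gt(mean(co$maternal_smoking[m4], na.rm = TRUE),
            mean(co$maternal_smoking[!m4], na.rm = TRUE))
  # marginal availability near the configured rates
  expect_equal(mean(!m4), 1 - 0.161, tolerance = 0.04)
  expect_equal(mean(!is.na(co$age_d_2)), 1 - 0.633, tolerance = 0.05)
})

test_that("default_config satisfies its own invariants and documented values", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  expect_equal(unname(cfg$baseline_delay_prob[["6"]]["boy"]), 0.089)
  expect_equal(cfg$p_multipara, 0.517)
})

test_that("cohort CSV round-trips through write_cohort/read_cohort", {
  cfg <- tiny_config(150)
  co <- simulate_cohort(cfg, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), nrow(co))
  expect_equal(back$birth_weight_g, co$birth_weight_g)
  expect_equal(back$maternal_smoking, co$maternal_smoking)
  expect_identical(back$asq6_communication_i1, co$asq6_communication_i1)
})
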