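test_that("conditional residuals match a closed-form simple regression", {
  # 5-row hand dataset, single regressor
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 2, 3, 4, 10)
  oracle <- ols_residuals_normal_eq(y, x)
  got <- conditional_length(y, data.frame(x = x))
  expect_equal(got, oracle / sd(oracle), tolerance = 1e-9)
})

test_that("conditional residuals match the normal-equations oracle", {
  set.seed(11)
  for (p in 1:3) {
    n <- sample(10:50, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    oracle <- ols_residuals_normal_eq(y, X)
    expect_equal(conditional_length(y, X), oracle / sd(oracle),
                 tolerance = 1e-9)
  }
  # relative weight: current length is an extra regressor
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  cl <- rnorm(n); w <- rnorm(n)
  oracle <- ols_residuals_normal_eq(w, cbind(cl, X))
  expect_equal(conditional_relative_weight(w, cl, X), oracle / sd(oracle),
               tolerance = 1e-9)
})

test_that("conditional variables are orthogonal to their regressors", {
  zs <- random_zscores(600, seed = 3)
  cs <- build_conditional_set(zs, 1, sex = "boy")
  d <- dplyr::inner_join(zs, cs, by = c("child_id", "sex"))
  regs <- list(
    cLength4 = c("z_length_birth", "z_weight_birth"),
    crWeight4 = c("z_length_4m", "z_length_birth", "z_weight_birth"),
    cLength7 = c("z_length_birth", "z_weight_birth", "z_length_4m",
                 "z_weight_4m"),
    crWeight10 = c("z_length_10m", "z_length_7m", "z_weight_7m",
                   "z_length_4m", "z_weight_4m", "z_length_birth",
                   "z_weight_birth"))
  for (v in names(regs)) {
    expect_lt(max(abs(mean(d[[v]]))), 1e-8)
    for (r in regs[[v]]) expect_lt(abs(cor(d[[v]], d[[r]])), 1e-8)
  }
  # the six derived conditional variables are mutually uncorrelated, and
  # each is uncorrelated with the birth conditionals (the two birth
  # z-scores themselves are correlated by construction)
  derived <- setdiff(exposures_for_variant(1), c("length0", "weight0"))
  cond <- as.matrix(d[derived])
  off <- abs(cor(cond))[lower.tri(diag(length(derived)))]
  expect_lt(max(off), 1e-6)
  for (v in derived) {
    expect_lt(abs(cor(d[[v]], d$length0)), 1e-6)
    expect_lt(abs(cor(d[[v]], d$weight0)), 1e-6)
  }
})

test_that("standardisation makes conditionals scale invariant", {
  zs <- random_zscores(200, seed = 5)
  cs1 <- build_conditional_set(zs, 2, sex = "girl")
  zs2 <- zs
  zcols <- grep("^z_", names(zs2), value = TRUE)
  zs2[zcols] <- zs2[zcols] * 3.7
  cs2 <- build_conditional_set(zs2, 2, sex = "girl")
  for (v in exposures_for_variant(2))
    expect_equal(cs1[[v]], cs2[[v]], tolerance = 1e-10)
})

test_that("variants emit the documented exposure sets", {
  expect_equal(exposures_for_variant(2),
               c("length0", "weight0", "cLength4", "crWeight4",
                 "cLength7", "crWeight7"))
  zs <- random_zscores(120, seed = 9)
  cs2 <- build_conditional_set(zs, 2)
  expect_false(any(grepl("10", names(cs2))))
  cs3 <- build_conditional_set(zs, 3)
  expect_true(all(c("cLength10", "crWeight10") %in% names(cs3)))
  expect_false(any(grepl("7", names(cs3))))
})

test_that("variant 3 conditions its 10-month variables on birth and 4 months only", {
  zs <- random_zscores(300, seed = 13)
  cs3 <- build_conditional_set(zs, 3, sex = "boy")
  d <- zs[zs$sex == "boy", ]
  oracle <- ols_residuals_normal_eq(
    d$z_length_10m,
    as.matrix(d[c("z_length_birth", "z_weight_birth",
                  "z_length_4m", "z_weight_4m")]))
  expect_equal(cs3$cLength10, oracle / sd(oracle), tolerance = 1e-9)
})

test_that("degenerate designs are flagged", {
  x <- rnorm(30)
  # current identical to a regressor: perfect fit
  expect_warning(r <- conditional_length(x, data.frame(x = x)),
                 "perfect fit")
  expect_lt(max(abs(r)), 1e-8)
  # constant regressor: rank deficient
  expect_error(conditional_length(rnorm(10), rep(1, 10)),
               class = "cg_estimation_error")
  # sample smaller than the design
  expect_error(conditional_length(rnorm(3), matrix(rnorm(9), 3, 3)),
               class = "cg_estimation_error")
  # identical children: zero variance in birth z
  zs <- random_zscores(50, seed = 1)
  zs[grep("^z_", names(zs))] <- 1
  expect_error(build_conditional_set(zs, 0, sex = "boy"),
               class = "cg_estimation_error")
})
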