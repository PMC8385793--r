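test_that("domain scoring follows the 10/5/0 point scheme", {
  expect_equal(score_domain(rep("yes", 6)), 60)
  expect_equal(score_domain(rep("not_yet", 6)), 0)
  expect_equal(score_domain(c("yes", "yes", "sometimes", "sometimes",
                              "not_yet", "not_yet")), 30)
  expect_error(score_domain(c(rep("yes", 5), "maybe")),
               class = "cg_data_error")
  expect_error(score_domain(rep("yes", 5)), class = "cg_data_error")
})

test_that("missing items make a domain absent unless proration is requested", {
  r <- c("yes", "yes", "yes", NA, "yes", "yes")
  expect_true(is.na(score_domain(r)))
  expect_equal(score_domain(r, prorate = TRUE), 10 * 6)
  r2 <- c("yes", "sometimes", NA, NA, NA, NA)
  expect_equal(score_domain(r2, prorate = TRUE), 7.5 * 6)
})

test_that("cutoffs are mean minus two sample SDs", {
  sc <- tibble::tibble(child_id = c("a", "b"), outcome_age = 6,
                       domain = "communication", points = c(40, 60),
                       n_answered = 6)
  cut <- derive_cutoffs(sc)
  expect_equal(cut$cutoff, 50 - 2 * sd(c(40, 60)))
  expect_equal(cut$cutoff, 21.7157, tolerance = 1e-4)
  # location shift moves the cutoff by the same amount
  sc5 <- sc; sc5$points <- sc5$points + 5
  expect_equal(derive_cutoffs(sc5)$cutoff, cut$cutoff + 5)
  # zero variance: cutoff collapses to the mean, with a warning
  sc0 <- tibble::tibble(child_id = letters[1:4], outcome_age = 6,
                        domain = "gross_motor", points = 50, n_answered = 6)
  expect_warning(c0 <- derive_cutoffs(sc0), "zero variance")
  expect_equal(c0$cutoff, 50)
})

test_that("delay flags use at-or-below semantics and OR across domains", {
  mk_scores <- function(points) {
    tibble::tibble(child_id = "x", outcome_age = 6, domain = asq_domains(),
                   points = points, n_answered = ifelse(is.na(points), 0, 6))
  }
  cuts <- tibble::tibble(outcome_age = 6, domain = asq_domains(),
                         cutoff = 30, reference_n = 100)
  # all above cutoff: not delayed
  expect_false(flag_delay(mk_scores(rep(60, 5)), cuts)$any_delay)
  # exactly at the cutoff counts as delayed
  expect_true(flag_delay(mk_scores(c(30, 60, 60, 60, 60)), cuts)$any_delay)
  # absent domain plus one delayed domain: delayed
  f <- flag_delay(mk_scores(c(NA, 25, 60, 60, 60)), cuts)
  expect_true(f$any_delay)
  expect_true(is.na(f$delayed_communication))
  # all domains absent: any_delay is absent
  expect_true(is.na(flag_delay(mk_scores(rep(NA_real_, 5)), cuts)$any_delay))
})

test_that("degrading one item never converts delayed into not delayed", {
  set.seed(21)
  cuts <- tibble::tibble(outcome_age = 6, domain = asq_domains(),
                         cutoff = runif(5, 20, 40), reference_n = 100)
  tokens <- c("yes", "sometimes", "not_yet")
  for (rep in 1:25) {
    items <- matrix(sample(tokens, 30, TRUE), 5, 6)
    pts <- apply(items, 1, score_domain)
    sc <- tibble::tibble(child_id = "x", outcome_age = 6,
                         domain = asq_domains(), points = pts, n_answered = 6)
    before <- flag_delay(sc, cuts)$any_delay
    # degrade one random item a notch
    i <- sample(5, 1); j <- sample(6, 1)
    items[i, j] <- switch(items[i, j], yes = "sometimes",
                          sometimes = "not_yet", not_yet = "not_yet")
    sc$points <- apply(items, 1, score_domain)
    after <- flag_delay(sc, cuts)$any_delay
    expect_true(!before || after)
  }
})

test_that("cohort-level scoring agrees with scalar scoring", {
  cfg <- tiny_config(300)
  co <- simulate_cohort(cfg, seed = 5)
  sc <- score_asq(co, 12)
  expect_true(all(sc$points %% 5 == 0, na.rm = TRUE))
  expect_true(all(sc$points >= 0 & sc$points <= 60, na.rm = TRUE))
  for (i in c(1, 57, 200)) {
    cols <- paste0("asq12_fine_motor_i", 1:6)
    manual <- score_domain(unlist(co[i, cols], use.names = FALSE))
    got <- sc$points[sc$child_id == co$child_id[i] &
                     sc$domain == "fine_motor"]
    expect_identical(is.na(got), is.na(manual))
    if (!is.na(manual)) expect_equal(got, manual)
  }
})
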