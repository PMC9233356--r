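test_that("degenerate configurations collapse to the intercept and pure slope", {
  # all components switched off -> every value equals the intercept
  cfg <- noiseless_config(dev_slope = 0, learning_increments = c(0, 0, 0),
                          intercept = 0.3)
  d <- simulate_cohort(cfg)
  expect_true(all(d$value == 0.3))

  # pure linear development: slope x elapsed years, subject by subject
  cfg <- noiseless_config(dev_slope = 0.1, learning_increments = c(0, 0, 0))
  d <- simulate_cohort(cfg)
  v1 <- d$value[d$visit == 1]
  v3 <- d$value[d$visit == 3]
  expect_equal(v3 - v1, rep(0.2, length(v1)), tolerance = 1e-12)
})

test_that("simulation is bit-reproducible for a seed and differs across seeds", {
  cfg <- sim_config(n_subjects = 40, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  attr(a, "sim_config") <- attr(b, "sim_config") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(cfg, seed = 6)
  expect_false(isTRUE(all.equal(a$value, c2$value)))
})

test_that("observed minus truth columns reconstruct the configured effects", {
  cfg <- sim_config(n_subjects = 300, dev_slope = 0.08,
                    learning_increments = c(0.5, 0.2, 0.05),
                    noise_sd = 0.5, re_sd = 0.4, seed = 1)
  d <- simulate_cohort(cfg)
  # oracle: the generator's own truth components sum to the configured
  # visit-2 minus visit-1 expectation, 0.08 (dev) + 0.5 (learning)
  tru <- d$dev_component + d$learning_component
  diffs <- tru[d$visit == 2] - tru[d$visit == 1]
  expect_equal(diffs, rep(0.58, length(diffs)), tolerance = 1e-12)
  # empirical within-subject difference agrees up to noise
  obs <- d$value[d$visit == 2] - d$value[d$visit == 1]
  expect_lt(abs(mean(obs) - 0.58), 4 * sd(obs) / sqrt(length(obs)))
  # residual structure: value - truth = random intercept + noise
  expect_equal(d$value, tru + (d$value - tru))
})

test_that("zero-noise simulation reproduces true_trajectory exactly", {
  cfg <- noiseless_config(dev_slope = 0.08, learning_increments = c(0.5, 0.2, 0.05),
                          learning_age_gradient = -0.03, sex_effect = 0.2,
                          sex_learning_multiplier = 1.5)
  d <- simulate_cohort(cfg)
  expected <- mapply(function(a, v, s) true_trajectory(cfg, a, v, s),
                     d$age, d$visit, d$sex)
  expect_equal(d$value, expected, tolerance = 1e-12)
})

test_that("true_trajectory decomposes into development plus learning", {
  cfg <- sim_config(dev_slope = 0, learning_increments = c(0.5, 0.2, 0.05))
  # visit 1 carries no learning
  expect_equal(true_trajectory(cfg, 15, 1), 0)
  # pure learning at visit 2
  expect_equal(true_trajectory(cfg, 15, 2), 0.5)
  # component-sum oracle at visit 3 with a developmental slope
  cfg2 <- sim_config(dev_slope = 0.08, learning_increments = c(0.5, 0.2, 0.05),
                     intercept = 0.1)
  expect_equal(true_trajectory(cfg2, 15, 3),
               0.1 + 0.08 * (15 - cfg2$age_center) + 0.5 + 0.2,
               tolerance = 1e-12)
})

test_that("empirical moments of a large simulation match the configured SDs", {
  cfg <- sim_config(n_subjects = 3000, dev_slope = 0,
                    learning_increments = c(0, 0, 0),
                    noise_sd = 0.5, re_sd = 0.4, seed = 2)
  d <- simulate_cohort(cfg)
  wide <- matrix(d$value, ncol = 4, byrow = TRUE)
  # covariance between visits = re_sd^2; residual variance = noise_sd^2
  cov12 <- cov(wide[, 1], wide[, 2])
  expect_lt(abs(sqrt(cov12) - 0.4) / 0.4, 0.05)
  noise_var <- mean(apply(wide, 1, var))  # E = noise_sd^2 within subject
  expect_lt(abs(sqrt(noise_var) - 0.5) / 0.5, 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(band_weights = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(noise_sd = -1), ">= 0")
  expect_error(sim_config(n_visits = 1), "n_visits")
  expect_error(sim_config(learning_increments = c(0.1, 0.2)), "length")
})

test_that("baseline ages honour the recruitment bands", {
  cfg <- sim_config(n_subjects = 500, seed = 9)
  d <- simulate_cohort(cfg)
  a1 <- d$age[d$visit == 1]
  in_band <- (a1 >= 12 & a1 <= 14) | (a1 >= 15 & a1 <= 17) | (a1 >= 18 & a1 <= 21)
  expect_true(all(in_band))
})

test_that("eligibility filter reproduces the bracketed caps", {
  cr <- drinking_criteria()
  # within both caps for a 16.4-year-old male
  h <- history_row("a", 16.4, "male", 11, 4)
  expect_identical(apply_drinking_filter(h, cr), "a")
  # female cap on drinks per occasion binds at any age
  h <- history_row("b", 17.2, "female", 10, 4)
  expect_identical(apply_drinking_filter(h, cr), character(0))
  # young male over the lifetime-days cap
  h <- history_row("c", 13.0, "male", 6, 2)
  expect_identical(apply_drinking_filter(h, cr), character(0))
})

test_that("filter applies at every visit and rejects bad input", {
  # fails the cap at the second visit only -> excluded entirely
  h <- rbind(history_row("a", 15.5, "male", 5, 3),
             history_row("a", 16.5, "male", 12, 3))
  expect_identical(apply_drinking_filter(h), character(0))
  expect_error(apply_drinking_filter(history_row("a", 11.5, "male", 0, 0)),
               "below 12")
  h_na <- history_row("a", 15, "male", NA, 0)
  expect_error(apply_drinking_filter(h_na), "missing")
})

test_that("raising any cap never shrinks the eligible set", {
  set.seed(4)
  n <- 200
  h <- history_row(sprintf("s%03d", 1:n),
                   runif(n, 12, 22),
                   sample(c("male", "female"), n, TRUE),
                   rpois(n, 8), rpois(n, 3))
  base <- drinking_criteria()
  e0 <- apply_drinking_filter(h, base)
  for (i in seq_len(nrow(base$lifetime_day_caps))) {
    cr <- base
    cr$lifetime_day_caps$cap[i] <- cr$lifetime_day_caps$cap[i] + 5L
    expect_true(all(e0 %in% apply_drinking_filter(h, cr)))
  }
  cr <- base
  cr$per_occasion_caps_female <- cr$per_occasion_caps_female + 2L
  expect_true(all(e0 %in% apply_drinking_filter(h, cr)))
})
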