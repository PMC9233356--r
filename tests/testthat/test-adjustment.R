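test_that("identical cross-sectional structure leaves the data untouched", {
  # same deterministic y = g(age) at every visit -> four identical fits,
  # zero increments, adjusted == raw bit-exact
  set.seed(31)
  n <- 50
  age1 <- runif(n, 12, 21)
  d <- data.frame(
    subject_id = rep(sprintf("s%03d", 1:n), each = 4),
    visit = rep(1:4, n),
    age = as.vector(t(outer(age1, 0:3, `+`))),
    sex = "male", stringsAsFactors = FALSE)
  d$value <- 1 + 0.1 * d$age  # in the spline span: every visit fits it exactly
  fits <- cross_sectional_fits(d)
  grid <- seq(15, 21, by = 0.5)  # common support
  for (t in 2:4) {
    expect_equal(predict(fits$fits[[t]], data.frame(age = grid)),
                 predict(fits$fits[[1]], data.frame(age = grid)),
                 tolerance = 1e-6)
  }
  adj <- adjust_visits(d, fits)
  expect_equal(adj$value_adjusted, adj$value, tolerance = 1e-6)
  # visit-1 rows are bit-identical by construction
  expect_identical(adj$value_adjusted[adj$visit == 1],
                   adj$value[adj$visit == 1])
})

test_that("an age-constant learning offset is recovered as a constant increment", {
  cfg <- noiseless_config(n_subjects = 100, dev_slope = 0.08,
                          learning_increments = c(0.5, 0, 0))
  d <- simulate_cohort(cfg)
  fits <- cross_sectional_fits(d)
  common <- seq(max(fits$fits[[1]]$age_range[1], fits$fits[[2]]$age_range[1]),
                min(fits$fits[[1]]$age_range[2], fits$fits[[2]]$age_range[2]),
                length.out = 25)
  inc <- learning_increment(fits$fits[[1]], fits$fits[[2]], common)
  expect_equal(as.vector(inc), rep(0.5, 25), tolerance = 1e-6)
})

test_that("learning_increment closed forms: identity and linear offset", {
  d <- data.frame(subject_id = sprintf("s%02d", 1:40), visit = 1L,
                  age = seq(12, 21, length.out = 40), sex = "male",
                  stringsAsFactors = FALSE)
  d$value <- 1 + 0.2 * d$age
  f1 <- fit_smooth_age(d, random_intercept = FALSE)
  expect_equal(as.vector(learning_increment(f1, f1, c(13, 16, 19))),
               c(0, 0, 0))
  d2 <- d
  d2$value <- 3 + 0.2 * d2$age
  f2 <- fit_smooth_age(d2, random_intercept = FALSE)
  expect_equal(as.vector(learning_increment(f1, f2, c(13, 16, 19, 25))),
               rep(2, 4), tolerance = 1e-5)
})

test_that("age-graded increments differ across ages by the configured gradient", {
  cfg <- noiseless_config(n_subjects = 400, dev_slope = 0.05,
                          learning_increments = c(0.5, 0.2, 0.1),
                          learning_age_gradient = -0.04, seed = 41)
  d <- simulate_cohort(cfg)
  fits <- cross_sectional_fits(d)
  inc <- learning_increment(fits$fits[[1]], fits$fits[[2]], c(14, 20))
  # oracle from the generator: lambda2(14) - lambda2(20) = -gradient * 6
  expect_equal(inc[1] - inc[2], 0.04 * 6, tolerance = 0.02)
})

test_that("noiseless cumulative learning and adjusted values are exact", {
  cfg <- noiseless_config(n_subjects = 120, dev_slope = 0.08,
                          learning_increments = c(0.4, 0.15, 0.05))
  d <- simulate_cohort(cfg)
  adj <- adjust_visits(d, cross_sectional_fits(d))
  v4 <- adj$cumulative_learning[adj$visit == 4]
  expect_equal(v4, rep(0.60, length(v4)), tolerance = 1e-6)
  expect_equal(adj$value_adjusted, adj$dev_component, tolerance = 1e-6)
})

test_that("two-visit adjustment equals the direct twice-minus-once-tested formula", {
  cfg <- sim_config(n_subjects = 150, n_visits = 2,
                    learning_increments = 0.35, seed = 13)
  d <- simulate_cohort(cfg)
  fits <- cross_sectional_fits(d)
  adj <- adjust_visits(d, fits)
  # direct formula: visit2 - (fit2(age2) - fit1(age2))
  d2 <- adj[adj$visit == 2, ]
  direct <- d2$value - (predict_ages(fits$fits[[2]], d2$age)$fit -
                          predict_ages(fits$fits[[1]], d2$age)$fit)
  expect_equal(d2$value_adjusted, direct, tolerance = 1e-10)
  expect_identical(adj$value_adjusted[adj$visit == 1],
                   adj$value[adj$visit == 1])
})

test_that("cumulative learning is the exact running sum of pair increments", {
  d <- simulate_cohort(sim_config(n_subjects = 80, seed = 19))
  fits <- cross_sectional_fits(d)
  adj <- adjust_visits(d, fits)
  ids <- unique(adj$subject_id)
  # recompute per subject from learning_increment directly
  for (id in ids[1:10]) {
    rows <- adj[adj$subject_id == id, ]
    cum <- 0
    for (v in 2:4) {
      cum <- cum + as.vector(learning_increment(
        fits$fits[[v - 1]], fits$fits[[v]], rows$age[rows$visit == v]))
      expect_equal(rows$cumulative_learning[rows$visit == v], cum,
                   tolerance = 1e-10)
    }
  }
  expect_equal(adj$value_adjusted, adj$value - adj$cumulative_learning)
})

test_that("the current-age convention re-evaluates increments at current ages", {
  d <- simulate_cohort(sim_config(n_subjects = 100, seed = 23,
                                  learning_age_gradient = -0.05))
  fits <- cross_sectional_fits(d)
  eq <- adjust_visits(d, fits, convention = "equation")
  ca <- adjust_visits(d, fits, convention = "current_age")
  # visit 2 is identical under both conventions
  expect_equal(eq$cumulative_learning[eq$visit == 2],
               ca$cumulative_learning[ca$visit == 2], tolerance = 1e-12)
  # later visits differ when increments vary with age
  expect_false(isTRUE(all.equal(eq$cumulative_learning[eq$visit == 4],
                                ca$cumulative_learning[ca$visit == 4])))
  # current-age oracle for one subject at visit 3
  s <- ca[ca$subject_id == ca$subject_id[1], ]
  a3 <- s$age[s$visit == 3]
  expect_equal(s$cumulative_learning[s$visit == 3],
               as.vector(learning_increment(fits$fits[[1]], fits$fits[[2]], a3)) +
                 as.vector(learning_increment(fits$fits[[2]], fits$fits[[3]], a3)),
               tolerance = 1e-10)
})

test_that("subjects with incomplete visit histories are dropped and counted", {
  d <- simulate_cohort(sim_config(n_subjects = 40, seed = 29))
  drop_id <- unique(d$subject_id)[5]
  d$value[d$subject_id == drop_id & d$visit == 3] <- NA
  adj <- adjust_visits(d, cross_sectional_fits(d))
  expect_false(drop_id %in% adj$subject_id)
  expect_identical(attr(adj, "n_excluded"), 1L)
})

test_that("cross_sectional_fits enforces the per-visit sample floor", {
  d <- simulate_cohort(sim_config(n_subjects = 15, seed = 2))
  expect_error(cross_sectional_fits(d, min_n = 20), "min_n")
})

test_that("learning curves: zero under no learning, monotone under a gradient, conserved", {
  d0 <- simulate_cohort(noiseless_config(n_subjects = 200, dev_slope = 0.08,
                                         learning_increments = c(0, 0, 0)))
  curve0 <- cumulative_learning_curve(cross_sectional_fits(d0))
  expect_lt(max(abs(curve0)), 1e-6)

  dg <- simulate_cohort(noiseless_config(n_subjects = 400,
                                         learning_increments = c(0.5, 0.2, 0.05),
                                         learning_age_gradient = -0.05, seed = 37))
  curve <- cumulative_learning_curve(cross_sectional_fits(dg))
  first_pair <- curve["1-2", ]
  expect_lt(first_pair[length(first_pair)], first_pair[1])  # decreasing in age
  # conservation: cumulative row is the exact column sum of the pair rows
  expect_equal(curve["cumulative", ],
               colSums(curve[c("1-2", "2-3", "3-4"), ]), tolerance = 1e-12)
  expect_error(cumulative_learning_curve(cross_sectional_fits(dg),
                                         age_grid = numeric(0)), "empty")
})
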