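#' Configuration for the synthetic cohort-sequential generator
#'
#' Describes an accelerated-longitudinal (cohort-sequential) study in which
#' subjects are recruited in three baseline-age bands and retested annually,
#' with a known developmental age trend, visit-specific practice ("learning")
#' increments that may depend on age and sex, a subject-level random
#' intercept, and observation noise. Scores are in Z units throughout.
#'
#' The observed score for subject i at visit t with age a_it is
#' \deqn{y_{it} = \mu + dev(a_{it}) + \sum_{t' \le t, t' \ge 2}
#'   \lambda_{t'}(a_{it'}) + s_i + b_i + e_{it}}
#' where `dev(a) = dev_slope * (a - age_center)` (or `dev_fn(a)` when given),
#' the per-visit-pair learning increment is
#' `lambda_t(a) = max(0, learning_increments[t-1] +
#' learning_age_gradient * (a - age_center))`, multiplied by
#' `sex_learning_multiplier` for female subjects; `s_i` is `sex_effect` for
#' female subjects, `b_i ~ N(0, re_sd^2)` and `e_it ~ N(0, noise_sd^2)`.
#' Each increment is evaluated at the age at which it accrued (the age at
#' visit `t'`).
#'
#' @param n_subjects number of subjects.
#' @param band_weights recruitment proportions over the three baseline-age
#'   bands; must sum to 1.
#' @param band_ranges list of three `c(lo, hi)` baseline-age bands in years.
#' @param n_visits number of annual visits (>= 2).
#' @param interval years between visits.
#' @param dev_slope developmental trend, Z units per year (linear truth).
#' @param dev_fn optional function age -> Z replacing the linear trend.
#' @param intercept grand mean at `age_center`, Z units.
#' @param age_center centering age for the linear trend and the learning age
#'   gradient (years).
#' @param learning_increments base learning increments for visit pairs
#'   (1,2), (2,3), ... ; length `n_visits - 1`, Z units.
#' @param learning_age_gradient change in each increment per year of age
#'   (negative means younger subjects learn more), Z/year.
#' @param sex_effect additive Z offset for female subjects.
#' @param sex_learning_multiplier multiplier on learning increments for
#'   female subjects (1 = no sex difference in learning).
#' @param p_female probability a subject is female.
#' @param re_sd SD of the subject random intercept (>= 0).
#' @param noise_sd residual SD (>= 0).
#' @param age_jitter_sd SD of jitter on follow-up visit timing (years,
#'   default 0 = exactly annual).
#' @param seed integer seed recorded in the config; used by
#'   [simulate_cohort()] unless overridden.
#' @return an object of class `sim_config`.
#' @seealso [simulate_cohort()], [true_trajectory()]
#' @export
sim_config <- function(n_subjects = 319,
                       band_weights = c(1, 1, 1) / 3,
                       band_ranges = list(c(12, 14), c(15, 17), c(18, 21)),
                       n_visits = 4,
                       interval = 1.0,
                       dev_slope = 0.08,
                       dev_fn = NULL,
                       intercept = 0,
                       age_center = 16.5,
                       learning_increments = c(0.4, 0.15, 0.05),
                       learning_age_gradient = 0,
                       sex_effect = 0,
                       sex_learning_multiplier = 1,
                       p_female = 0.5,
                       re_sd = 0.4,
                       noise_sd = 0.5,
                       age_jitter_sd = 0,
                       seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (length(band_weights) != length(band_ranges)) {
    stop("band_weights and band_ranges must have the same length", call. = FALSE)
  }
  if (any(band_weights < 0) || abs(sum(band_weights) - 1) > 1e-8) {
    stop("band_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_visits < 2) stop("n_visits must be >= 2", call. = FALSE)
  if (noise_sd < 0 || re_sd < 0 || age_jitter_sd < 0) {
    stop("noise_sd, re_sd and age_jitter_sd must be >= 0", call. = FALSE)
  }
  if (length(learning_increments) != n_visits - 1) {
    stop("learning_increments must have length n_visits - 1", call. = FALSE)
  }
  if (!is.null(dev_fn) && !is.function(dev_fn)) {
    stop("dev_fn must be a function of age", call. = FALSE)
  }
  if (p_female < 0 || p_female > 1) stop("p_female must be in [0, 1]", call. = FALSE)
  cfg <- list(
    n_subjects = as.integer(n_subjects), band_weights = band_weights,
    band_ranges = band_ranges, n_visits = as.integer(n_visits),
    interval = interval, dev_slope = dev_slope, dev_fn = dev_fn,
    intercept = intercept, age_center = age_center,
    learning_increments = learning_increments,
    learning_age_gradient = learning_age_gradient,
    sex_effect = sex_effect,
    sex_learning_multiplier = sex_learning_multiplier,
    p_female = p_female, re_sd = re_sd, noise_sd = noise_sd,
    age_jitter_sd = age_jitter_sd, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Developmental component (includes the grand intercept and, for female
# subjects, the additive sex offset): everything systematic that is not
# learning.
dev_value <- function(config, age, female = FALSE) {
  base <- if (is.null(config$dev_fn)) {
    config$dev_slope * (age - config$age_center)
  } else {
    config$dev_fn(age)
  }
  config$intercept + base + ifelse(female, config$sex_effect, 0)
}

# Learning increment gained at visit t (t >= 2), evaluated at the age the
# subject had at that visit; clipped at zero.
lambda_value <- function(config, t, age_at_t, female = FALSE) {
  base <- config$learning_increments[t - 1] +
    config$learning_age_gradient * (age_at_t - config$age_center)
  mult <- ifelse(female, config$sex_learning_multiplier, 1)
  pmax(0, base) * mult
}

#' Simulate a cohort-sequential dataset with known ground truth
#'
#' Draws baseline ages uniformly within the recruitment bands, follows each
#' subject over `n_visits` annual visits, and emits observed scores together
#' with the ground-truth `dev_component` (intercept + developmental trend +
#' sex offset) and `learning_component` (cumulative practice effect) columns.
#' Output is bit-reproducible given `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a long-format `data.frame` with columns `subject_id`, `visit`,
#'   `age`, `sex`, `value`, `dev_component`, `learning_component`, carrying
#'   the config and seed as attributes `sim_config` and `seed`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_subjects
  band <- sample.int(length(config$band_weights), n, replace = TRUE,
                     prob = config$band_weights)
  lo <- vapply(config$band_ranges, `[`, numeric(1), 1)
  hi <- vapply(config$band_ranges, `[`, numeric(1), 2)
  age1 <- stats::runif(n, lo[band], hi[band])
  female <- stats::runif(n) < config$p_female
  b <- stats::rnorm(n, 0, config$re_sd)

  tt <- config$n_visits
  offsets <- (seq_len(tt) - 1) * config$interval
  ages <- outer(age1, offsets, `+`)            # n x tt
  if (config$age_jitter_sd > 0 && tt > 1) {
    jit <- matrix(stats::rnorm(n * (tt - 1), 0, config$age_jitter_sd),
                  n, tt - 1)
    ages[, -1] <- ages[, -1] + jit
    if (any(apply(ages, 1, function(a) any(diff(a) <= 0)))) {
      stop("age_jitter_sd too large: visit ages not strictly increasing",
           call. = FALSE)
    }
  }

  # cumulative learning: increment for pair (t-1, t) accrues at visit t
  learn <- matrix(0, n, tt)
  for (t in 2:tt) {
    learn[, t] <- learn[, t - 1] + lambda_value(config, t, ages[, t], female)
  }
  dev <- dev_value(config, ages, matrix(female, n, tt))
  noise <- matrix(stats::rnorm(n * tt, 0, config$noise_sd), n, tt)

  out <- data.frame(
    subject_id = rep(sprintf("S%04d", seq_len(n)), each = tt),
    visit = rep(seq_len(tt), n),
    age = as.vector(t(ages)),
    sex = rep(ifelse(female, "female", "male"), each = tt),
    value = as.vector(t(dev + learn + b + noise)),
    dev_component = as.vector(t(dev)),
    learning_component = as.vector(t(learn)),
    stringsAsFactors = FALSE)
  attr(out, "sim_config") <- config
  attr(out, "seed") <- as.integer(seed)
  validate_longitudinal(out, "value", contiguous = TRUE)
  out
}

#' Noiseless expected score under a simulation configuration
#'
#' Returns the expectation of the observed score for a subject of the given
#' age at the given visit (no random intercept, no noise). Visit 1 carries no
#' learning; later visits carry the cumulative learning increments, each
#' evaluated at the age the subject had at the visit where it accrued
#' (derived from `age` by subtracting whole inter-visit intervals).
#'
#' @param config a [sim_config()].
#' @param age age in years at `visit`.
#' @param visit visit index within `1:config$n_visits`.
#' @param sex `"male"` or `"female"`.
#' @return expected Z score (vectorized over `age`).
#' @export
true_trajectory <- function(config, age, visit, sex = "male") {
  stopifnot(inherits(config, "sim_config"))
  visit <- as.integer(visit)
  if (visit < 1 || visit > config$n_visits) {
    stop("visit out of range for this config", call. = FALSE)
  }
  female <- sex == "female"
  out <- dev_value(config, age, female)
  if (visit >= 2) {
    for (t in 2:visit) {
      age_at_t <- age - (visit - t) * config$interval
      out <- out + lambda_value(config, t, age_at_t, female)
    }
  }
  out
}
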