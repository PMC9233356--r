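#' Per-visit cross-sectional fits
#'
#' Fits the smoothed-age regression of a score on age separately for each
#' visit, using only that visit's rows (one row per subject, so no random
#' effects; GCV smoothing selection). These cross-sectional fits carry the
#' practice-free developmental age relation at each visit and are the
#' ingredients of the learning adjustment.
#'
#' @param data long-format dataset with all visits present.
#' @param value score column name.
#' @param min_n minimum rows per visit (default 20).
#' @param k spline basis dimension.
#' @return object of class `cs_fit_set`: a list of `age_fit` objects, one
#'   per visit, plus the visit indices and score column name.
#' @export
cross_sectional_fits <- function(data, value = "value", min_n = 20, k = 5) {
  validate_longitudinal(data, value)
  visits <- seq_len(n_visits_present(data))
  fits <- vector("list", length(visits))
  for (t in visits) {
    d <- data[data$visit == t & !is.na(data[[value]]), , drop = FALSE]
    if (nrow(d) < min_n) {
      stop("visit ", t, " has ", nrow(d), " usable rows (< min_n = ",
           min_n, ")", call. = FALSE)
    }
    fits[[t]] <- fit_smooth_age(d, value, random_intercept = FALSE, k = k)
  }
  structure(list(fits = fits, visits = visits, value = value, k = k),
            class = "cs_fit_set")
}

#' Age-dependent learning increment between two cross-sectional fits
#'
#' The estimated learning gained at the current visit is the predicted
#' value from the current visit's cross-sectional fit minus the predicted
#' value from the previous visit's fit, both evaluated at the same ages.
#' Ages beyond a fit's training range are predicted by linear extension
#' from the boundary (see [predict_ages()]).
#'
#' @param fit_prev,fit_curr `age_fit` objects (cross-sectional, age-only).
#' @param ages ages at which to evaluate the increment.
#' @return numeric vector of increments (Z), with logical attribute
#'   `extrapolated` marking ages outside either training range.
#' @export
learning_increment <- function(fit_prev, fit_curr, ages) {
  if (any(!is.finite(ages))) stop("ages must be finite", call. = FALSE)
  pc <- predict_ages(fit_curr, ages)
  pp <- predict_ages(fit_prev, ages)
  out <- pc$fit - pp$fit
  attr(out, "extrapolated") <- pc$extrapolated | pp$extrapolated
  out
}

#' Remove cumulative learning from visits 2 onward
#'
#' Implements the cumulative extension of the twice-minus-once-tested
#' method. For each visit pair (t-1, t) the age-dependent learning
#' increment is estimated from the cross-sectional fits
#' (`fit_t - fit_{t-1}`); the adjusted value at visit v subtracts the sum
#' of increments for all pairs up to v. Visit-1 values are returned
#' unchanged.
#'
#' Under the default `"equation"` convention each pair's increment is
#' evaluated at the subject's age *at the later visit of that pair* and the
#' same number is carried into all later visits (matching the printed form
#' of the adjustment equations). The `"current_age"` convention instead
#' re-evaluates every increment at the subject's age at the visit being
#' adjusted.
#'
#' Only subjects with a non-missing score at every visit are adjusted;
#' others are dropped and counted in attribute `n_excluded`.
#'
#' @param data long-format dataset.
#' @param fits a [cross_sectional_fits()] result for the same score.
#' @param value score column name (defaults to the one the fits used).
#' @param convention `"equation"` or `"current_age"`.
#' @return data.frame of the retained rows plus columns `value_adjusted`
#'   (here named `<value>_adjusted`), `cumulative_learning` and
#'   `extrapolated`; attributes `n_excluded` and `convention`.
#' @export
adjust_visits <- function(data, fits, value = fits$value,
                          convention = c("equation", "current_age")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fits, "cs_fit_set"))
  validate_longitudinal(data, value)
  tt <- length(fits$fits)
  if (n_visits_present(data) != tt) {
    stop("dataset has ", n_visits_present(data), " visits but fits cover ",
         tt, call. = FALSE)
  }
  keep_ids <- complete_subjects(data, value, seq_len(tt))
  n_excluded <- length(unique(data$subject_id)) - length(keep_ids)
  d <- data[data$subject_id %in% keep_ids, , drop = FALSE]
  d <- d[order(d$subject_id, d$visit), , drop = FALSE]

  ns <- length(keep_ids)
  age_m <- matrix(d$age, nrow = ns, ncol = tt, byrow = TRUE)  # subjects x visits
  cum <- matrix(0, ns, tt)
  extra <- matrix(FALSE, ns, tt)
  for (v in 2:tt) {
    if (convention == "equation") {
      # increment for pair (v-1, v) at ages of visit v, carried forward
      inc <- learning_increment(fits$fits[[v - 1]], fits$fits[[v]], age_m[, v])
      cum[, v] <- cum[, v - 1] + inc
      extra[, v] <- extra[, v - 1] | attr(inc, "extrapolated")
    } else {
      # all increments re-evaluated at the current visit's ages
      for (t in 2:v) {
        inc <- learning_increment(fits$fits[[t - 1]], fits$fits[[t]], age_m[, v])
        cum[, v] <- cum[, v] + inc
        extra[, v] <- extra[, v] | attr(inc, "extrapolated")
      }
    }
  }
  adj_col <- paste0(value, "_adjusted")
  d$cumulative_learning <- as.vector(t(cum))
  d[[adj_col]] <- d[[value]] - d$cumulative_learning
  d$extrapolated <- as.vector(t(extra))
  attr(d, "n_excluded") <- n_excluded
  attr(d, "convention") <- convention
  attr(d, "adjusted_value") <- adj_col
  d
}

#' Learning curves over an age grid
#'
#' Evaluates each visit pair's estimated learning increment, and their
#' cumulative sum, over a grid of ages (by default 101 points spanning the
#' age range common to all cross-sectional fits).
#'
#' @param fits a [cross_sectional_fits()] result.
#' @param age_grid optional numeric vector of ages.
#' @param clip clip the default grid to the common age support.
#' @return numeric matrix with one row per visit pair (named `"1-2"`, ...)
#'   plus a final `"cumulative"` row; columns are grid ages (attribute
#'   `age`).
#' @export
cumulative_learning_curve <- function(fits, age_grid = NULL, clip = TRUE) {
  stopifnot(inherits(fits, "cs_fit_set"))
  if (is.null(age_grid)) {
    lo <- max(vapply(fits$fits, function(f) f$age_range[1], numeric(1)))
    hi <- min(vapply(fits$fits, function(f) f$age_range[2], numeric(1)))
    if (!clip) {
      lo <- min(vapply(fits$fits, function(f) f$age_range[1], numeric(1)))
      hi <- max(vapply(fits$fits, function(f) f$age_range[2], numeric(1)))
    }
    age_grid <- seq(lo, hi, length.out = 101)
  }
  if (length(age_grid) == 0) stop("empty age grid", call. = FALSE)
  tt <- length(fits$fits)
  out <- matrix(NA_real_, tt - 1 + 1, length(age_grid))
  rownames(out) <- c(sprintf("%d-%d", seq_len(tt - 1), 2:tt), "cumulative")
  for (v in 2:tt) {
    out[v - 1, ] <- as.vector(
      learning_increment(fits$fits[[v - 1]], fits$fits[[v]], age_grid))
  }
  out["cumulative", ] <- colSums(out[seq_len(tt - 1), , drop = FALSE])
  attr(out, "age") <- age_grid
  out
}
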