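#' Fit developmental trajectories and decide their shape
#'
#' Fits both the smoothed-age and the linear-age model across all visits
#' (with a subject random intercept, and optionally sex as a factor),
#' compares them by LRT to decide whether development is better described
#' as smooth or linear, and tests the sex effect by comparing the chosen
#' shape with and without sex.
#'
#' @param data long-format dataset (raw or learning-adjusted).
#' @param value score column name (e.g. `"value"` or `"value_adjusted"`).
#' @param include_sex include sex as a factor in the trajectory models.
#' @param threshold significance threshold for preferring the smooth shape
#'   (default the Bonferroni 0.00625).
#' @param k spline basis dimension.
#' @return object of class `development_fit`: `shape` (`"linear"` or
#'   `"smooth"`), `slope` and `slope_se` (Z-units/year from the linear
#'   model), `shape_comparison`, `sex_comparison`, and the two fits.
#' @export
fit_development <- function(data, value = "value", include_sex = TRUE,
                            threshold = bonferroni_threshold(), k = 5) {
  sm <- fit_smooth_age(data, value, sex_effect = include_sex,
                       random_intercept = TRUE, k = k)
  ln <- fit_linear_age(data, value, sex_effect = include_sex,
                       random_intercept = TRUE)
  shape_cmp <- compare_models(ln, sm)
  shape <- if (shape_cmp$p_value <= threshold) "smooth" else "linear"
  sex_cmp <- NULL
  if (include_sex) {
    if (shape == "smooth") {
      base <- fit_smooth_age(data, value, sex_effect = FALSE,
                             random_intercept = TRUE, k = k)
      sex_cmp <- compare_models(base, sm)
    } else {
      base <- fit_linear_age(data, value, sex_effect = FALSE,
                             random_intercept = TRUE)
      sex_cmp <- compare_models(base, ln)
    }
  }
  structure(list(
    shape = shape, slope = ln$slope, slope_se = ln$slope_se,
    shape_comparison = shape_cmp, sex_comparison = sex_cmp,
    smooth_fit = sm, linear_fit = ln, threshold = threshold,
    value = value, n = ln$n),
    class = "development_fit")
}

#' @export
print.development_fit <- function(x, ...) {
  cat(sprintf("Development (%s): shape = %s (LRT p = %.4g), slope = %.4f Z/yr (SE %.4f)\n",
              x$value, x$shape, x$shape_comparison$p_value, x$slope, x$slope_se))
  invisible(x)
}

#' Cross-sectional, unadjusted and learning-adjusted slopes
#'
#' Computes the three rates of change per year that summarize the effect of
#' the learning adjustment: the slope of the simple linear regression on
#' the baseline (visit-1) cross-section, and the longitudinal rates of
#' change from linear mixed models (subject random intercepts) on all
#' visits of the raw and of the learning-adjusted scores.
#'
#' In a cohort-sequential design, regressing on a single age term would mix
#' the within-person rate of change with the practice-free between-cohort
#' age relation, understating the inflation due to practice. The
#' longitudinal models therefore disaggregate age into baseline age and
#' years since baseline (`y ~ baseline_age + time`, random intercept per
#' subject); the reported longitudinal slope is the `time` fixed effect,
#' the within-person rate of change per year.
#'
#' @param raw long-format dataset with the raw score column; defaults to
#'   `adjusted`, which retains the raw column alongside the adjusted one.
#' @param adjusted an [adjust_visits()] result.
#' @param value raw score column name.
#' @param adjusted_value adjusted score column name (default
#'   `<value>_adjusted`).
#' @return data.frame with rows `cross_sectional_baseline`,
#'   `longitudinal_unadjusted`, `longitudinal_adjusted` and columns
#'   `slope`, `se`. All three slopes are computed on the adjusted
#'   dataset's rows (subjects with complete visit histories).
#' @export
slope_triptych <- function(adjusted, raw = adjusted, value = "value",
                           adjusted_value = paste0(value, "_adjusted")) {
  validate_longitudinal(adjusted, value)
  if (!adjusted_value %in% names(adjusted)) {
    stop("adjusted score column ", adjusted_value, " not found", call. = FALSE)
  }
  key <- function(d) paste(d$subject_id, d$visit, sep = "\r")
  if (!all(key(adjusted) %in% key(raw))) {
    stop("adjusted rows are not a subset of the raw dataset's rows",
         call. = FALSE)
  }
  base <- adjusted[adjusted$visit == 1L, , drop = FALSE]
  cs <- stats::lm(stats::reformulate("age", value), data = base)
  cs_cf <- summary(cs)$coefficients
  age0 <- base$age[match(adjusted$subject_id, base$subject_id)]
  if (anyNA(age0)) {
    stop("every subject needs a visit-1 row to anchor the time axis",
         call. = FALSE)
  }
  d <- data.frame(age0 = age0, time = adjusted$age - age0,
                  subject_id = factor(adjusted$subject_id))
  long_slope <- function(col) {
    d$.y <- adjusted[[col]]
    m <- nlme::lme(.y ~ age0 + time, random = ~ 1 | subject_id,
                   data = d[!is.na(d$.y), ], method = "ML",
                   control = robust_lme_control())
    tt <- summary(m)$tTable
    c(unname(tt["time", "Value"]), unname(tt["time", "Std.Error"]))
  }
  unadj <- long_slope(value)
  adj <- long_slope(adjusted_value)
  data.frame(
    component = c("cross_sectional_baseline", "longitudinal_unadjusted",
                  "longitudinal_adjusted"),
    slope = c(unname(cs_cf["age", "Estimate"]), unadj[1], adj[1]),
    se = c(unname(cs_cf["age", "Std. Error"]), unadj[2], adj[2]),
    stringsAsFactors = FALSE)
}

#' Developmental summary report across composites
#'
#' For each requested score column: estimates the per-visit cross-sectional
#' fits, removes cumulative learning, fits developmental trajectories
#' before and after adjustment, and computes the slope triptych. One row
#' per composite.
#'
#' @param data long-format dataset with the score columns.
#' @param values character vector of score column names.
#' @param threshold significance threshold for shape and sex decisions.
#' @param include_sex include sex in the trajectory models.
#' @param convention adjustment age convention (see [adjust_visits()]).
#' @param k spline basis dimension.
#' @param min_n minimum rows per visit for the cross-sectional fits.
#' @return data.frame with per-composite shapes, slopes and p-values before
#'   and after learning adjustment.
#' @export
developmental_report <- function(data, values = "value",
                                 threshold = bonferroni_threshold(),
                                 include_sex = TRUE,
                                 convention = "equation",
                                 k = 5, min_n = 20) {
  rows <- list()
  for (v in values) {
    fits <- cross_sectional_fits(data, v, min_n = min_n, k = k)
    adj <- adjust_visits(data, fits, convention = convention)
    before <- fit_development(adj, v, include_sex, threshold, k)
    after <- fit_development(adj, paste0(v, "_adjusted"), include_sex,
                             threshold, k)
    tri <- slope_triptych(adj, value = v)
    rows[[length(rows) + 1]] <- data.frame(
      composite = v, n = before$n,
      shape_unadjusted = before$shape,
      p_shape_unadjusted = before$shape_comparison$p_value,
      shape_adjusted = after$shape,
      p_shape_adjusted = after$shape_comparison$p_value,
      slope_cross_sectional = tri$slope[1],
      slope_unadjusted = tri$slope[2],
      slope_adjusted = tri$slope[3],
      p_sex_adjusted = after$sex_comparison$p_value %||% NA_real_,
      threshold = threshold,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
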