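#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return `alpha / m` (e.g. 0.05 / 8 = 0.00625).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 8L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Extract a consecutive visit-pair dataset
#'
#' Returns the rows of visits `t` and `t + 1` for subjects observed (with a
#' non-missing score) at both; other subjects are dropped pair-wise, and the
#' number dropped is recorded in attribute `n_excluded`.
#'
#' @param data long-format dataset.
#' @param t first visit of the pair.
#' @param value score column name.
#' @return subset data.frame with attributes `pair` and `n_excluded`.
#' @export
pair_dataset <- function(data, t, value = "value") {
  validate_longitudinal(data, value)
  t <- as.integer(t)
  visits <- c(t, t + 1L)
  if (!all(visits %in% data$visit)) {
    stop("visits ", t, " and ", t + 1, " are not both present", call. = FALSE)
  }
  sub <- data[data$visit %in% visits, , drop = FALSE]
  keep_ids <- complete_subjects(sub, value, visits)
  all_ids <- unique(sub$subject_id)
  out <- sub[sub$subject_id %in% keep_ids & !is.na(sub[[value]]), , drop = FALSE]
  if (nrow(out) == 0) stop("no complete subjects for pair (", t, ", ",
                           t + 1, ")", call. = FALSE)
  attr(out, "pair") <- visits
  attr(out, "n_excluded") <- length(all_ids) - length(keep_ids)
  out
}

#' Test for age-dependent learning in a visit pair
#'
#' Compares the smoothed-age + visit model against a model with separate
#' age smooths per visit (age-by-visit interaction), both with a subject
#' random intercept. A significant improvement indicates that the learning
#' increment varies with age.
#'
#' @param pair a [pair_dataset()] result.
#' @param value score column name.
#' @param k spline basis dimension.
#' @return a [compare_models()] result.
#' @export
test_age_by_learning <- function(pair, value = "value", k = 5) {
  m1 <- fit_smooth_age(pair, value, visit_effect = TRUE,
                       random_intercept = TRUE, k = k)
  m2 <- fit_smooth_age(pair, value, age_by_visit = TRUE,
                       random_intercept = TRUE, k = k)
  compare_models(m1, m2)
}

#' Test for sex-dependent learning in a visit pair
#'
#' On top of the age-by-visit model with a sex main effect, adds a
#' sex-by-visit interaction and compares by LRT. Requires both sexes to be
#' present.
#'
#' @inheritParams test_age_by_learning
#' @return a [compare_models()] result.
#' @export
test_sex_by_learning <- function(pair, value = "value", k = 5) {
  ma <- fit_smooth_age(pair, value, age_by_visit = TRUE, sex_effect = TRUE,
                       random_intercept = TRUE, k = k)
  mb <- fit_smooth_age(pair, value, age_by_visit = TRUE, sex_by_visit = TRUE,
                       random_intercept = TRUE, k = k)
  compare_models(ma, mb)
}

#' Quantify visit-to-visit learning for one visit pair
#'
#' Fits the smoothed-age model without and with visit as a factor (both
#' with a subject random intercept), compares them by LRT, and reports the
#' gain in adjusted R-squared as the learning index, together with
#' age-by-visit and sex-by-visit interaction tests.
#'
#' @param pair a [pair_dataset()] result.
#' @param threshold per-test significance threshold (default the Bonferroni
#'   0.05/8 = 0.00625).
#' @param value score column name.
#' @param interactions also run the age-by-visit and sex-by-visit tests.
#' @param k spline basis dimension.
#' @return object of class `learning_estimate`: `pair`, `r2_age_only`,
#'   `r2_age_plus_visit`, `delta_r2`, `pct_due_to_learning` (100 *
#'   delta_r2 / r2_age_only; can exceed 100), `pct_of_full` (alternative
#'   denominator r2_age_plus_visit), `l_ratio`, `p_value`, `visit_coef`,
#'   `significant`, `age_interaction`, `sex_interaction`.
#' @export
estimate_learning <- function(pair, threshold = bonferroni_threshold(),
                              value = "value", interactions = TRUE, k = 5) {
  pr <- attr(pair, "pair") %||% sort(unique(as.integer(pair$visit)))
  if (length(unique(pair$visit)) != 2) {
    stop("`pair` must contain exactly two visits", call. = FALSE)
  }
  m0 <- fit_smooth_age(pair, value, random_intercept = TRUE, k = k)
  m1 <- fit_smooth_age(pair, value, visit_effect = TRUE,
                       random_intercept = TRUE, k = k)
  cmp <- compare_models(m0, m1)
  vc_name <- paste0("visit", max(pr))
  visit_coef <- unname(m1$coefficients[vc_name])
  age_int <- sex_int <- NULL
  if (interactions) {
    age_int <- test_age_by_learning(pair, value, k)
    sex_int <- tryCatch(test_sex_by_learning(pair, value, k),
                        error = function(e) NULL)
  }
  structure(list(
    pair = pr,
    r2_age_only = m0$r2, r2_age_plus_visit = m1$r2,
    delta_r2 = cmp$delta_r2,
    pct_due_to_learning = 100 * cmp$delta_r2 / m0$r2,
    pct_of_full = 100 * cmp$delta_r2 / m1$r2,
    l_ratio = cmp$l_ratio, df = cmp$df, p_value = cmp$p_value,
    visit_coef = visit_coef,
    threshold = threshold,
    significant = cmp$p_value <= threshold,
    age_interaction = age_int, sex_interaction = sex_int,
    n = m1$n),
    class = "learning_estimate")
}

#' @export
print.learning_estimate <- function(x, ...) {
  cat(sprintf("Learning, visits %d-%d: delta R2 = %.4f (%.1f%% of age-only R2), L = %.3f, p = %.4g%s\n",
              x$pair[1], x$pair[2], x$delta_r2, x$pct_due_to_learning,
              x$l_ratio, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Learning table across visit pairs and composites
#'
#' Runs [estimate_learning()] for every consecutive visit pair of every
#' requested score column, mirroring a per-composite learning summary
#' table (delta R-squared, percent due to learning, LRT statistic and
#' p-values, interaction p-values, Bonferroni significance flag).
#'
#' @param data long-format dataset.
#' @param values character vector of score column names.
#' @param threshold per-test significance threshold.
#' @param interactions include interaction tests.
#' @param k spline basis dimension.
#' @return data.frame with one row per composite x visit pair.
#' @export
learning_table <- function(data, values = "value",
                           threshold = bonferroni_threshold(),
                           interactions = TRUE, k = 5) {
  tt <- n_visits_present(data)
  rows <- list()
  for (v in values) {
    for (t in seq_len(tt - 1)) {
      est <- estimate_learning(pair_dataset(data, t, v), threshold, v,
                               interactions, k)
      rows[[length(rows) + 1]] <- data.frame(
        composite = v, pair = sprintf("%d-%d", t, t + 1),
        n = est$n,
        r2_age = est$r2_age_only, r2_age_visit = est$r2_age_plus_visit,
        delta_r2 = est$delta_r2, pct_learning = est$pct_due_to_learning,
        l_ratio = est$l_ratio, p = est$p_value,
        p_age_by_visit = est$age_interaction$p_value %||% NA_real_,
        p_sex_by_visit = est$sex_interaction$p_value %||% NA_real_,
        significant = est$significant,
        threshold = threshold,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
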