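#' @importFrom mgcv gam gamm s
#' @importFrom nlme lme fixef VarCorr
NULL

# optimizer settings that also cope with degenerate (zero-variance)
# random-intercept fits, e.g. noise-free validation data
robust_lme_control <- function() {
  nlme::lmeControl(opt = "optim", msMaxIter = 200, returnObject = TRUE)
}

# mean-structure effective degrees of freedom of a gam: parametric
# coefficients plus penalized-smooth edf (random-effect smooths excluded).
mean_edf <- function(g) {
  sm <- 0
  for (s in g$smooth) {
    if (inherits(s, "random.effect")) next
    sm <- sm + sum(g$edf[s$first.para:s$last.para])
  }
  g$nsdf + sm
}

prepare_fit_data <- function(data, value, need_sex, need_visit, need_subject) {
  validate_longitudinal(data, value)
  d <- data.frame(
    .y = data[[value]],
    age = data$age,
    visit = factor(data$visit),
    sex = factor(data$sex, levels = c("male", "female")),
    subject_id = factor(data$subject_id))
  keep <- !is.na(d$.y) & !is.na(d$age)
  if (need_sex) keep <- keep & !is.na(d$sex)
  d <- droplevels(d[keep, , drop = FALSE])
  if (nrow(d) < 10) stop("fewer than 10 usable rows", call. = FALSE)
  if (stats::var(d$age) == 0) {
    stop("singular design: term s(age) has no age variation", call. = FALSE)
  }
  if (need_visit && nlevels(d$visit) < 2) {
    stop("singular design: term visit has a single level", call. = FALSE)
  }
  if (need_sex && nlevels(d$sex) < 2) {
    stop("singular design: term sex has a single level (both sexes required)",
         call. = FALSE)
  }
  d
}

finish_age_fit <- function(m, d, mixed, shape, value, terms, method, k) {
  gamm_fit <- mixed && shape == "smooth"
  g <- if (gamm_fit) m$gam else m
  ll <- if (gamm_fit) stats::logLik(m$lme) else stats::logLik(m)
  r2 <- if (shape == "smooth") {
    summary(g)$r.sq
  } else if (mixed) {
    pred <- as.vector(stats::predict(m, level = 0))
    p <- length(nlme::fixef(m))
    n <- nrow(d)
    raw <- 1 - sum((d$.y - pred)^2) / sum((d$.y - mean(d$.y))^2)
    1 - (1 - raw) * (n - 1) / (n - p - 1)
  } else {
    summary(m)$adj.r.squared
  }
  edf <- if (shape == "smooth") mean_edf(g) else {
    length(if (mixed) nlme::fixef(m) else stats::coef(m))
  }
  slope <- slope_se <- NULL
  if (shape == "linear") {
    if (mixed) {
      tt <- summary(m)$tTable
      slope <- unname(tt["age", "Value"]); slope_se <- unname(tt["age", "Std.Error"])
    } else {
      cf <- summary(m)$coefficients
      slope <- unname(cf["age", "Estimate"]); slope_se <- unname(cf["age", "Std. Error"])
    }
  }
  re_var <- if (mixed) {
    vc <- nlme::VarCorr(if (shape == "smooth") m$lme else m)
    as.numeric(vc["(Intercept)", "Variance"])
  } else NULL
  structure(list(
    model = m, mixed = mixed, shape = shape, value = value, terms = terms,
    method = method, k = k, n = nrow(d),
    logLik = as.numeric(ll), ll_df = attr(ll, "df"),
    edf = edf, r2 = r2, slope = slope, slope_se = slope_se,
    re_var = re_var,
    age_range = range(d$age), y_checksum = sum(d$.y),
    coefficients = if (shape == "smooth") stats::coef(g) else
      if (mixed) nlme::fixef(m) else stats::coef(m)),
    class = "age_fit")
}

#' Fit a penalized-spline ("smoothed age") trajectory model
#'
#' Regresses a score on a penalized cubic regression spline of age with 3
#' interior knots at age quantiles (`mgcv` basis `"cr"` with `k = 5`),
#' optionally with a visit factor, separate smooths per visit
#' (`age_by_visit`), a sex factor, and a sex-by-visit interaction.
#'
#' Fits without a subject random intercept (one row per subject, e.g.
#' per-visit cross-sectional fits) use [mgcv::gam()] with GCV smoothing
#' selection. Fits with repeated subjects include a subject random intercept
#' and use [mgcv::gamm()] (nlme backend) with maximum likelihood, so nested
#' fixed-structure models can be compared by a marginal likelihood-ratio
#' test via [compare_models()].
#'
#' @param data long-format dataset.
#' @param value score column name.
#' @param visit_effect include visit as a factor.
#' @param age_by_visit separate age smooths per visit level (implies
#'   `visit_effect`).
#' @param sex_effect include sex as a factor.
#' @param sex_by_visit include a sex-by-visit interaction (implies
#'   `sex_effect` and `visit_effect`).
#' @param random_intercept include a per-subject random intercept; default
#'   `NULL` = automatic (TRUE when any subject has repeated rows).
#' @param k spline basis dimension (`k = 5` gives 3 interior knots).
#' @param method smoothing/estimation method; default `"GCV.Cp"` for fixed
#'   fits and `"ML"` for mixed fits; `"REML"` accepted for either.
#' @return an object of class `age_fit` with fields `edf` (mean-structure
#'   effective degrees of freedom), `logLik`, `r2` (adjusted), `age_range`,
#'   `re_var` and the underlying `mgcv` model.
#' @export
fit_smooth_age <- function(data, value = "value",
                           visit_effect = FALSE, age_by_visit = FALSE,
                           sex_effect = FALSE, sex_by_visit = FALSE,
                           random_intercept = NULL, k = 5, method = NULL) {
  if (age_by_visit) visit_effect <- TRUE
  if (sex_by_visit) { sex_effect <- TRUE; visit_effect <- TRUE }
  d <- prepare_fit_data(data, value, sex_effect, visit_effect, TRUE)
  if (is.null(random_intercept)) {
    random_intercept <- anyDuplicated(d$subject_id) > 0
  }
  rhs <- if (age_by_visit) {
    sprintf("s(age, bs='cr', k=%d, by=visit) + visit", k)
  } else {
    sprintf("s(age, bs='cr', k=%d)", k)
  }
  if (visit_effect && !age_by_visit) rhs <- paste(rhs, "+ visit")
  if (sex_effect) rhs <- paste(rhs, "+ sex")
  if (sex_by_visit) rhs <- paste(rhs, "+ sex:visit")
  f <- stats::as.formula(paste(".y ~", rhs))
  terms <- list(shape = 1L, visit_effect = visit_effect,
                age_by_visit = age_by_visit, sex_effect = sex_effect,
                sex_by_visit = sex_by_visit)
  m <- tryCatch({
    if (random_intercept) {
      mgcv::gamm(f, random = list(subject_id = ~1), data = d,
                 method = method %||% "ML")
    } else {
      mgcv::gam(f, data = d, method = method %||% "GCV.Cp")
    }
  }, error = function(e) {
    stop("smooth age fit failed for terms [", rhs, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  finish_age_fit(m, d, random_intercept, "smooth", value, terms,
                 method %||% if (random_intercept) "ML" else "GCV.Cp", k)
}

#' Fit a linear-age trajectory model
#'
#' Same factor structure as [fit_smooth_age()] but with a linear age term.
#' Fixed-effects-only fits use [stats::lm()]; fits with a subject random
#' intercept use [nlme::lme()] with maximum likelihood. The fitted Z-unit
#' change per year is exposed as `slope` (with `slope_se`).
#'
#' @inheritParams fit_smooth_age
#' @param age_by_visit include an age-by-visit (slope) interaction.
#' @return an object of class `age_fit` with `shape = "linear"`.
#' @export
fit_linear_age <- function(data, value = "value",
                           visit_effect = FALSE, age_by_visit = FALSE,
                           sex_effect = FALSE, sex_by_visit = FALSE,
                           random_intercept = NULL, method = NULL) {
  if (age_by_visit) visit_effect <- TRUE
  if (sex_by_visit) { sex_effect <- TRUE; visit_effect <- TRUE }
  d <- prepare_fit_data(data, value, sex_effect, visit_effect, TRUE)
  if (is.null(random_intercept)) {
    random_intercept <- anyDuplicated(d$subject_id) > 0
  }
  rhs <- "age"
  if (visit_effect) rhs <- paste(rhs, "+ visit")
  if (age_by_visit) rhs <- paste(rhs, "+ age:visit")
  if (sex_effect) rhs <- paste(rhs, "+ sex")
  if (sex_by_visit) rhs <- paste(rhs, "+ sex:visit")
  f <- stats::as.formula(paste(".y ~", rhs))
  terms <- list(shape = 0L, visit_effect = visit_effect,
                age_by_visit = age_by_visit, sex_effect = sex_effect,
                sex_by_visit = sex_by_visit)
  m <- tryCatch({
    if (random_intercept) {
      nlme::lme(f, random = ~ 1 | subject_id, data = d,
                method = method %||% "ML", control = robust_lme_control())
    } else {
      stats::lm(f, data = d)
    }
  }, error = function(e) {
    stop("linear age fit failed for terms [", rhs, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  finish_age_fit(m, d, random_intercept, "linear", value, terms,
                 method %||% if (random_intercept) "ML" else "OLS", NULL)
}

#' Predict expected scores from an age trajectory fit
#'
#' Population-level predictions (random effects excluded). `newdata` must
#' supply `age` plus any factor the fit includes (`visit`, `sex`).
#'
#' @param object an `age_fit`.
#' @param newdata data.frame of covariate values.
#' @param ... unused.
#' @return numeric vector of expected scores.
#' @export
predict.age_fit <- function(object, newdata, ...) {
  if (!is.null(newdata$visit)) newdata$visit <- factor(newdata$visit)
  if (!is.null(newdata$sex)) {
    newdata$sex <- factor(newdata$sex, levels = c("male", "female"))
  }
  if (object$shape == "smooth") {
    g <- if (object$mixed) object$model$gam else object$model
    as.vector(stats::predict(g, newdata = newdata, type = "response"))
  } else if (object$mixed) {
    as.vector(stats::predict(object$model, newdata = newdata, level = 0))
  } else {
    as.vector(stats::predict(object$model, newdata = newdata))
  }
}

#' Predict over ages with linear extrapolation beyond the training range
#'
#' Inside the fit's observed age range this is the ordinary model
#' prediction; outside, predictions extend linearly from the boundary using
#' the boundary slope (finite difference). Intended for age-only
#' cross-sectional fits, where a later visit's oldest subjects exceed the
#' previous visit's age range.
#'
#' @param fit an age-only `age_fit`.
#' @param ages numeric vector of ages.
#' @return list with `fit` (predictions) and `extrapolated` (logical,
#'   per age).
#' @export
predict_ages <- function(fit, ages) {
  stopifnot(inherits(fit, "age_fit"))
  if (isTRUE(fit$terms$visit_effect) || isTRUE(fit$terms$sex_effect)) {
    stop("predict_ages() requires an age-only fit", call. = FALSE)
  }
  r <- fit$age_range
  inner <- pmin(pmax(ages, r[1]), r[2])
  h <- 1e-3 * diff(r)
  p <- predict(fit, data.frame(age = c(inner, r[1], r[1] + h, r[2] - h, r[2])))
  n <- length(ages)
  base <- p[seq_len(n)]
  d_lo <- (p[n + 2] - p[n + 1]) / h
  d_hi <- (p[n + 4] - p[n + 3]) / h
  below <- ages < r[1]
  above <- ages > r[2]
  base[below] <- base[below] + d_lo * (ages[below] - r[1])
  base[above] <- base[above] + d_hi * (ages[above] - r[2])
  list(fit = base, extrapolated = below | above)
}

#' Likelihood-ratio comparison of two nested trajectory fits
#'
#' The smaller model must be nested in the larger (same response rows, same
#' random-effect structure, term set a subset, linear nested in smooth).
#' For mixed fits the test uses the marginal (nlme) likelihood with degrees
#' of freedom equal to the difference in likelihood parameter counts; for
#' fixed-effects fits it uses the fit likelihood with fractional degrees of
#' freedom equal to the difference in mean-structure effective degrees of
#' freedom. The p-value comes from the chi-square distribution.
#'
#' @param smaller,larger `age_fit` objects fitted to the same rows.
#' @return object of class `model_comparison` with fields `l_ratio`
#'   (2 x delta logLik, floored at 0), `df`, `p_value`, `delta_r2` (signed,
#'   larger minus smaller).
#' @export
compare_models <- function(smaller, larger) {
  stopifnot(inherits(smaller, "age_fit"), inherits(larger, "age_fit"))
  if (smaller$n != larger$n ||
      abs(smaller$y_checksum - larger$y_checksum) > 1e-6 * max(1, abs(smaller$y_checksum))) {
    stop("models were not fitted to the same response rows", call. = FALSE)
  }
  if (smaller$mixed != larger$mixed) {
    stop("models must share the same random-effect structure", call. = FALSE)
  }
  flags <- c("visit_effect", "age_by_visit", "sex_effect", "sex_by_visit")
  nested <- smaller$terms$shape <= larger$terms$shape &&
    all(vapply(flags, function(f)
      !isTRUE(smaller$terms[[f]]) || isTRUE(larger$terms[[f]]), logical(1)))
  if (!nested) stop("models are not nested", call. = FALSE)
  l_ratio <- max(0, 2 * (larger$logLik - smaller$logLik))
  df <- if (smaller$mixed) larger$ll_df - smaller$ll_df else
    larger$edf - smaller$edf
  df <- max(df, 0)
  p <- if (df < 1e-8) 1 else
    stats::pchisq(l_ratio, df = df, lower.tail = FALSE)
  structure(list(l_ratio = l_ratio, df = df, p_value = p,
                 delta_r2 = larger$r2 - smaller$r2, n = larger$n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("LRT: L = %.4f on %.2f df, p = %.4g, delta R2 = %.4f (n = %d)\n",
              x$l_ratio, x$df, x$p_value, x$delta_r2, x$n))
  invisible(x)
}

#' @export
print.age_fit <- function(x, ...) {
  cat(sprintf("%s age fit (%s): n = %d, edf = %.2f, logLik = %.2f, adj R2 = %.4f\n",
              x$shape, if (x$mixed) "subject random intercept" else "fixed effects",
              x$n, x$edf, x$logLik, x$r2))
  if (!is.null(x$slope)) {
    cat(sprintf("  slope = %.4f Z/year (SE %.4f)\n", x$slope, x$slope_se))
  }
  invisible(x)
}
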