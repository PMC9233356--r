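#' No-to-low drinking eligibility criteria
#'
#' Age-bracketed caps defining a "no-to-low" drinker: a cap on maximum
#' lifetime drinking days (same for both sexes) and a cap on maximum drinks
#' per occasion (constant for female participants, age-graded for male
#' participants). Age brackets are closed-open, e.g. "16 to 16.9 years" is
#' [16, 17).
#'
#' @param lifetime_day_caps data.frame with columns `lo`, `hi`, `cap` giving
#'   the maximum lifetime drinking days by age bracket.
#' @param per_occasion_caps_female single non-negative integer cap applying
#'   at any age.
#' @param per_occasion_caps_male data.frame with columns `lo`, `hi`, `cap`.
#' @return an object of class `drinking_criteria`.
#' @export
drinking_criteria <- function(
    lifetime_day_caps = data.frame(
      lo = c(12, 16, 17, 18), hi = c(16, 17, 18, Inf),
      cap = c(5L, 11L, 23L, 51L)),
    per_occasion_caps_female = 3L,
    per_occasion_caps_male = data.frame(
      lo = c(12, 14, 20), hi = c(14, 20, Inf), cap = c(3L, 4L, 5L))) {
  check_brackets <- function(df, what) {
    if (!all(c("lo", "hi", "cap") %in% names(df))) {
      stop(what, " must have columns lo, hi, cap", call. = FALSE)
    }
    df <- df[order(df$lo), ]
    if (df$lo[1] > 12 || any(df$hi[-nrow(df)] != df$lo[-1])) {
      stop(what, " brackets must partition the age axis from 12 with no gaps",
           call. = FALSE)
    }
    if (any(df$cap < 0) || any(df$cap != floor(df$cap))) {
      stop(what, " caps must be non-negative integers", call. = FALSE)
    }
    df
  }
  cr <- list(
    lifetime_day_caps = check_brackets(lifetime_day_caps, "lifetime_day_caps"),
    per_occasion_caps_female = as.integer(per_occasion_caps_female),
    per_occasion_caps_male = check_brackets(per_occasion_caps_male,
                                            "per_occasion_caps_male"))
  if (cr$per_occasion_caps_female < 0) {
    stop("per_occasion_caps_female must be non-negative", call. = FALSE)
  }
  class(cr) <- "drinking_criteria"
  cr
}

bracket_cap <- function(brackets, age) {
  idx <- findInterval(age, c(brackets$lo, Inf))
  if (any(idx < 1)) stop("age below first bracket", call. = FALSE)
  brackets$cap[idx]
}

#' Apply the no-to-low drinking eligibility filter
#'
#' A subject is eligible only if, at every reported visit, both the lifetime
#' drinking-days cap and the per-occasion cap for their age (at that visit)
#' and sex are satisfied. This is the whole-subject rule: failing either cap
#' at any visit excludes the subject entirely.
#'
#' @param history data.frame with one row per subject-visit and columns
#'   `subject_id`, `age`, `sex`, `lifetime_days`, `max_drinks` (maximum
#'   drinks on any single occasion).
#' @param criteria a [drinking_criteria()] object.
#' @return character vector of eligible subject ids.
#' @export
apply_drinking_filter <- function(history, criteria = drinking_criteria()) {
  req <- c("subject_id", "age", "sex", "lifetime_days", "max_drinks")
  missing_cols <- setdiff(req, names(history))
  if (length(missing_cols) > 0) {
    stop("history is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(history$lifetime_days) || anyNA(history$max_drinks) ||
      anyNA(history$age)) {
    stop("history contains missing ages or drinking quantities", call. = FALSE)
  }
  if (any(history$age < 12)) {
    stop("ages below 12 are outside the criteria's domain", call. = FALSE)
  }
  if (!all(history$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  life_cap <- bracket_cap(criteria$lifetime_day_caps, history$age)
  occ_cap <- ifelse(history$sex == "female",
                    criteria$per_occasion_caps_female,
                    bracket_cap(criteria$per_occasion_caps_male, history$age))
  ok <- history$lifetime_days <= life_cap & history$max_drinks <= occ_cap
  bad <- unique(history$subject_id[!ok])
  sort(setdiff(unique(history$subject_id), bad))
}
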