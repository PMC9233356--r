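#' Validate a long-format longitudinal dataset
#'
#' A longitudinal dataset is a plain `data.frame` with one row per
#' subject-by-visit observation and at least the columns `subject_id`,
#' `visit` (1-based integer index), `age` (years) and `sex`
#' (`"male"`/`"female"`), plus one or more score columns.
#'
#' Checks enforced: required columns present; each `(subject_id, visit)`
#' combination appears at most once; within a subject age strictly increases
#' with visit; and, when `contiguous = TRUE` (full datasets, not per-visit
#' or per-pair subsets), visit indices are contiguous from 1.
#'
#' @param data data.frame to validate.
#' @param value optional name of a score column that must also be present.
#' @param contiguous require visit indices to be contiguous from 1.
#' @return `data` invisibly, with `visit` coerced to integer.
#' @export
validate_longitudinal <- function(data, value = NULL, contiguous = FALSE) {
  if (!is.data.frame(data)) stop("`data` must be a data.frame", call. = FALSE)
  if (nrow(data) == 0) stop("dataset has no rows", call. = FALSE)
  required <- c("subject_id", "visit", "age", "sex", value)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data$visit <- as.integer(data$visit)
  if (anyNA(data$visit) || any(data$visit < 1)) {
    stop("`visit` must be a positive integer index", call. = FALSE)
  }
  bad_sex <- setdiff(unique(as.character(data$sex)), c("male", "female", NA))
  if (length(bad_sex) > 0) {
    stop("unknown sex level(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  key <- paste(data$subject_id, data$visit, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (subject_id, visit) rows", call. = FALSE)
  }
  if (contiguous) {
    visits <- sort(unique(data$visit))
    if (!identical(visits, seq_len(max(visits)))) {
      stop("visit indices must be contiguous from 1", call. = FALSE)
    }
  }
  ord <- order(data$subject_id, data$visit)
  d <- data[ord, ]
  same_subj <- d$subject_id[-1] == d$subject_id[-nrow(d)]
  if (nrow(d) > 1 && any(same_subj & diff(d$age) <= 0)) {
    stop("age must strictly increase with visit within each subject",
         call. = FALSE)
  }
  invisible(data)
}

#' Number of visits present in a dataset
#' @param data a validated longitudinal dataset.
#' @return integer, the largest visit index.
#' @keywords internal
n_visits_present <- function(data) max(as.integer(data$visit))

# Subjects having a non-missing value at every visit in `visits`.
complete_subjects <- function(data, value, visits) {
  ok <- !is.na(data[[value]]) & data$visit %in% visits
  tab <- table(data$subject_id[ok])
  names(tab)[tab == length(visits)]
}
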