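#' Composite domain specification
#'
#' Names the measures that form one cognitive or motor composite (e.g.
#' Abstraction accuracy), with the scoring direction of each raw measure.
#' Measures whose raw direction is `lower_is_better` (e.g. response times,
#' error counts) are sign-flipped after standardization so that higher
#' always means better.
#'
#' @param domain composite name, e.g. `"Abstraction"`.
#' @param metric `"accuracy"` or `"speed"`.
#' @param members character vector of measure (column) names; non-empty.
#' @param directions per-measure direction, `"higher_is_better"` or
#'   `"lower_is_better"`; recycled if length 1.
#' @return an object of class `composite_spec`.
#' @export
composite_spec <- function(domain, metric = c("accuracy", "speed"),
                           members, directions = "higher_is_better") {
  metric <- match.arg(metric)
  if (length(members) == 0) stop("members must be non-empty", call. = FALSE)
  if (length(directions) == 1) directions <- rep(directions, length(members))
  if (length(directions) != length(members)) {
    stop("directions must match members", call. = FALSE)
  }
  if (!all(directions %in% c("higher_is_better", "lower_is_better"))) {
    stop("directions must be 'higher_is_better' or 'lower_is_better'",
         call. = FALSE)
  }
  names(directions) <- members
  structure(list(domain = domain, metric = metric, members = members,
                 directions = directions),
            class = "composite_spec")
}

#' Read composite specifications from a YAML file
#'
#' The file holds a list of entries, each with fields `domain`, `metric`,
#' `members` and `directions` (a map measure -> direction, or a single
#' direction applied to all members).
#'
#' @param path YAML file path.
#' @return list of [composite_spec()] objects, named by
#'   `"<domain>_<metric>"`.
#' @export
read_composite_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(x) {
    dirs <- x$directions
    if (is.list(dirs)) dirs <- unlist(dirs)
    if (!is.null(names(dirs))) dirs <- dirs[x$members]
    composite_spec(x$domain, x$metric, unlist(x$members),
                   unname(dirs %||% "higher_is_better"))
  })
  names(specs) <- vapply(specs, function(s)
    paste(gsub("\\s+", "_", tolower(s$domain)), s$metric, sep = "_"),
    character(1))
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the baseline Z standardizer
#'
#' Computes, for each measure, the mean and sample SD of the visit-1
#' (baseline) values across all subjects. The resulting transform is applied
#' to all subjects at all visits. Measures with zero baseline SD (constant
#' at baseline) cannot be standardized and are dropped with a warning.
#'
#' @param data long-format dataset containing visit-1 rows.
#' @param measures character vector of measure column names.
#' @return an object of class `z_transform` with fields `mean`, `sd` and
#'   `dropped`.
#' @export
fit_baseline_standardizer <- function(data, measures) {
  validate_longitudinal(data)
  missing_cols <- setdiff(measures, names(data))
  if (length(missing_cols) > 0) {
    stop("measure column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  base <- data[data$visit == 1L, , drop = FALSE]
  if (nrow(base) == 0) stop("no visit-1 rows to standardize on", call. = FALSE)
  m <- vapply(measures, function(v) mean(base[[v]], na.rm = TRUE), numeric(1))
  s <- vapply(measures, function(v) stats::sd(base[[v]], na.rm = TRUE), numeric(1))
  n_ok <- vapply(measures, function(v) sum(!is.na(base[[v]])), numeric(1))
  if (any(n_ok < 2)) {
    stop("measure(s) with fewer than 2 non-missing baseline values: ",
         paste(measures[n_ok < 2], collapse = ", "), call. = FALSE)
  }
  dropped <- measures[!is.na(s) & s == 0]
  if (length(dropped) > 0) {
    warning("dropping measure(s) with zero baseline SD: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(measures, dropped)
  structure(list(mean = m[keep], sd = s[keep], dropped = dropped),
            class = "z_transform")
}

#' Apply a baseline standardizer to a dataset
#'
#' @param transform a [fit_baseline_standardizer()] result.
#' @param data long-format dataset with the transform's measure columns.
#' @return `data` with each retained measure replaced by its Z-score.
#' @export
apply_standardizer <- function(transform, data) {
  stopifnot(inherits(transform, "z_transform"))
  for (v in names(transform$mean)) {
    data[[v]] <- (data[[v]] - transform$mean[[v]]) / transform$sd[[v]]
  }
  data
}

#' Orient Z-scores so that higher always means better
#'
#' Scores whose raw direction is `lower_is_better` are multiplied by -1
#' (for response times this is the "speed inversion": larger = faster).
#' Applying the orientation twice returns the original values.
#'
#' @param z numeric vector of Z-scores.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @return oriented Z-scores.
#' @export
orient_scores <- function(z, direction) {
  direction <- match.arg(direction, c("higher_is_better", "lower_is_better"))
  if (direction == "lower_is_better") -z else z
}

#' Compute a composite Z-score from oriented member Z-scores
#'
#' The composite is the mean of the non-missing member scores; missing
#' members are allowed, but at least 2 must be present or the composite is
#' missing for that row.
#'
#' @param z data.frame or matrix of oriented member Z-scores (columns =
#'   measures), or a numeric vector for a single row.
#' @param spec a [composite_spec()]; all `spec$members` must be columns of
#'   `z`.
#' @param min_members minimum member scores required (default 2).
#' @return numeric vector of composite scores (NA where fewer than
#'   `min_members` members are present).
#' @export
compute_composite <- function(z, spec, min_members = 2L) {
  stopifnot(inherits(spec, "composite_spec"))
  if (is.null(dim(z))) z <- as.data.frame(as.list(z))
  missing_cols <- setdiff(spec$members, colnames(z))
  if (length(missing_cols) > 0) {
    stop("member column(s) not present: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  zm <- as.matrix(as.data.frame(z)[, spec$members, drop = FALSE])
  k <- rowSums(!is.na(zm))
  out <- rowMeans(zm, na.rm = TRUE)
  out[k < min_members] <- NA_real_
  out
}

#' Build composite columns for a dataset
#'
#' Runs the full three-step construction: baseline standardization, sign
#' orientation, and per-row composite means, adding one column per
#' composite spec.
#'
#' @param data long-format dataset with raw measure columns.
#' @param specs list of [composite_spec()] objects (e.g. from
#'   [read_composite_specs()]).
#' @param transform optional pre-fitted [fit_baseline_standardizer()]; by
#'   default fitted on `data`'s visit-1 rows over all member measures.
#' @return `data` plus one column per spec (named as in `names(specs)` or
#'   `"<domain>_<metric>"`).
#' @export
build_composites <- function(data, specs, transform = NULL) {
  measures <- unique(unlist(lapply(specs, `[[`, "members")))
  if (is.null(transform)) {
    transform <- fit_baseline_standardizer(data, measures)
  }
  z0 <- apply_standardizer(transform, data)
  nm <- names(specs) %||% vapply(specs, function(s)
    paste(gsub("\\s+", "_", tolower(s$domain)), s$metric, sep = "_"),
    character(1))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    keep <- intersect(spec$members, names(transform$mean))
    if (length(keep) == 0) {
      data[[nm[i]]] <- NA_real_
      next
    }
    spec$members <- keep
    spec$directions <- spec$directions[keep]
    z <- z0
    for (v in keep) {
      z[[v]] <- orient_scores(z[[v]], spec$directions[[v]])
    }
    data[[nm[i]]] <- compute_composite(z, spec)
  }
  data
}

#' Efficiency score
#'
#' Sum of the Total Accuracy and Total Speed composite Z-scores; missing if
#' either is missing.
#'
#' @param total_accuracy,total_speed numeric vectors of composite Z-scores.
#' @return numeric vector.
#' @export
efficiency_score <- function(total_accuracy, total_speed) {
  total_accuracy + total_speed
}
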