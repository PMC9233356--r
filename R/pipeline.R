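#' Read a long-format longitudinal CSV
#'
#' Expects columns `subject_id`, `visit`, `age`, `sex` plus score columns;
#' empty fields are read as missing. Leading `#` comment lines (e.g. a
#' recorded seed) are skipped.
#'
#' @param path CSV file path.
#' @return validated long-format data.frame; a `# seed: N` header comment,
#'   if present, is restored as attribute `seed`.
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 10L)
  seed <- NULL
  m <- regmatches(head_lines, regexec("^#\\s*seed:\\s*(-?[0-9]+)", head_lines))
  for (g in m) if (length(g) == 2) seed <- as.integer(g[2])
  data <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("subject_id", "visit", "age", "sex")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_age <- which(!is.finite(data$age))
  if (length(bad_age) > 0) {
    stop("malformed age in ", path, " at data row(s) ",
         paste(utils::head(bad_age, 5), collapse = ", "), call. = FALSE)
  }
  data <- validate_longitudinal(data, contiguous = TRUE)
  if (!is.null(seed)) attr(data, "seed") <- seed
  data
}

#' Write a long-format longitudinal CSV
#'
#' Missing values are written as empty fields. If a seed is supplied (or
#' stored as attribute `seed`), it is recorded in a `# seed: N` header
#' comment so a round-trip preserves it.
#'
#' @param data long-format data.frame.
#' @param path output CSV path.
#' @param seed optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(data, path, seed = attr(data, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(data, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Build a pipeline run configuration
#'
#' Exactly one of `input` (a CSV path) or `simulation` (a [sim_config()] or
#' a list of its arguments) must be given.
#'
#' @param input path to a long-format CSV, or `NULL`.
#' @param simulation a [sim_config()] (or argument list), or `NULL`.
#' @param values score column names to analyse.
#' @param steps analysis switches: any of `"learning"`, `"adjust"`,
#'   `"develop"`, `"triptych"`.
#' @param alpha,m family-wise level and comparison count for the Bonferroni
#'   threshold.
#' @param convention adjustment age convention (see [adjust_visits()]).
#' @param seed integer seed for any randomness (simulation).
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulation = NULL, values = "value",
                       steps = c("learning", "adjust", "develop", "triptych"),
                       alpha = 0.05, m = 8L, convention = "equation",
                       seed = 1L, out_dir = "practiceAdjust-run") {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of `input` or `simulation` must be given", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  bad <- setdiff(steps, c("learning", "adjust", "develop", "triptych"))
  if (length(bad) > 0) stop("unknown step(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  structure(list(input = input, simulation = simulation, values = values,
                 steps = steps, alpha = alpha, m = as.integer(m),
                 convention = convention, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level fields mirror the arguments of [run_config()]; `simulation` is
#' a map of [sim_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("input", "values", "steps", "alpha", "m",
                          "convention", "seed", "out_dir"))]
  if (!is.null(raw$simulation)) {
    sim <- raw$simulation
    if (!is.null(sim$band_ranges)) sim$band_ranges <- lapply(sim$band_ranges, unlist)
    if (!is.null(sim$learning_increments)) {
      sim$learning_increments <- unlist(sim$learning_increments)
    }
    if (!is.null(sim$band_weights)) sim$band_weights <- unlist(sim$band_weights)
    args$simulation <- sim
  }
  if (!is.null(args$values)) args$values <- unlist(args$values)
  if (!is.null(args$steps)) args$steps <- unlist(args$steps)
  do.call(run_config, args)
}

#' Run the end-to-end analysis pipeline
#'
#' Loads or simulates the dataset, then (per the configured steps)
#' estimates visit-to-visit learning, removes cumulative learning, fits
#' developmental trajectories before and after adjustment, and computes
#' the slope triptych. Every stage's outputs are written under
#' `config$out_dir` as CSV/JSON, with a plain-text log recording row and
#' subject counts. Deterministic given the config and seed.
#'
#' @param config a [run_config()].
#' @return named list of the in-memory artifacts (`data`, and depending on
#'   steps `learning`, `adjusted`, `development`, `triptych`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  say <- function(...) writeLines(paste0(...), log_con)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("ERROR in stage '", name, "': ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  threshold <- bonferroni_threshold(config$alpha, config$m)
  say("seed: ", config$seed)
  say("threshold: ", format(threshold))

  data <- stage("input", {
    if (!is.null(config$simulation)) {
      d <- simulate_cohort(config$simulation, seed = config$seed)
      say("simulated ", length(unique(d$subject_id)), " subjects, ",
          nrow(d), " rows")
      d
    } else {
      d <- read_long_csv(config$input)
      say("read ", nrow(d), " rows from ", config$input)
      d
    }
  })
  write_long_csv(data, file.path(config$out_dir, "dataset.csv"),
                 seed = config$seed)
  artifacts <- list(data = data)

  if ("learning" %in% config$steps) {
    artifacts$learning <- stage("learning", {
      tab <- learning_table(data, config$values, threshold)
      utils::write.csv(tab, file.path(config$out_dir, "learning.csv"),
                       row.names = FALSE)
      say("learning table: ", nrow(tab), " composite x pair rows")
      tab
    })
  }

  if ("adjust" %in% config$steps) {
    artifacts$adjusted <- stage("adjust", {
      adj_list <- list()
      for (v in config$values) {
        fits <- cross_sectional_fits(data, v)
        adj <- adjust_visits(data, fits, convention = config$convention)
        say("adjusted '", v, "': ", nrow(adj), " rows; subjects excluded: ",
            attr(adj, "n_excluded"))
        curve <- cumulative_learning_curve(fits)
        curve_df <- data.frame(age = rep(attr(curve, "age"), each = nrow(curve)),
                               pair = rep(rownames(curve), ncol(curve)),
                               learning = as.vector(curve))
        utils::write.csv(curve_df,
                         file.path(config$out_dir,
                                   paste0("learning_curve_", v, ".csv")),
                         row.names = FALSE)
        adj_list[[v]] <- adj
      }
      first <- adj_list[[1]]
      write_long_csv(first, file.path(config$out_dir, "adjusted.csv"),
                     seed = config$seed)
      adj_list
    })
  }

  if ("develop" %in% config$steps) {
    artifacts$development <- stage("develop", {
      target <- if (!is.null(artifacts$adjusted)) {
        rep <- developmental_report(data, config$values, threshold,
                                    convention = config$convention)
        rep
      } else {
        do.call(rbind, lapply(config$values, function(v) {
          fit <- fit_development(data, v, threshold = threshold)
          data.frame(composite = v, n = fit$n, shape_unadjusted = fit$shape,
                     p_shape_unadjusted = fit$shape_comparison$p_value,
                     slope_unadjusted = fit$slope, threshold = threshold,
                     stringsAsFactors = FALSE)
        }))
      }
      utils::write.csv(target, file.path(config$out_dir, "development.csv"),
                       row.names = FALSE)
      say("development report: ", nrow(target), " rows")
      target
    })
  }

  if ("triptych" %in% config$steps && !is.null(artifacts$adjusted)) {
    artifacts$triptych <- stage("triptych", {
      tri <- do.call(rbind, lapply(names(artifacts$adjusted), function(v) {
        t <- slope_triptych(artifacts$adjusted[[v]], value = v)
        t$composite <- v
        t
      }))
      utils::write.csv(tri, file.path(config$out_dir, "triptych.csv"),
                       row.names = FALSE)
      say("triptych: ", nrow(tri), " rows")
      tri
    })
  }

  summary_obj <- list(
    seed = config$seed, threshold = threshold, steps = config$steps,
    n_rows = nrow(data), n_subjects = length(unique(data$subject_id)))
  jsonlite::write_json(summary_obj,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(artifacts)
}
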