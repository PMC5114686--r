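#' Read historical control cohorts from CSV
#'
#' Accepts either of two schemas (detected from the header):
#' * summary — columns `source_id, n, mean, sd`: one cohort per row;
#' * patient-level — columns `source_id, patient_id, outcome`: rows are
#'   grouped by `source_id` and summarized (an optional `n` column, if
#'   present, is checked against the per-source row counts).
#'
#' Files mixing the two schemas are rejected. Non-numeric or missing values
#' in numeric columns raise a parse error naming the offending data line
#' (line 1 is the header).
#'
#' @param path Path to a comma-separated, UTF-8, headered file with `.`
#'   decimal marks.
#' @return A cohort tibble (see [as_historical_cohorts()]); patient-level
#'   input keeps the raw outcomes in a `values` list-column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("source_id,n,mean,sd", "trial_A,100,0.0,1.0"), f)
#' read_cohort_csv(f)
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cohort file not found: %s.", path),
          class = "threshtrial_parse_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  cols <- names(df)
  is_summary <- all(c("n", "mean") %in% cols)
  is_patient <- all(c("patient_id", "outcome") %in% cols)
  if (is_summary && is_patient) {
    abort(sprintf("%s mixes the summary and patient-level schemas.", path),
          class = "threshtrial_parse_error")
  }
  if (!is_summary && !is_patient) {
    abort(sprintf(
      "%s matches neither cohort schema: need {source_id,n,mean,sd} or {source_id,patient_id,outcome}.",
      path
    ), class = "threshtrial_parse_error")
  }
  if (!"source_id" %in% cols) {
    abort(sprintf("%s lacks the source_id column.", path),
          class = "threshtrial_parse_error")
  }
  if (is_summary) {
    num <- c("n", "mean", if ("sd" %in% cols) "sd")
    for (col in num) {
      df[[col]] <- parse_numeric_column(df[[col]], col, path)
    }
    return(validate_cohorts(df[, c("source_id", num)]))
  }
  df$outcome <- parse_numeric_column(df$outcome, "outcome", path)
  stated_n <- NULL
  if ("n" %in% cols) {
    stated_n <- parse_numeric_column(df$n, "n", path)
  }
  out <- df |>
    dplyr::group_by(.data$source_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$outcome),
      sd = if (dplyr::n() > 1L) sd(.data$outcome) else 0,
      values = list(.data$outcome),
      .groups = "drop"
    )
  if (!is.null(stated_n)) {
    stated <- tapply(stated_n, df$source_id, function(v) v[1])
    mismatch <- out$source_id[out$n != stated[out$source_id]]
    if (length(mismatch) > 0L) {
      abort(sprintf(
        "%s: stated n disagrees with the patient row count for source(s) %s.",
        path, paste(dQuote(mismatch), collapse = ", ")
      ), class = "threshtrial_parse_error")
    }
  }
  validate_cohorts(out)
}

parse_numeric_column <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s: column %s has a non-numeric or missing value at line %d.",
      path, dQuote(col), bad[1] + 1L
    ), class = "threshtrial_parse_error")
  }
  out
}

#' Write historical control cohorts to CSV
#'
#' Writes either the summary schema (`source_id, n, mean, sd`; default) or,
#' when `patient_level = TRUE` and a `values` list-column is present, the
#' patient-level schema (`source_id, patient_id, outcome`). Both round-trip
#' through [read_cohort_csv()].
#'
#' @param cohorts A cohort tibble.
#' @param path Output path.
#' @param patient_level Write one row per patient instead of per cohort.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohorts, path, patient_level = FALSE) {
  cohorts <- validate_cohorts(cohorts)
  if (patient_level) {
    if (!"values" %in% names(cohorts) ||
        any(vapply(cohorts$values, is.null, logical(1)))) {
      abort("Patient-level export needs a complete `values` list-column.",
            class = "threshtrial_config_error")
    }
    long <- cohorts |>
      dplyr::select("source_id", "values") |>
      tidyr::unnest_longer("values", values_to = "outcome") |>
      dplyr::group_by(.data$source_id) |>
      dplyr::mutate(patient_id = dplyr::row_number(), .before = "outcome") |>
      dplyr::ungroup()
    readr::write_csv(long, path, progress = FALSE)
  } else {
    readr::write_csv(cohorts[, c("source_id", "n", "mean", "sd")], path,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read a run configuration (the machine-readable analysis plan)
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON configuration describing a full
#' threshold-crossing analysis: estimand metadata, design parameters,
#' threshold rules, the historical input (exactly one of inline `cohorts`,
#' a `csv` path, or a `generate` spec), the scenario grid, replication
#' counts, the seed, and optionally a multistage `flow` block. See
#' [run_pipeline()] for the fields consumed.
#'
#' @param path Path to the configuration file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s.", path),
          class = "threshtrial_config_error")
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$.dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!is.list(cfg)) {
    abort("Configuration must be a mapping.", class = "threshtrial_config_error")
  }
  d <- cfg$design %||% list()
  cfg$design <- design_params(
    delta = d$delta %||% 0.2, sigma = d$sigma %||% 1,
    alpha = d$alpha %||% 0.025, power = d$power %||% 0.80
  )
  cfg$rules <- cfg$rules %||% c("naive", "ci", "ci+0.1", "ci+0.2", "ci+0.3")
  hist <- cfg$historical %||% list()
  sources <- c("cohorts", "csv", "generate")
  given <- sources[sources %in% names(hist)]
  if (length(given) != 1L) {
    abort("`historical` must name exactly one input source: cohorts, csv, or generate.",
          class = "threshtrial_config_error")
  }
  cfg$historical_source <- given
  if (given == "csv") {
    p <- hist$csv
    if (!file.exists(p) && !is.null(cfg$.dir)) {
      p <- file.path(cfg$.dir, hist$csv)
    }
    if (!file.exists(p)) {
      abort(sprintf("Historical cohort file not found: %s.", hist$csv),
            class = "threshtrial_config_error")
    }
    cfg$historical$csv <- p
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = c("run_config", "list"))
}

resolve_cohorts <- function(cfg) {
  hist <- cfg$historical
  switch(cfg$historical_source,
    cohorts = validate_cohorts(dplyr::bind_rows(lapply(hist$cohorts, as_tibble))),
    csv = read_cohort_csv(hist$csv),
    generate = {
      g <- hist$generate
      k <- as.integer(g$k %||% 1L)
      dplyr::bind_rows(lapply(seq_len(k), function(i) {
        simulate_historical_cohort(
          n = g$n, mu = g$mu %||% 0, sigma = g$sigma %||% cfg$design$sigma,
          source_id = sprintf("synthetic_%02d", i),
          seed = cell_seed(cfg$seed, "historical_cohort", i, g$n)
        )
      }))
    }
  )
}

#' Run the full threshold-crossing pipeline from a configuration
#'
#' Executes the linear design sequence — pool the historical cohorts, derive
#' the threshold and planned trial size for each rule, estimate the
#' operating-characteristic grid, and (when a `flow` block is present)
#' simulate the multistage program — and writes the artifact bundle to
#' `out_dir`:
#' * `threshold_report.json` — pooled estimate(s), threshold and planned
#'   size per rule (infeasible rules flagged);
#' * `oc_grid.csv` — the long operating-characteristic table;
#' * `program_oc.csv` — multistage program summary (if configured);
#' * `run_log.json` — config hash, seed, package version.
#'
#' The same configuration and seed always reproduce byte-identical outputs.
#' Errors are re-signalled with the failing pipeline stage named.
#'
#' @param config A [read_run_config()] result, a path to a config file, or
#'   a bare list in the same shape.
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `output` field or `"."`.
#' @param seed Root seed; defaults to the config's `seed`.
#' @return Invisibly, a list with the in-memory results (`cohorts`, `pool`,
#'   `thresholds`, `oc`, `program`) and the written `paths`.
#' @examples
#' cfg <- list(
#'   design = list(delta = 0.2), rules = c("naive", "ci"),
#'   historical = list(generate = list(k = 2, n = 500)),
#'   grid = list(n_h = c(100, 1000)), reps_null = 2000, reps_power = 2000,
#'   seed = 1
#' )
#' res <- run_pipeline(cfg, out_dir = tempfile())
#' names(res)
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    config <- read_run_config(config)
  } else if (!inherits(config, "run_config")) {
    config <- validate_run_config(config)
  }
  seed <- as.integer(seed %||% config$seed)
  out_dir <- out_dir %||% config$output %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$design
  paths <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage %s failed: %s", dQuote(name),
                    conditionMessage(e)),
            class = "threshtrial_pipeline_error", parent = e)
    })
  }

  cohorts <- stage("historical input", resolve_cohorts(config))
  method <- (config$pooling %||% list())$method %||% "fixed"
  pool <- stage("pooling", pool_controls(cohorts, method = method,
                                         sigma = params$sigma))
  hist_for_rules <- pooled_to_cohort(pool)

  rules <- lapply(config$rules, parse_threshold_rule)
  thresholds <- stage("threshold derivation", lapply(rules, function(r) {
    th <- compute_threshold(hist_for_rules, r, params)
    planned <- tryCatch(planned_trial_size(r, hist_for_rules$n, params),
                        threshtrial_infeasible_error = function(e) NA_integer_)
    list(
      rule = r$rule, gamma = r$gamma, c = r$c, t = th$t,
      planned_n = planned, feasible = !is.na(planned)
    )
  }))
  report <- list(
    estimand = config$estimand %||% list(),
    design = unclass(params),
    pooled = as.list(glance(pool)),
    cohorts = as.list(cohorts[, c("source_id", "n", "mean", "sd")]),
    thresholds = thresholds
  )
  paths$threshold_report <- file.path(out_dir, "threshold_report.json")
  jsonlite::write_json(report, paths$threshold_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  grid_cfg <- config$grid %||% list()
  rule_tbl <- dplyr::bind_rows(lapply(rules, function(r) {
    tibble(rule = r$rule, gamma = r$gamma, c = r$c)
  }))
  oc <- stage("operating characteristics", oc_grid(
    params, rules = rule_tbl,
    n_h = as.integer(grid_cfg$n_h %||% c(100, 250, 500, 1000)),
    drift = as.numeric(grid_cfg$drift %||% 0),
    true_delta = as.numeric(grid_cfg$true_delta %||% c(0, params$delta)),
    n_reps_null = as.integer(config$reps_null %||% 1e5),
    n_reps_power = as.integer(config$reps_power %||% 1e4),
    seed = seed
  ))
  paths$oc_grid <- file.path(out_dir, "oc_grid.csv")
  readr::write_csv(oc, paths$oc_grid, progress = FALSE)

  program <- NULL
  if (!is.null(config$flow)) {
    fl <- config$flow
    program <- stage("decision flow", dplyr::bind_rows(lapply(
      as.numeric(fl$true_delta %||% c(0, params$delta)),
      function(td) {
        simulate_program(
          params, parse_threshold_rule(fl$rule %||% "ci"),
          n_h = as.integer(fl$n_h %||% 1000),
          true_delta = td, drift = as.numeric(fl$drift %||% 0),
          stage2 = fl$stage2 %||% "rct",
          stage2_alpha = fl$stage2_alpha %||% NULL,
          futility = fl$futility %||% "historical_mean",
          n_reps = as.integer(fl$reps %||% 1e4), seed = seed
        )
      }
    )))
    paths$program_oc <- file.path(out_dir, "program_oc.csv")
    readr::write_csv(program, paths$program_oc, progress = FALSE)
  }

  log <- list(
    config_hash = rlang::hash(config[setdiff(names(config), ".dir")]),
    seed = seed,
    package = "threshtrial",
    version = as.character(utils::packageVersion("threshtrial"))
  )
  paths$run_log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, digits = NA)

  invisible(list(cohorts = cohorts, pool = pool, thresholds = thresholds,
                 oc = oc, program = program, paths = paths))
}
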