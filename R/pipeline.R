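#' Pipeline configuration
#'
#' Collects every knob of the end-to-end calibration workflow. Exactly one
#' of `input_path` (a wide/long spectral CSV) or `sim_config` (a
#' [simulation_config()]) must be given.
#'
#' @param input_path Optional path to a spectral table CSV.
#' @param sim_config Optional [simulation_config()] for simulated input.
#' @param range_nm Screening window, nm (default `c(400, 1400)`).
#' @param derivative_mode `"printed"` or `"central"` differencing.
#' @param n_train,n_test Split sizes (default 80 % / 20 % of N).
#' @param split_seed Seed of the train/validation split.
#' @param stratum_threshold Low-content stratum bound, mg/g (default 20).
#' @param stratum_mode `"refit"` (default) re-runs screening and fitting on
#'   the below-threshold training samples; `"evaluate"` only re-evaluates
#'   the full-range model on the stratum.
#' @param max_excluded_frac Passed to [fit_model()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input_path = NULL, sim_config = NULL,
                            range_nm = c(400, 1400),
                            derivative_mode = c("printed", "central"),
                            n_train = NULL, n_test = NULL,
                            split_seed = 1L,
                            stratum_threshold = 20,
                            stratum_mode = c("refit", "evaluate"),
                            max_excluded_frac = 0.1) {
  if (is.null(input_path) == is.null(sim_config)) {
    stop("exactly one of input_path or sim_config must be supplied",
         call. = FALSE)
  }
  if (!is.null(input_path) && !file.exists(input_path)) {
    stop("input file not found: ", input_path, call. = FALSE)
  }
  if (!is.null(sim_config)) stopifnot(inherits(sim_config,
                                               "simulation_config"))
  structure(
    list(input_path = input_path, sim_config = sim_config,
         range_nm = range_nm,
         derivative_mode = match.arg(derivative_mode),
         n_train = n_train, n_test = n_test,
         split_seed = as.integer(split_seed),
         stratum_threshold = stratum_threshold,
         stratum_mode = match.arg(stratum_mode),
         max_excluded_frac = max_excluded_frac),
    class = "pipeline_config"
  )
}

.report_row <- function(rep, label) {
  data.frame(subset = label, transform = rep$transform, band_nm = rep$band,
             family = rep$family, r2 = rep$r2, r2_cor = rep$r2_cor,
             rmse_mg_per_g = rep$rmse, n = rep$n,
             n_domain_violations = rep$n_domain_violations,
             stringsAsFactors = FALSE)
}

# screening + fitting + selection on one training dataset
.calibrate <- function(train, cfg) {
  screen <- screen_all_transforms(train, derivative_mode = cfg$derivative_mode)
  candidates <- fit_all_candidates(train, screen,
                                   derivative_mode = cfg$derivative_mode,
                                   max_excluded_frac = cfg$max_excluded_frac)
  list(screen = screen, candidates = candidates,
       best = select_best_model(candidates))
}

#' Run the end-to-end calibration workflow
#'
#' Loads or simulates the spectral dataset, restricts it to the screening
#' window, splits into training and validation samples, screens all eight
#' transforms on the training set, fits the five model families at each
#' sensitive band, selects the best model by original-scale R^2, evaluates
#' it on training and held-out samples, and repeats the
#' calibration on the low-anthocyanin stratum. All artifacts are written to
#' `out_dir` as plain CSV/JSON/text so that identical configuration and
#' seeds reproduce them byte-identically.
#'
#' Artifacts: `screening_report.csv`, `correlation_spectra.csv`,
#' `candidate_grid.csv`, `model_table.txt`, `best_model.json`,
#' `validation_report.csv`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisibly, a list with the dataset, split, screening result,
#'   candidate set, best model, validation table and (if written) artifact
#'   paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (!is.null(config$input_path)) {
    read_spectral_table(config$input_path)
  } else {
    generate_dataset(config$sim_config)
  }
  ds <- restrict_range(dataset, config$range_nm[1], config$range_nm[2])
  plan <- split_train_test(ds, config$n_train, config$n_test,
                           seed = config$split_seed)
  train <- subset_samples(ds, plan$train_ids)
  test <- subset_samples(ds, plan$test_ids)

  cal <- .calibrate(train, config)
  reports <- rbind(
    .report_row(evaluate_model(cal$best, train, config$derivative_mode,
                               stratum = "full"), "train"),
    .report_row(evaluate_model(cal$best, test, config$derivative_mode,
                               stratum = "full"), "test"))

  stratum <- NULL
  st_label <- sprintf("< %g mg/g", config$stratum_threshold)
  st_train <- tryCatch(stratify_below(train, config$stratum_threshold),
                       error = function(e) NULL)
  st_test <- tryCatch(stratify_below(test, config$stratum_threshold),
                      error = function(e) NULL)
  if (!is.null(st_train)) {
    st_model <- if (config$stratum_mode == "refit") {
      stratum <- .calibrate(st_train, config)
      stratum$best
    } else cal$best
    reports <- rbind(reports,
      .report_row(evaluate_model(st_model, st_train, config$derivative_mode,
                                 stratum = st_label), "stratum_train"))
    if (!is.null(st_test)) {
      reports <- rbind(reports,
        .report_row(evaluate_model(st_model, st_test, config$derivative_mode,
                                   stratum = st_label), "stratum_test"))
    }
  }

  result <- list(dataset = dataset, restricted = ds, split = plan,
                 screen = cal$screen, candidates = cal$candidates,
                 best = cal$best, stratum = stratum, validation = reports,
                 config = config)
  if (!is.null(out_dir)) {
    result$paths <- .write_artifacts(result, out_dir)
  }
  invisible(result)
}

.write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  grid <- candidate_grid(result$candidates)
  utils::write.csv(screening_report(result$screen), p("screening_report.csv"),
                   row.names = FALSE)
  utils::write.csv(correlation_long(result$screen),
                   p("correlation_spectra.csv"), row.names = FALSE)
  utils::write.csv(grid, p("candidate_grid.csv"), row.names = FALSE)
  writeLines(render_table1_report(grid), p("model_table.txt"))
  best <- result$best
  jsonlite::write_json(
    list(transform = best$transform, band_nm = best$band,
         family = best$family,
         coefficients = as.list(best$coefficients),
         equation = equation_string(best),
         r2 = best$r2, n_fit = best$n_fit),
    p("best_model.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(result$validation, p("validation_report.csv"),
                   row.names = FALSE)
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("anthospec")),
    input = if (is.null(cfg$input_path)) "simulated" else cfg$input_path,
    simulation_seed = if (is.null(cfg$sim_config)) NULL else
      cfg$sim_config$seed,
    split_seed = cfg$split_seed,
    n_train = length(result$split$train_ids),
    n_test = length(result$split$test_ids),
    range_nm = cfg$range_nm,
    derivative_mode = cfg$derivative_mode,
    stratum_threshold = cfg$stratum_threshold,
    stratum_mode = cfg$stratum_mode,
    best_transform = result$best$transform,
    best_band_nm = result$best$band,
    best_family = result$best$family,
    best_r2 = result$best$r2)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  vapply(c("screening_report.csv", "correlation_spectra.csv",
           "candidate_grid.csv", "model_table.txt", "best_model.json",
           "validation_report.csv", "manifest.json"), p, character(1))
}

#' Render the candidate grid as a grouped model table
#'
#' Formats the fitted-candidate grid the way calibration tables are usually
#' printed: one block per transform (in the canonical transform order) with
#' its sensitive band, then one line per family with the equation and R^2;
#' skipped families are annotated with the reason.
#'
#' @param grid A data frame from [candidate_grid()].
#' @return Character vector of report lines.
#' @export
render_table1_report <- function(grid) {
  if (!NROW(grid)) stop("empty candidate grid", call. = FALSE)
  lines <- character(0)
  for (k in transform_kinds()$kind) {
    rows <- grid[grid$transform == k, , drop = FALSE]
    if (!nrow(rows)) next
    lines <- c(lines, sprintf("%s  (sensitive band %g nm)", k,
                              rows$band_nm[1L]))
    for (i in seq_len(nrow(rows))) {
      lines <- c(lines, if (rows$status[i] == "ok") {
        sprintf("  %-12s %-45s R2 = %.3f", rows$family[i], rows$equation[i],
                rows$r2_original_scale[i])
      } else {
        sprintf("  %-12s skipped (%s)", rows$family[i], rows$reason[i])
      })
    }
  }
  lines
}
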