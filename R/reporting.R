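#' Resolved run configuration
#'
#' Collects every tunable of the pipeline in one flat list that round-trips
#' losslessly through JSON. Each pipeline run writes its resolved
#' configuration (plus an md5 stamp) beside its outputs.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_subjects,n_replicates,tracer_fraction Study design.
#' @param cv,subject_sd Noise model of the synthetic generator.
#' @param s_pa,s_a Blood/intracellular scaling factors (mandatory study
#'   inputs for real analyses; default 1).
#' @param bounds_log10 Log10 rate bounds.
#' @param ratio_bounds Inter-intervention ratio bounds.
#' @param n_restarts Optimizer restarts per fit.
#' @param mcmc_n Retained posterior samples per window.
#' @param split_candidates Candidate window split points (minutes).
#' @param de_maxiter Generations per optimizer restart.
#' @param sigma_floor_abs,sigma_floor_frac Standard-deviation floor.
#' @param subject_average Across-subject averaging convention.
#' @param quantile_type Quartile convention for the outlier filter.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_subjects = 11, n_replicates = 3,
                       tracer_fraction = 0.02, cv = 0.1, subject_sd = 0.1,
                       s_pa = 1, s_a = 1, bounds_log10 = c(-5, 1),
                       ratio_bounds = c(0.1, 10), n_restarts = 50,
                       mcmc_n = 10000, split_candidates = c(75, 90, 105, 120, 150),
                       de_maxiter = 300, sigma_floor_abs = 1e-6,
                       sigma_floor_frac = 0.01,
                       subject_average = "mean", quantile_type = 7) {
  cfg <- list(seed = seed, n_subjects = n_subjects, n_replicates = n_replicates,
              tracer_fraction = tracer_fraction, cv = cv,
              subject_sd = subject_sd, s_pa = s_pa, s_a = s_a,
              bounds_log10 = bounds_log10, ratio_bounds = ratio_bounds,
              n_restarts = n_restarts, mcmc_n = mcmc_n,
              split_candidates = split_candidates, de_maxiter = de_maxiter,
              sigma_floor_abs = sigma_floor_abs,
              sigma_floor_frac = sigma_floor_frac,
              subject_average = subject_average, quantile_type = quantile_type)
  class(cfg) <- "run_config"
  cfg
}

#' Read and write run configurations
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, raw)
  cfg
}

dialect_columns <- function() {
  c("subject", "intervention", "replicate", "time_min", "metabolite",
    "isotopologue", "concentration_uM")
}

#' Read and write the tidy isotopologue CSV dialect
#'
#' UTF-8, comma-separated, header
#' `subject,intervention,replicate,time_min,metabolite,isotopologue,concentration_uM`;
#' times in minutes relative to ingestion; missing values as empty cells.
#' Malformed numeric fields are reported with their line numbers.
#'
#' @param path CSV path.
#' @param data Tidy dataset.
#' @return `read_isotopologue_csv` returns the dataset as a data.frame;
#'   `write_isotopologue_csv` returns `path` invisibly.
#' @export
read_isotopologue_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject = "character"))
  missing_cols <- setdiff(dialect_columns(), names(d))
  if (length(missing_cols)) {
    stop("malformed CSV ", path, ": missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("replicate", "time_min", "concentration_uM")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad)) {
        stop(sprintf("malformed CSV %s: non-numeric `%s` at data line(s) %s",
                     path, col, paste(bad + 1L, collapse = ", ")),
             call. = FALSE)
      }
      d[[col]] <- vn
    }
  }
  d
}

#' @rdname read_isotopologue_csv
#' @export
write_isotopologue_csv <- function(data, path) {
  stopifnot(all(dialect_columns() %in% names(data)))
  utils::write.csv(data[dialect_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline on a synthetic or supplied study
#'
#' End-to-end driver: simulate (or read) the replicate-level dataset, filter
#' outliers, reduce to the modelling dataset, scan window splits, fit the
#' selected early and late windows, sample both posteriors, and write the
#' flux and ROC-AUC tables. All artifacts are stamped with the md5 of the
#' resolved configuration and the seed.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param data Optional tidy replicate-level dataset; if `NULL` a synthetic
#'   study is generated from the default ground truth with the config's
#'   design and noise settings.
#' @param de_control Optional overrides for [de_optimize()] (applied on top
#'   of the config's `de_maxiter`).
#' @return Invisibly, a list with the main intermediate objects (`dataset`,
#'   `model_data`, `split_report`, `fits`, `populations`, `fluxes`, `auc`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("pfrun"),
                         data = NULL, de_control = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- study_design(n_subjects = config$n_subjects,
                         n_replicates = config$n_replicates,
                         tracer_fraction = config$tracer_fraction)
  schedule <- scaling_schedule(s_pa = config$s_pa, s_a = config$s_a)
  if (is.null(data)) {
    truth <- default_ground_truth(cv = config$cv, subject_sd = config$subject_sd)
    data <- simulate_study(truth, design, seed = child_seed(config$seed, 11))
  }
  write_isotopologue_csv(data, file.path(out_dir, "dataset.csv"))

  filtered <- remove_outliers_iqr(data, quantile_type = config$quantile_type)
  utils::write.csv(filtered$log, file.path(out_dir, "outlier_log.csv"),
                   row.names = FALSE)
  model_data <- reduce_to_model_dataset(
    filtered$data, subject_average = config$subject_average,
    sigma_floor_abs = config$sigma_floor_abs,
    sigma_floor_frac = config$sigma_floor_frac)
  utils::write.csv(model_data, file.path(out_dir, "model_dataset.csv"),
                   row.names = FALSE)

  de_control <- utils::modifyList(list(maxiter = config$de_maxiter), de_control)
  scan <- scan_splits(model_data, candidates = config$split_candidates,
                      schedule = schedule,
                      bounds_log10 = config$bounds_log10,
                      ratio_bounds = config$ratio_bounds,
                      n_restarts = config$n_restarts,
                      seed = child_seed(config$seed, 23),
                      de_control = de_control)
  utils::write.csv(scan$table, file.path(out_dir, "split_scan.csv"),
                   row.names = FALSE)

  split <- scan$selected
  t_max <- max(model_data$time)
  windows <- list(early = c(0, split), late = c(split, t_max))
  fits <- scan$fits[[as.character(split)]]
  fluxes <- list()
  aucs <- list()
  pops <- list()
  for (ph in names(windows)) {
    prob <- fit_problem(model_data, windows[[ph]], schedule,
                        config$bounds_log10, config$ratio_bounds)
    pop <- sample_posterior(prob, fits[[ph]], n = config$mcmc_n,
                            seed = child_seed(config$seed, 31 + match(ph, names(windows))))
    pops[[ph]] <- pop
    fx <- fluxes_from_samples(pop, model_data, windows[[ph]], ph, schedule,
                              config$tracer_fraction)
    fluxes[[ph]] <- fx
    auc <- roc_auc_per_parameter(pop)
    auc$window <- ph
    aucs[[ph]] <- auc
  }
  flux_table <- do.call(rbind, fluxes)
  auc_table <- do.call(rbind, aucs)
  utils::write.csv(flux_table, file.path(out_dir, "flux_table.csv"),
                   row.names = FALSE)
  utils::write.csv(auc_table, file.path(out_dir, "auc_table.csv"),
                   row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.json")
  write_run_config(config, cfg_path)
  stamp <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                seed = config$seed, selected_split = split)
  jsonlite::write_json(stamp, file.path(out_dir, "run_stamp.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = data, model_data = model_data, split_report = scan,
                 fits = fits, populations = pops, fluxes = flux_table,
                 auc = auc_table, out_dir = out_dir))
}
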