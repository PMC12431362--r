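# End-to-end orchestration: configuration, the three pipeline stages
# (simulate -> features -> evaluate) and a thin command-line front-end in
# inst/cli/nibgm.R.

#' Default run configuration
#'
#' The full pipeline configuration with its defaults: the synthetic-study
#' block (4 subjects x 4 days x 17 samples/day = 272 records over 16
#' subject-days), the model block echoing the fixed training settings
#' (3 + 3 layers of width 25, MSE loss, Adam, 50 epochs, learning rate
#' 0.01), the cross-validation scheme, the Parkes grid variant, the master
#' seed, and the output directory.
#'
#' @return Nested list of configuration defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "nibgm_run",
    study = list(n_subjects = 4L, n_days = 4L, samples_per_day = 17L),
    model = list(hidden_size = 25L, n_lstm_layers = 3L, mlp_width = 25L,
                 n_mlp_layers = 3L, epochs = 50L, learning_rate = 0.01,
                 batch_days = 4L),
    cv = list(mode = "ablation", k_random = 10L, k_days = 8L,
              days_per_fold = 2L),
    parkes_variant = "type1"
  )
}

#' Read a run configuration file
#'
#' Loads a YAML configuration and merges it over [default_run_config()];
#' missing fields keep their defaults. `overrides` (e.g. from command-line
#' flags) are merged last.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides Named list merged after the file.
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop_nibgm(sprintf("config file not found: %s", path),
                 "nibgm_config_error")
    }
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

log_msg <- function(...) message(sprintf("[nibgm] %s", sprintf(...)))

write_config_echo <- function(cfg, dir) {
  echo <- c(cfg, list(package_version = as.character(
    utils::packageVersion("nibgm"))))
  yaml::write_yaml(echo, file.path(dir, "config_echo.yaml"))
}

#' Simulate a synthetic study to disk
#'
#' Generates the configured synthetic study and writes one device CSV per
#' record plus a `manifest.csv` (subject, day, file, reference glucose) and
#' a config echo to the output directory.
#'
#' @param config Configuration list (see [read_run_config()]).
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config = default_run_config()) {
  dir <- config$out_dir
  dir.create(file.path(dir, "records"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "records"))) {
    stop_nibgm(sprintf("cannot create output directory: %s", dir),
               "nibgm_io_error")
  }
  scfg <- synth_config(seed = config$seed)
  log_msg("simulating study: %d subjects x %d days x %d samples/day (seed %d)",
          config$study$n_subjects, config$study$n_days,
          config$study$samples_per_day, config$seed)
  study <- generate_study(scfg, config$study$n_subjects,
                          config$study$n_days, config$study$samples_per_day)
  m <- study$manifest
  m$file <- file.path("records", paste0(m$record, ".csv"))
  for (i in seq_len(nrow(m))) {
    write_record(study$records[[m$record[i]]], file.path(dir, m$file[i]))
  }
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  write_config_echo(config, dir)
  log_msg("wrote %d records and manifest.csv to %s", nrow(m), dir)
  invisible(m)
}

#' Extract the feature table from a simulated study on disk
#'
#' Reads `manifest.csv` and every record CSV from the run directory, runs
#' absorbance and PPG feature extraction, and writes `features.csv` with
#' the 12 feature columns in the fixed order plus metadata. Records whose
#' extraction fails are skipped and counted.
#'
#' @param config Configuration list.
#' @return The feature table, invisibly.
#' @export
cmd_features <- function(config = default_run_config()) {
  dir <- config$out_dir
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) {
    stop_nibgm(sprintf("no manifest.csv in %s (run cmd_simulate first)", dir),
               "nibgm_io_error")
  }
  m <- utils::read.csv(mf)
  if (nrow(m) == 0L) stop_nibgm("empty study manifest", "nibgm_io_error")
  rows <- vector("list", nrow(m))
  n_failed <- 0L
  for (i in seq_len(nrow(m))) {
    rows[[i]] <- tryCatch({
      rec <- read_record(file.path(dir, m$file[i]))
      fv <- extract_features(rec)
      cbind(m[i, setdiff(names(m), "file"), drop = FALSE],
            as.data.frame(as.list(unclass(fv))))
    }, error = function(e) {
      log_msg("record %s skipped: %s", m$record[i], conditionMessage(e))
      NULL
    })
    if (is.null(rows[[i]])) n_failed <- n_failed + 1L
  }
  if (n_failed > 0L) log_msg("%d record(s) failed feature extraction", n_failed)
  ft <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(ft) <- NULL
  utils::write.csv(ft, file.path(dir, "features.csv"), row.names = FALSE)
  log_msg("wrote features.csv (%d rows x %d columns)", nrow(ft), ncol(ft))
  invisible(ft)
}

#' Evaluate models on an extracted feature table
#'
#' Runs the configured evaluation scheme on `features.csv`:
#' `"baselines10"` (random 10-fold CV of the four classical baselines),
#' `"stmf8"` (day-grouped 8-fold CV of the fusion model with recursive
#' validation), or `"ablation"` (methods A/B/C on shared day folds).
#' Writes a flat `report.csv` and per-point prediction CSVs to the run
#' directory.
#'
#' @param config Configuration list.
#' @return The report object, invisibly.
#' @export
cmd_evaluate <- function(config = default_run_config()) {
  dir <- config$out_dir
  ff <- file.path(dir, "features.csv")
  if (!file.exists(ff)) {
    stop_nibgm(sprintf("no features.csv in %s (run cmd_features first)", dir),
               "nibgm_io_error")
  }
  ft <- utils::read.csv(ff)
  mode <- config$cv$mode
  mcfg <- config$model
  log_msg("evaluation mode '%s' (seed %d)", mode, config$seed)
  result <- switch(
    mode,
    baselines10 = {
      rep <- run_baselines(ft[, FEATURE_NAMES], ft$glucose,
                           k = config$cv$k_random, seed = config$seed,
                           variant = config$parkes_variant)
      utils::write.csv(attr(rep, "predictions"),
                       file.path(dir, "predictions_baselines.csv"),
                       row.names = FALSE)
      tab <- do.call(rbind, lapply(names(rep), function(m) {
        cbind(model = m, as.data.frame(rep[[m]]))
      }))
      utils::write.csv(tab, file.path(dir, "report.csv"), row.names = FALSE)
      rep
    },
    stmf8 = {
      rep <- run_stmf_cv(ft, k = config$cv$k_days,
                         days_per_fold = config$cv$days_per_fold,
                         seed = config$seed, epochs = mcfg$epochs,
                         variant = config$parkes_variant,
                         hidden_size = mcfg$hidden_size,
                         n_lstm_layers = mcfg$n_lstm_layers,
                         mlp_width = mcfg$mlp_width,
                         n_mlp_layers = mcfg$n_mlp_layers,
                         learning_rate = mcfg$learning_rate,
                         batch_days = mcfg$batch_days)
      utils::write.csv(attr(rep, "predictions"),
                       file.path(dir, "predictions_stmf.csv"),
                       row.names = FALSE)
      utils::write.csv(cbind(model = "stmf_lstm", as.data.frame(rep)),
                       file.path(dir, "report.csv"), row.names = FALSE)
      rep
    },
    ablation = {
      rep <- run_ablation(ft, k = config$cv$k_days,
                          days_per_fold = config$cv$days_per_fold,
                          seed = config$seed, epochs = mcfg$epochs,
                          variant = config$parkes_variant)
      utils::write.csv(rep$predictions$AB,
                       file.path(dir, "predictions_ablation_ab.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$predictions$C,
                       file.path(dir, "predictions_ablation_c.csv"),
                       row.names = FALSE)
      tab <- do.call(rbind, lapply(names(rep$reports), function(m) {
        cbind(method = m, as.data.frame(rep$reports[[m]]))
      }))
      utils::write.csv(tab, file.path(dir, "report.csv"), row.names = FALSE)
      rep
    },
    stop_nibgm(sprintf("unknown evaluation mode '%s'", mode),
               "nibgm_config_error")
  )
  write_config_echo(config, dir)
  log_msg("wrote report.csv to %s", dir)
  invisible(result)
}
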