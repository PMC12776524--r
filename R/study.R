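#' Study configuration
#'
#' Assembles and validates the configuration of an end-to-end simulation
#' study. Defaults reproduce the reference study conditions: n = 8000
#' observations of 31 variables, five planted pairs and five triplets
#' with weights of magnitude 0.05-0.3, linear coefficients N(0, 0.3), the
#' SNR grid {5, 3, 1, 0.5, 0.3, 0.1}, an MLP (35, 60, 32, 1) trained for
#' 100 epochs with batch size 50, learning rates 0.01 (regression) and
#' 0.003 (network), 20\% dropout, and an 80/2 train/sensitivity split.
#' Five replicate seeds are used so medians are stable.
#'
#' @param ... named overrides of the defaults (unknown names error).
#' @return an object of class `study_config` (a validated named list).
#' @export
study_config <- function(...) {
  defaults <- list(
    n = 8000, n_vars = 31,
    snr = c(5, 3, 1, 0.5, 0.3, 0.1),
    n_pairs = 5, n_triplets = 5,
    weight_range = c(0.05, 0.3), coef_sd = 0.3,
    off_diag_fraction = 0.6, off_diag_range = c(-0.3, 0.3),
    hidden = c(60, 32), dropout = 0.2,
    epochs = 100, batch_size = 50,
    lr_regression = 0.01, lr_network = 0.003,
    weight_decay = 0, optimizer = "adam",
    split = c(train = 0.8, sensitivity = 0.02),
    quantile = 0.84,
    seeds = 1:5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s. Valid keys: %s",
                  paste(unknown, collapse = ", "),
                  paste(names(defaults), collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  if (length(cfg$split) == 2L) names(cfg$split) <- c("train", "sensitivity")
  if (!length(cfg$snr) || any(!is.finite(cfg$snr)) || any(cfg$snr <= 0)) {
    abort("`snr` must be a non-empty vector of positive values")
  }
  if (anyDuplicated(cfg$seeds)) abort("`seeds` must be distinct")
  check_count(cfg$n, "n", lower = 10L)
  check_count(cfg$epochs, "epochs", lower = 0L)
  check_count(cfg$batch_size, "batch_size", lower = 1L)
  structure(cfg, class = "study_config")
}

#' Load a study configuration from YAML
#'
#' Absent keys fall back to the defaults of [study_config()]; unknown
#' keys are an error.
#'
#' @param path a YAML file. An empty file yields the full default
#'   configuration.
#' @return a `study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$split)) raw$split <- unlist(raw$split)
  if (!is.null(raw$weight_range)) raw$weight_range <- unlist(raw$weight_range)
  if (!is.null(raw$off_diag_range)) raw$off_diag_range <- unlist(raw$off_diag_range)
  do.call(study_config, raw)
}

#' Save a study configuration to YAML
#' @param config a `study_config`.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end simulation study
#'
#' For every replicate seed a complete dataset is generated (one base
#' sample and planted moderator, outcomes at every SNR); for every SNR a
#' ReGNN is trained with the fixed hyperparameters and the recovery
#' metrics are collected (see [evaluate_recovery()]). A failing cell is
#' recorded as failed and the sweep continues.
#'
#' @param config a `study_config`.
#' @param quiet suppress progress messages (default TRUE).
#' @return an object of class `study_result`: `records` (one row per
#'   SNR x seed), `aggregates` (per-SNR medians and IQRs), and the
#'   `config`.
#' @export
run_simulation_study <- function(config = study_config(), quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  records <- list()
  for (seed in config$seeds) {
    sim <- simulate_regnn_data(
      n = config$n, n_vars = config$n_vars, snr = config$snr,
      n_pairs = config$n_pairs, n_triplets = config$n_triplets,
      weight_range = config$weight_range, coef_sd = config$coef_sd,
      off_diag_fraction = config$off_diag_fraction,
      off_diag_range = config$off_diag_range, seed = seed
    )
    for (s in config$snr) {
      if (!quiet) message(sprintf("seed %d, snr %g ...", seed, s))
      rec <- tryCatch({
        fit <- regnn(sim, snr = s,
                     hidden = config$hidden, dropout = config$dropout,
                     epochs = config$epochs, batch_size = config$batch_size,
                     lr_regression = config$lr_regression,
                     lr_network = config$lr_network,
                     weight_decay = config$weight_decay,
                     optimizer = config$optimizer, split = config$split,
                     seed = seed, trace_with = NULL)
        out <- evaluate_recovery(fit, sim$truth$M, snr = s,
                                 quantile = config$quantile)
        out$sigma2_noise <- sim$outcomes$noise_variance[sim$outcomes$snr == s]
        out$seed <- seed
        out$failed <- FALSE
        out
      }, error = function(e) {
        warn(sprintf("cell (snr %g, seed %d) failed: %s", s, seed,
                     conditionMessage(e)))
        tibble::tibble(snr = s, rho = NA_real_, rmse_train = NA_real_,
                       rmse_sensitivity = NA_real_, p_train = NA_real_,
                       p_sensitivity = NA_real_, recall_at_q = NA_real_,
                       sigma2_noise = NA_real_, seed = seed, failed = TRUE)
      })
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- dplyr::bind_rows(records) |>
    dplyr::relocate("snr", "seed", "sigma2_noise")
  aggregates <- records |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$snr) |>
    dplyr::summarise(
      dplyr::across(c("sigma2_noise", "rho", "rmse_train", "rmse_sensitivity",
                      "p_train", "p_sensitivity", "recall_at_q"),
                    list(median = median, iqr = stats::IQR)),
      n_ok = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$snr))
  structure(list(records = records, aggregates = aggregates, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d cell(s): %d SNR level(s) x %d seed(s), %d failed\n",
              nrow(x$records), dplyr::n_distinct(x$records$snr),
              dplyr::n_distinct(x$records$seed), sum(x$records$failed)))
  print(as.data.frame(
    x$aggregates[, c("snr", "sigma2_noise_median", "rho_median",
                     "rmse_train_median", "rmse_sensitivity_median",
                     "p_train_median", "p_sensitivity_median",
                     "recall_at_q_median")]
  ), digits = 3)
  invisible(x)
}

#' Write the study report
#'
#' Writes the per-cell records (`records.csv`, the machine twin of the
#' study summary table), the per-SNR aggregates (`aggregates.csv`), and a
#' short markdown summary naming the seeds and configuration.
#'
#' @param study a `study_result`.
#' @param dir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
report <- function(study, dir) {
  stopifnot(inherits(study, "study_result"))
  if (!nrow(study$records)) abort("empty study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "records.csv")
  p2 <- file.path(dir, "aggregates.csv")
  p3 <- file.path(dir, "summary.md")
  write.csv(study$records, p1, row.names = FALSE)
  write.csv(study$aggregates, p2, row.names = FALSE)
  cfg <- study$config
  lines <- c(
    "# Simulation study summary", "",
    sprintf("- n = %d, %d variables, SNR grid {%s}", cfg$n, cfg$n_vars,
            paste(cfg$snr, collapse = ", ")),
    sprintf("- seeds: %s", paste(cfg$seeds, collapse = ", ")),
    sprintf("- network (%s), %d epochs, batch %d, lr %g/%g, dropout %g, optimizer %s",
            paste(c("q", cfg$hidden, 1), collapse = ", "), cfg$epochs,
            cfg$batch_size, cfg$lr_regression, cfg$lr_network, cfg$dropout,
            cfg$optimizer),
    sprintf("- failed cells: %d", sum(study$records$failed)), "",
    "Median recovery by SNR:", "",
    "| SNR | sigma2 | rho | RMSE (train) | RMSE (sens) | p (train) | p (sens) | recall |",
    "|-----|--------|-----|--------------|-------------|-----------|----------|--------|"
  )
  ag <- study$aggregates
  for (i in seq_len(nrow(ag))) {
    lines <- c(lines, sprintf(
      "| %g | %.3f | %.3f | %.3f | %.3f | %s | %s | %.2f |",
      ag$snr[i], ag$sigma2_noise_median[i], ag$rho_median[i],
      ag$rmse_train_median[i], ag$rmse_sensitivity_median[i],
      format_pval(ag$p_train_median[i]), format_pval(ag$p_sensitivity_median[i]),
      ag$recall_at_q_median[i]
    ))
  }
  writeLines(lines, p3)
  invisible(c(p1, p2, p3))
}
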