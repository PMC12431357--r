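#' Build a pipeline run configuration
#'
#' Collects the per-stage parameters of a full vital-signs extraction
#' run. Exactly one of `input` (path of a cube written by
#' [write_cube()]) or `simulate` (a list of [sim_config()] arguments)
#' must be provided. Any stage parameter left out keeps its default.
#'
#' @param input path to a stored radar cube, or `NULL`.
#' @param simulate list of [sim_config()] arguments, or `NULL`.
#' @param seed integer seed controlling every stochastic stage.
#' @param out_dir optional directory for intermediate artifacts and the
#'   report JSON.
#' @param preprocess,bss,cardio,metrics named lists overriding stage
#'   defaults (see Details in the package vignette).
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, seed = 1L, out_dir = NULL,
                       preprocess = list(), bss = list(), cardio = list(),
                       metrics = list()) {
  if (is.null(input) && is.null(simulate)) {
    uv_stop("config needs either an input cube or a simulation block",
            "uwbvitals_config_error")
  }
  if (!is.null(input) && !is.null(simulate)) {
    uv_stop("config must not give both an input cube and a simulation block",
            "uwbvitals_config_error")
  }
  pre <- utils::modifyList(list(max_lag = 10, na = 10, dc_window = 100,
                                half_width = 2, baseline = "beads",
                                baseline_cutoff_hz = 0.05,
                                phase_comp = "auto"), preprocess)
  bssd <- utils::modifyList(list(n_sources = NULL, resp_band = c(0.1, 0.6)), bss)
  card <- utils::modifyList(list(low = 0.85, high = 3.3, orders = 3:5,
                                 pole_radius = 0.995, feedback = 3,
                                 extension = "ar",
                                 hr_band = c(0.85, 2.0)), cardio)
  met <- utils::modifyList(list(snr_band = c(0, 2), rr_reference = NULL,
                                hr_reference = NULL), metrics)
  structure(list(input = input, simulate = simulate, seed = as.integer(seed),
                 out_dir = out_dir, preprocess = pre, bss = bssd,
                 cardio = card, metrics = met),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) uv_stop(sprintf("config '%s' not found", path),
                                  "uwbvitals_io_error")
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    uv_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "uwbvitals_stage_error")
  })
  if (!is.null(log)) {
    cat(sprintf("[%s] stage %-12s %.2fs\n",
                format(Sys.time(), "%H:%M:%S"), name,
                proc.time()[["elapsed"]] - t0),
        file = log, append = TRUE)
  }
  res
}

#' Run the full vital-signs extraction pipeline
#'
#' Executes the stages in processing order: (optional) simulation,
#' envelope alignment, phase compensation (complex cubes), DC drift
#' removal, target localization, five-channel extraction with baseline
#' removal, JADE source separation with respiratory-component
#' selection, and heartbeat recovery (band-pass, harmonic localization
#' from the respiratory waveform, feedback-notch cascade, spectral HR
#' estimation). SNR and - when references are supplied - rate
#' accuracies are attached.
#'
#' @param config a `run_config` (or list of its arguments, or the path
#'   of a YAML file).
#' @return object of class `vitals_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  log <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(config$out_dir, "run.log")
    cat(sprintf("[%s] run started, seed %d\n",
                format(Sys.time(), "%H:%M:%S"), config$seed),
        file = log)
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", log, {
      args <- config$simulate
      args$seed <- config$seed
      simulate_cube(do.call(sim_config, args))
    })
    cube <- sim$cube
    truth <- sim$truth
    if (!is.null(config$out_dir)) {
      write_cube(cube, file.path(config$out_dir, "cube.csv"))
      jsonlite::write_json(truth[c("rr_hz", "hr_hz", "target_bin")],
                           file.path(config$out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else {
    cube <- run_stage("read", log, read_cube(config$input))
  }

  pre <- config$preprocess
  align <- run_stage("align", log, envelope_align(cube, max_lag = pre$max_lag))
  # Fine (scalar) phase compensation needs a static reference scatterer
  # besides the target; with a lone prominent scatterer it would cancel
  # the vital phase itself, so "auto" applies it only when the scene has
  # at least two prominent clusters.
  do_comp <- is_complex_cube(cube) && pre$phase_comp != "off" &&
    (pre$phase_comp == "on" || length(prominent_clusters(align$aligned)) >= 2)
  comp <- if (do_comp) {
    run_stage("phase", log, phase_compensate(align, Na = pre$na))
  } else {
    align$aligned
  }
  dc <- run_stage("dc", log, remove_dc(comp, window = pre$dc_window))
  loc <- run_stage("locate", log, locate_target(dc))
  channels <- run_stage("channels", log, {
    ch <- extract_channels(dc, loc$bin, half_width = pre$half_width)
    remove_baseline(ch, method = pre$baseline, cutoff_hz = pre$baseline_cutoff_hz)
  })

  sep <- run_stage("separate", log, {
    m <- config$bss$n_sources
    if (is.null(m) || identical(m, "auto")) {
      # effective rank of the channel covariance: a clean scene collapses
      # all phase channels onto one source, a cluttered one keeps all
      xc <- channels$signals - rowMeans(channels$signals)
      ev <- eigen(tcrossprod(xc) / ncol(xc), symmetric = TRUE,
                  only.values = TRUE)$values
      m <- max(1L, sum(ev > 1e-8 * ev[1]))
    }
    jade_separate(channels, n_sources = m, resp_band = config$bss$resp_band)
  })
  resp <- run_stage("respiration", log,
                    select_respiratory(sep, band = config$bss$resp_band))
  rr <- run_stage("rr", log,
                  estimate_rate(resp$waveform, band = config$bss$resp_band))

  card <- config$cardio
  target_row <- which(channels$bin_labels == loc$bin)
  if (!length(target_row)) target_row <- (nrow(channels$signals) + 1L) %/% 2L
  rtp <- signal_trace(channels$signals[target_row, ], channels$rate, "target bin")
  heart <- run_stage("heartbeat", log, {
    bp <- bandpass_heart(rtp, low = card$low, high = card$high)
    harms <- locate_harmonics(resp$waveform, orders = card$orders,
                              band = c(card$low, card$high),
                              fund_band = config$bss$resp_band)
    hb <- suppress_harmonics(bp, harmonics = harms,
                             pole_radius = card$pole_radius,
                             feedback = card$feedback,
                             extension = card$extension)
    list(waveform = hb, harmonics = harms)
  })
  hr <- run_stage("hr", log,
                  estimate_hr(heart$waveform, band = card$hr_band))

  met <- config$metrics
  report <- structure(list(
    rr_hz = rr,
    hr_hz = hr,
    rr_accuracy_pct = if (!is.null(met$rr_reference)) rate_accuracy(rr, met$rr_reference) else NULL,
    hr_accuracy_pct = if (!is.null(met$hr_reference)) rate_accuracy(hr, met$hr_reference) else NULL,
    snr_resp_db = snr_db(resp$waveform, band = met$snr_band),
    snr_heart_db = snr_db(heart$waveform, band = met$snr_band),
    target_bin = loc$bin,
    component_index = resp$index,
    harmonics_hz = as.numeric(heart$harmonics),
    respiration = resp$waveform,
    heartbeat = heart$waveform,
    truth = truth,
    seed = config$seed), class = "vitals_report")

  if (!is.null(config$out_dir)) {
    utils::write.csv(data.frame(t(sep$components)),
                     file.path(config$out_dir, "components.csv"),
                     row.names = FALSE)
    write_trace(resp$waveform, file.path(config$out_dir, "respiration.csv"))
    write_trace(heart$waveform, file.path(config$out_dir, "heartbeat.csv"))
    jsonlite::write_json(
      report[c("rr_hz", "hr_hz", "rr_accuracy_pct", "hr_accuracy_pct",
               "snr_resp_db", "snr_heart_db", "target_bin",
               "component_index", "harmonics_hz")],
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.vitals_report <- function(x, ...) {
  cat("<vitals_report>\n")
  cat(sprintf("  RR %.4f Hz (%.1f breaths/min)%s\n", x$rr_hz, 60 * x$rr_hz,
              if (!is.null(x$rr_accuracy_pct))
                sprintf(", accuracy %.2f%%", x$rr_accuracy_pct) else ""))
  cat(sprintf("  HR %.4f Hz (%.1f beats/min)%s\n", x$hr_hz, 60 * x$hr_hz,
              if (!is.null(x$hr_accuracy_pct))
                sprintf(", accuracy %.2f%%", x$hr_accuracy_pct) else ""))
  cat(sprintf("  SNR: respiration %.2f dB, heartbeat %.2f dB\n",
              x$snr_resp_db, x$snr_heart_db))
  cat(sprintf("  target bin %d, respiratory component %d, notches at %s Hz\n",
              x$target_bin, x$component_index,
              paste(sprintf("%.3f", x$harmonics_hz), collapse = ", ")))
  invisible(x)
}
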