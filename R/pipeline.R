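#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the input (a list of
#' [decay_trace()] objects, a directory of trace CSVs, a
#' [temperature_series()], or a series CSV path), the region-of-interest
#' windows, decay-fit options, and transition-fit options. Temperatures are
#' taken from trace labels; traces without one are skipped with a reason.
#'
#' @param input list of `decay_trace`s, a directory path, a
#'   `temperature_series`, or a series CSV path.
#' @param roi a [roi_config()].
#' @param n_max,weighting passed to [fit_multiexponential()].
#' @param uncertainty,n_boot,seed passed to [fit_transition()].
#' @param output_dir optional directory for intermediate CSV/JSON artifacts;
#'   created if missing. NULL writes nothing.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, roi = roi_config(), n_max = 5L,
                            weighting = "poisson",
                            uncertainty = "covariance", n_boot = 500L,
                            seed = 1L, output_dir = NULL) {
  stopifnot(inherits(roi, "roi_config"))
  mode <- if (inherits(input, "temperature_series")) "series"
  else if (is.character(input) && length(input) == 1L) {
    if (dir.exists(input)) "trace_dir"
    else if (file.exists(input)) "series_file"
    else stop("input path does not exist: ", input)
  } else if (is.list(input) &&
             all(vapply(input, inherits, logical(1), "decay_trace"))) {
    if (length(input) == 0L) stop("no input traces")
    "trace_list"
  } else stop("unrecognized input: need traces, a directory, or a series")
  structure(
    list(input = input, mode = mode, roi = roi, n_max = n_max,
         weighting = weighting, uncertainty = uncertainty,
         n_boot = n_boot, seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the full lifetime-to-thermodynamics pipeline
#'
#' The two-stage procedure: every decay trace is deconvolved with
#' [fit_multiexponential()] and summarized by its ensemble-average lifetime;
#' the per-temperature averages form a series whose frozen-window mean
#' defines tau0; the series is normalized and the two-state model fitted
#' over the transition window. A trace whose decay fit fails is excluded
#' with a logged reason rather than aborting; the run aborts only if the
#' series stage lacks the minimum points. Deterministic given the
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: `decay_summaries` (data.frame:
#'   temperature, tau_avg, n_components, reduced_chi2, background),
#'   `skipped` (data.frame: label, reason), `tau0`, `tau0_sd`, `transition`
#'   (a `transition_fit_result`), `log` (character), `config` echo,
#'   `version`, `elapsed_s`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- proc.time()[["elapsed"]]
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  say("windows: baseline [", config$roi$baseline_window[1], ", ",
      config$roi$baseline_window[2], "] K, fit [",
      config$roi$fit_window[1], ", ", config$roi$fit_window[2], "] K")
  say("seed: ", config$seed)

  decay_summaries <- NULL
  skipped <- data.frame(label = character(0), reason = character(0))
  series <- NULL
  tau0 <- NA_real_
  tau0_sd <- NA_real_

  if (config$mode %in% c("trace_list", "trace_dir")) {
    traces <- if (config$mode == "trace_list") config$input else {
      paths <- sort(list.files(config$input, pattern = "\\.csv$",
                               full.names = TRUE))
      if (length(paths) == 0L) stop("no input traces in ", config$input)
      lapply(paths, read_trace)
    }
    rows <- list()
    for (i in seq_along(traces)) {
      tr <- traces[[i]]
      label <- if (!is.na(tr$temperature)) sprintf("T=%.1fK", tr$temperature)
               else sprintf("trace %d", i)
      if (is.na(tr$temperature)) {
        skipped <- rbind(skipped,
                         data.frame(label = label,
                                    reason = "no temperature label"))
        say("skipped ", label, ": no temperature label")
        next
      }
      res <- tryCatch(
        fit_multiexponential(tr, n_max = config$n_max,
                             weighting = config$weighting),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- rbind(skipped,
                         data.frame(label = label,
                                    reason = conditionMessage(res)))
        say("skipped ", label, ": ", conditionMessage(res))
        next
      }
      say(label, ": n = ", res$mixture$n, ", tau_avg = ",
          format(res$tau_avg, digits = 6), " ms, reduced chi2 = ",
          format(res$reduced_chi2, digits = 4))
      rows[[length(rows) + 1L]] <- data.frame(
        temperature = tr$temperature,
        tau_avg = res$tau_avg,
        n_components = res$mixture$n,
        reduced_chi2 = res$reduced_chi2,
        background = res$background
      )
    }
    if (length(rows) == 0L) stop("no input traces survived the decay stage")
    decay_summaries <- do.call(rbind, rows)
    decay_summaries <- decay_summaries[order(decay_summaries$temperature), ]
    series <- temperature_series(decay_summaries$temperature,
                                 tau_avg = decay_summaries$tau_avg)
  } else {
    series <- if (config$mode == "series") config$input
              else read_series(config$input)
  }

  if (!is.null(series$tau_avg)) {
    b <- compute_tau0(series, config$roi)
    tau0 <- b$tau0
    tau0_sd <- b$sd
    say("tau0 = ", format(tau0, digits = 6), " +/- ",
        format(tau0_sd, digits = 3), " ms over ", b$n_points,
        " baseline points")
    series <- normalize_series(series, tau0)
  } else {
    say("series provides ratio only; tau0 stage skipped")
  }

  transition <- fit_transition(series, roi = config$roi,
                               uncertainty = config$uncertainty,
                               n_boot = config$n_boot, seed = config$seed,
                               tau0 = if (is.na(tau0)) NULL else tau0)
  say("transition: dE = ", format(transition$params$delta_E, digits = 6),
      " kJ/mol, dS = ", format(transition$params$delta_S, digits = 6),
      " J/(mol K), K_d = ", format(transition$params$K_d, digits = 6),
      ", T_MP = ", format(transition$T_MP, digits = 6), " K")

  report <- structure(
    list(
      decay_summaries = decay_summaries,
      skipped = skipped,
      tau0 = tau0,
      tau0_sd = tau0_sd,
      series = series,
      transition = transition,
      log = log_lines,
      config = config[c("mode", "n_max", "weighting", "uncertainty",
                        "n_boot", "seed")],
      roi = unclass(config$roi),
      version = as.character(utils::packageVersion("phosdyn")),
      elapsed_s = proc.time()[["elapsed"]] - t_start
    ),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) .write_artifacts(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$decay_summaries))
    cat("  ", nrow(x$decay_summaries), "traces fitted,",
        nrow(x$skipped), "skipped\n")
  if (!is.na(x$tau0))
    cat(sprintf("  tau0 = %.4g +/- %.2g ms\n", x$tau0, x$tau0_sd))
  print(x$transition)
  invisible(x)
}

.write_artifacts <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(report$decay_summaries))
    utils::write.csv(report$decay_summaries,
                     file.path(dir, "decay_summaries.csv"),
                     row.names = FALSE)
  write_series(report$series, file.path(dir, "series.csv"))
  write_report(report, file.path(dir, "run_report.json"))
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Serialize a run report (or transition fit) to JSON
#'
#' Writes every fitted quantity — per-trace summaries, tau0, the two-state
#' parameters with SDs, the midpoint temperature, goodness of fit, windows,
#' and method metadata — as plain JSON so each number in the report is
#' traceable on disk.
#'
#' @param report a `run_report` or `transition_fit_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- if (inherits(report, "transition_fit_result"))
    .transition_json(report)
  else {
    stopifnot(inherits(report, "run_report"))
    list(
      version = report$version,
      config = report$config,
      roi = report$roi,
      decay_summaries = report$decay_summaries,
      skipped = report$skipped,
      tau0_ms = report$tau0,
      tau0_sd_ms = report$tau0_sd,
      transition = .transition_json(report$transition),
      log = report$log
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

.transition_json <- function(tf) {
  list(
    delta_E_kJ_mol = tf$params$delta_E,
    delta_S_J_mol_K = tf$params$delta_S,
    K_d = tf$params$K_d,
    tau0_ms = tf$params$tau0,
    T_MP_K = tf$T_MP,
    sd = as.list(tf$sd),
    T_MP_sd_K = tf$T_MP_sd,
    reduced_chi2 = tf$reduced_chi2,
    n_points = tf$n_points,
    converged = tf$converged,
    method = tf$method_meta
  )
}
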