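#' Temperature series of ensemble-average lifetimes
#'
#' The per-temperature summary of a warming experiment: temperatures (K,
#' strictly increasing), the ensemble-average lifetime `tau_avg` (ms) and/or
#' the normalized ratio `tau_avg / tau0`, optional per-point uncertainties,
#' and provenance metadata (which carries the generator ground truth for
#' synthetic series). At least one of `tau_avg`, `ratio` must be present; if
#' both are given together with a `tau0` in the provenance, their consistency
#' is checked to relative 1e-9.
#'
#' @param temperatures strictly increasing temperatures (K), > 0.
#' @param tau_avg ensemble-average lifetimes (ms) or NULL.
#' @param ratio normalized lifetimes or NULL.
#' @param sd optional per-point uncertainties: on the ratio scale when
#'   `ratio` is present, otherwise on the `tau_avg` (ms) scale.
#' @param provenance free-form metadata list; `provenance$tau0` links the two
#'   scales.
#' @return an object of class `temperature_series`.
#' @export
temperature_series <- function(temperatures, tau_avg = NULL, ratio = NULL,
                               sd = NULL, provenance = list()) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1L) stop("empty temperature list")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop("temperatures must be finite and > 0 K")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  if (is.null(tau_avg) && is.null(ratio))
    stop("at least one of tau_avg, ratio must be present")
  for (v in list(tau_avg, ratio, sd)) {
    if (!is.null(v) && length(v) != length(temperatures))
      stop("tau_avg/ratio/sd must match the number of temperatures")
  }
  if (!is.null(tau_avg) && !is.null(ratio) && !is.null(provenance$tau0)) {
    if (max(abs(ratio * provenance$tau0 - tau_avg)) >
        1e-9 * max(abs(tau_avg)))
      stop("inconsistent series: ratio * tau0 differs from tau_avg")
  }
  structure(
    list(temperatures = temperatures, tau_avg = tau_avg, ratio = ratio,
         sd = sd, provenance = provenance),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> %d points, %.1f-%.1f K%s%s\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures),
              if (is.null(x$tau_avg)) "" else ", tau_avg",
              if (is.null(x$ratio)) "" else ", ratio"))
  invisible(x)
}

#' Region-of-interest windows for baseline and transition fitting
#'
#' The frozen-state baseline window (default 10-180 K, over which the
#' average lifetime is flat and its mean defines the normalization factor
#' tau0) and the transition fit window (default 180-245 K, covering the
#' protein-specific transition while excluding the higher-temperature
#' solvent-driven drop).
#'
#' @param baseline_window numeric length-2, `[T_lo, T_hi]` K.
#' @param fit_window numeric length-2, must start at or above the baseline
#'   window's end.
#' @return an object of class `roi_config`.
#' @export
roi_config <- function(baseline_window = c(10, 180),
                       fit_window = c(180, 245)) {
  for (w in list(baseline_window, fit_window)) {
    if (length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2])
      stop("windows must be [T_lo, T_hi] with T_lo < T_hi")
  }
  if (fit_window[1] < baseline_window[2])
    stop("fit_window must start at or above the baseline window end")
  structure(list(baseline_window = baseline_window, fit_window = fit_window),
            class = "roi_config")
}

#' Frozen-state reference lifetime from the baseline window
#'
#' The ensemble-average lifetime does not change significantly in the frozen
#' regime; its mean over the baseline window is the normalization factor
#' tau0, with the sample standard deviation as its spread.
#'
#' @param series a [temperature_series()] with `tau_avg` present.
#' @param roi a [roi_config()].
#' @return a list with `tau0` (ms), `sd` (ms), and `n_points`.
#' @export
compute_tau0 <- function(series, roi = roi_config()) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(roi, "roi_config"))
  if (is.null(series$tau_avg))
    stop("series has no tau_avg values; cannot compute tau0")
  inside <- series$temperatures >= roi$baseline_window[1] &
    series$temperatures <= roi$baseline_window[2]
  if (sum(inside) < 3L)
    stop("too few baseline points: need >= 3 inside the baseline window, got ",
         sum(inside))
  vals <- series$tau_avg[inside]
  list(tau0 = mean(vals), sd = stats::sd(vals), n_points = sum(inside))
}

#' Normalize a lifetime series by the reference lifetime
#'
#' Divides each `tau_avg` by `tau0`. Per-point uncertainties on the
#' lifetime scale are propagated by the same division; a series that
#' already carries a ratio keeps its (ratio-scale) uncertainties unchanged.
#'
#' @param series a [temperature_series()] with `tau_avg`.
#' @param tau0 reference lifetime (ms), > 0.
#' @return a `temperature_series` with `ratio` filled in and
#'   `provenance$tau0` recorded.
#' @export
normalize_series <- function(series, tau0) {
  stopifnot(inherits(series, "temperature_series"))
  if (!is.finite(tau0) || tau0 <= 0) stop("tau0 must be > 0")
  if (is.null(series$tau_avg)) stop("series has no tau_avg to normalize")
  prov <- series$provenance
  prov$tau0 <- tau0
  temperature_series(
    series$temperatures,
    tau_avg = series$tau_avg,
    ratio = series$tau_avg / tau0,
    sd = if (is.null(series$sd)) NULL
         else if (is.null(series$ratio)) series$sd / tau0
         else series$sd,
    provenance = prov
  )
}

#' Read / write a temperature series as CSV
#'
#' Columns `temperature_K`, `tau_ms`, `ratio`, `sd` (the latter three may be
#' empty). Numeric fields round-trip to 15 significant digits. Rows must be
#' sorted by strictly increasing temperature; offending row numbers are
#' reported otherwise.
#'
#' @param series a [temperature_series()].
#' @param path CSV path.
#' @return `write_series` returns `path` invisibly; `read_series` a
#'   `temperature_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "temperature_series"))
  n <- length(series$temperatures)
  df <- data.frame(
    temperature_K = format(series$temperatures, digits = 15, trim = TRUE),
    tau_ms = .fmt_col(series$tau_avg, n),
    ratio = .fmt_col(series$ratio, n),
    sd = .fmt_col(series$sd, n)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.fmt_col <- function(x, n) {
  if (is.null(x)) rep("", n) else format(x, digits = 15, trim = TRUE)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- "temperature_K"
  if (!need %in% names(df))
    stop("series CSV must have a temperature_K column")
  parse_num <- function(col) {
    if (!col %in% names(df)) return(NULL)
    raw <- trimws(df[[col]])
    if (all(raw == "" | is.na(raw))) return(NULL)
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(out))
    if (length(bad))
      stop("non-numeric ", col, " at row(s) ", paste(bad, collapse = ", "))
    out
  }
  tt <- parse_num("temperature_K")
  if (is.null(tt)) stop("temperature_K column is empty")
  if (is.unsorted(tt, strictly = TRUE)) {
    bad <- which(diff(tt) <= 0) + 1L
    stop("temperatures not strictly increasing at row(s) ",
         paste(bad, collapse = ", "))
  }
  temperature_series(tt,
                     tau_avg = parse_num("tau_ms"),
                     ratio = parse_num("ratio"),
                     sd = parse_num("sd"))
}
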