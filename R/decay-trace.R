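#' Binned photon-counting decay trace
#'
#' A single phosphorescence decay measured (or simulated) at one temperature:
#' uniform time bins with nonnegative photon counts. `times` are bin-start
#' times in ms; uniformity of the spacing is enforced to relative 1e-9.
#'
#' @param times bin-start times (ms), strictly increasing, uniform spacing.
#' @param counts nonnegative counts per bin, same length as `times`.
#' @param temperature optional temperature label (K).
#' @param meta free-form provenance list.
#' @return an object of class `decay_trace`.
#' @export
decay_trace <- function(times, counts, temperature = NA_real_, meta = list()) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) < 2L) stop("a trace needs at least 2 bins")
  if (length(counts) != length(times))
    stop("counts length must equal times length")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("non-uniform binning: bin spacing varies by more than relative 1e-9")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0")
  structure(
    list(times = times, counts = counts, bin_width = dt[1],
         temperature = temperature, meta = meta),
    class = "decay_trace"
  )
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf(
    "<decay_trace> %d bins of %.4g ms, total %.4g counts%s\n",
    length(x$times), x$bin_width, sum(x$counts),
    if (is.na(x$temperature)) "" else sprintf(", T = %.1f K", x$temperature)))
  invisible(x)
}

#' Write / read a decay trace as two-column CSV
#'
#' Plain CSV with header `time_ms,counts`. A sidecar JSON (same path with
#' extension `.json`) records the temperature label and any metadata, so the
#' trace round-trips losslessly.
#'
#' @param trace a [decay_trace()].
#' @param path output CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   `decay_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "decay_trace"))
  utils::write.csv(
    data.frame(time_ms = trace$times, counts = trace$counts),
    path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(temperature_K = trace$temperature, meta = trace$meta),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "counts") %in% names(df)))
    stop("trace CSV must have columns time_ms,counts")
  temperature <- NA_real_
  meta <- list()
  side <- sub("\\.csv$", ".json", path)
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(js$temperature_K)) temperature <- as.numeric(js$temperature_K)
    if (!is.null(js$meta)) meta <- js$meta
  }
  decay_trace(df$time_ms, df$counts, temperature = temperature, meta = meta)
}
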