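#' Calibration data table
#'
#' The calibration data is an ordered table of measurements, one row per
#' observation: the measurement time, the observed value, the (known, fixed)
#' noise scale, and a condition label selecting the experimental regime the
#' model is simulated under (e.g. `"control"` vs `"treated"`). Multiple
#' conditions are flattened into a single residual vector, so a simultaneous
#' fit to several experiments is a single objective.
#'
#' @param times numeric vector of measurement times (model time units; days
#'   for both built-in dynamical models).
#' @param values numeric vector of observed values, one per time.
#' @param sigma numeric vector of noise scales (same units as `values`),
#'   recycled; strictly positive. Defaults to 1.
#' @param condition character vector of condition labels, recycled. Defaults
#'   to `"control"`.
#'
#' @return A `calibration_data` object: a `data.frame` with columns `time`,
#'   `value`, `sigma`, `condition`. Within each condition, times must be
#'   strictly increasing.
#' @examples
#' calibrationData(c(1, 2, 3), c(0.4, 1.1, 2.0))
#' @export
calibrationData <- function(times, values, sigma = 1, condition = "control") {
  d <- length(times)
  df <- data.frame(
    time = as.numeric(times),
    value = as.numeric(values),
    sigma = rep_len(as.numeric(sigma), d),
    condition = rep_len(as.character(condition), d),
    stringsAsFactors = FALSE
  )
  class(df) <- c("calibration_data", "data.frame")
  validateCalibrationData(df)
  df
}

validateCalibrationData <- function(data) {
  stopifnot(inherits(data, "data.frame"))
  need <- c("time", "value", "sigma", "condition")
  miss <- setdiff(need, base::names(data))
  if (length(miss)) stop("calibration data missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 1L) stop("calibration data must have at least one row")
  if (anyNA(data$time) || anyNA(data$value) || anyNA(data$sigma)) {
    stop("calibration data contains missing values")
  }
  if (any(data$sigma <= 0)) stop("noise scales must be strictly positive")
  for (cond in unique(data$condition)) {
    tt <- data$time[data$condition == cond]
    if (any(diff(tt) <= 0)) {
      stop("times must be strictly increasing within condition '", cond, "'")
    }
  }
  invisible(data)
}

#' @export
print.calibration_data <- function(x, ...) {
  cat("<calibration_data> d =", nrow(x), "rows,",
      length(unique(x$condition)), "condition(s)\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read / write calibration data as CSV
#'
#' The on-disk format is a CSV with header `time,value,sigma,condition`.
#' `sigma` and `condition` are optional on input and default to 1 and
#' `"control"`.
#'
#' @param path file path.
#' @return `readCalibrationCSV` returns a [calibrationData()] object;
#'   `writeCalibrationCSV` invisibly returns `path`.
#' @export
readCalibrationCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$sigma)) df$sigma <- 1
  if (is.null(df$condition)) df$condition <- "control"
  calibrationData(df$time, df$value, df$sigma, df$condition)
}

#' @rdname readCalibrationCSV
#' @param data a `calibration_data` object.
#' @export
writeCalibrationCSV <- function(data, path) {
  validateCalibrationData(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Replace the observed values of a calibration table
#'
#' Convenience for perturbation studies where the design (times, noise scales,
#' conditions) is fixed and only the measured values change.
#'
#' @param data a `calibration_data` object.
#' @param values_new numeric vector, one value per row of `data`.
#' @return a `calibration_data` object.
#' @export
setDataValues <- function(data, values_new) {
  stopifnot(length(values_new) == nrow(data))
  data$value <- as.numeric(values_new)
  validateCalibrationData(data)
  data
}

## Row labels used in reports: "time@condition"
dataRowLabels <- function(data) {
  paste0(format(data$time, trim = TRUE), "@", data$condition)
}
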