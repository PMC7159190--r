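#' Construct a biomarker time series
#'
#' The atomic input of every analysis stage: one subject-by-element profile of
#' calcium-normalized ion counts (or any univariate biomarker) on a strictly
#' increasing developmental time axis in years since birth.
#'
#' @param time Numeric vector of sampling times (years), strictly increasing.
#' @param values Numeric vector of measurements, same length as `time`, finite.
#' @param subject_id Optional subject identifier.
#' @param element Optional element (or biomarker) label.
#' @return An object of class `biomarker_series`: a list with fields `time`,
#'   `values`, `subject_id`, `element`, `n`.
#' @examples
#' s <- biomarker_series(seq(0, 10, length.out = 200), sin(1:200 / 5))
#' print(s)
#' @export
biomarker_series <- function(time, values, subject_id = NA_character_,
                             element = NA_character_) {
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values)) {
    stop("`time` and `values` must have equal length")
  }
  if (length(time) < 2) stop("a series needs at least 2 samples")
  if (any(!is.finite(values))) stop("`values` must be finite")
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop("`time` must be finite and strictly increasing")
  }
  structure(
    list(time = time, values = values,
         subject_id = as.character(subject_id),
         element = as.character(element),
         n = length(values)),
    class = "biomarker_series"
  )
}

#' @export
print.biomarker_series <- function(x, ...) {
  cat(sprintf("<biomarker_series> %s / %s: %d samples, %.2f-%.2f yr\n",
              x$subject_id, x$element, x$n, min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.biomarker_series <- function(x, ...) {
  data.frame(time_years = x$time, value = x$values)
}

#' @export
plot.biomarker_series <- function(x, ...) {
  graphics::plot(x$time, x$values, type = "l",
                 xlab = "time since birth (years)", ylab = "value",
                 main = paste(x$subject_id, x$element), ...)
  invisible(x)
}

# Accept either a biomarker_series or a bare numeric vector.
series_values <- function(series) {
  if (inherits(series, "biomarker_series")) series$values
  else if (is.numeric(series)) as.numeric(series)
  else stop("expected a `biomarker_series` or a numeric vector")
}

series_time <- function(series, n = NULL) {
  if (inherits(series, "biomarker_series")) series$time
  else seq_len(if (is.null(n)) length(series) else n)
}
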