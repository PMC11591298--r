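#' Construct a waveform
#'
#' A waveform is a named, unit-tagged quantity sampled on a 0-100%
#' activity-cycle grid. It is the carrier for every profile handled by the
#' package: condylar low-point translations, knee flexion, tibiofemoral
#' compression, quadriceps force, and the derived simulator load profiles.
#'
#' @param percent_cycle strictly increasing numeric vector in `[0, 100]`.
#' @param values numeric vector, same length as `percent_cycle`, finite.
#' @param quantity label for the sampled quantity (e.g. `"quadriceps"`).
#' @param units unit label (e.g. `"N"`, `"mm"`, `"deg"`).
#' @param activity activity label (e.g. `"gait"`).
#' @return an object of class `"waveform"`.
#' @export
#' @examples
#' wf <- waveform(seq(0, 100, by = 1), sin(seq(0, 2 * pi, length.out = 101)),
#'                "flexion", "deg", "gait")
#' print(wf)
waveform <- function(percent_cycle, values, quantity = "value", units = "",
                     activity = "") {
  percent_cycle <- as.numeric(percent_cycle)
  values <- as.numeric(values)
  if (length(percent_cycle) != length(values))
    stop("percent_cycle and values must have equal length")
  if (length(percent_cycle) < 2L)
    stop("a waveform needs at least two samples")
  if (any(diff(percent_cycle) <= 0))
    stop("percent_cycle must be strictly increasing")
  if (any(percent_cycle < 0 | percent_cycle > 100))
    stop("percent_cycle must lie in [0, 100]")
  if (!all(is.finite(values)))
    stop("waveform values must be finite")
  structure(list(quantity = quantity, units = units, activity = activity,
                 percent_cycle = percent_cycle, values = values),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s [%s] %s: %d nodes on [%g, %g]%%, range [%g, %g]\n",
              x$quantity, x$units, x$activity, length(x$values),
              min(x$percent_cycle), max(x$percent_cycle),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(activity = x$activity, quantity = x$quantity,
             percent_cycle = x$percent_cycle, value = x$values,
             units = x$units, stringsAsFactors = FALSE)
}

is_waveform <- function(x) inherits(x, "waveform")

# Linear interpolation of a waveform at new percent-cycle locations.
wf_interp <- function(wf, percent) {
  stats::approx(wf$percent_cycle, wf$values, xout = percent, rule = 2)$y
}

# Replace values, keeping metadata.
wf_with <- function(wf, values, quantity = wf$quantity, units = wf$units) {
  waveform(wf$percent_cycle, values, quantity, units, wf$activity)
}

# Check that waveforms share one grid.
wf_common_grid <- function(...) {
  wfs <- list(...)
  g <- wfs[[1L]]$percent_cycle
  for (w in wfs[-1L])
    if (length(w$percent_cycle) != length(g) ||
        any(abs(w$percent_cycle - g) > 1e-9))
      stop("waveforms are not on a common percent-cycle grid")
  g
}

#' Resample a timed series onto the uniform activity-cycle grid
#'
#' Time normalization maps raw `(time, value)` samples of one movement
#' cycle onto a uniform 0-100% grid by linear interpolation, the
#' prerequisite for averaging trials of different durations.
#'
#' @param time strictly increasing sample times (any unit).
#' @param values sample values.
#' @param n_nodes number of grid nodes (default 101, i.e. 0, 1, ..., 100%).
#' @inheritParams waveform
#' @return a [waveform()] on `seq(0, 100, length.out = n_nodes)`.
#' @export
#' @examples
#' time_normalize(c(0, 0.4, 1.2), c(0, 2, 6), n_nodes = 5)$values
time_normalize <- function(time, values, n_nodes = 101L, quantity = "value",
                           units = "", activity = "") {
  time <- as.numeric(time)
  values <- as.numeric(values)
  if (length(time) != length(values)) stop("time and values lengths differ")
  if (length(time) < 2L) stop("need at least two samples")
  if (any(duplicated(time))) stop("duplicate timestamps")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  pct <- (time - time[1L]) / (time[length(time)] - time[1L]) * 100
  grid <- seq(0, 100, length.out = n_nodes)
  waveform(grid, stats::approx(pct, values, xout = grid)$y,
           quantity, units, activity)
}
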