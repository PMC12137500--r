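#' Summary statistics of a run
#'
#' Mean, sample standard deviation, extremes and quartiles of the measured
#' (four-center-pixel) temperature over an analysis window. The default
#' window is the final two-thirds of the run, separating the initial heating
#' ramp from the regulated phase; quartiles use the linear-interpolation
#' convention (`stats::quantile()` type 7).
#'
#' @param record A `thermo_run` record.
#' @param window Length-2 numeric `c(from, to)` in seconds, or `NULL` for the
#'   final two-thirds.
#' @return An object of class `run_summary`: list with `mean`, `sd`, `min`,
#'   `q1`, `median`, `q3`, `max` (degC), `n_samples` and `window`.
#' @export
#' @examples
#' rec <- structure(
#'   data.frame(time_s = 0:2, frame_temp_C = c(41, 42, 43)),
#'   class = c("thermo_run", "data.frame"))
#' summarize_run(rec, window = c(0, 2))
summarize_run <- function(record, window = NULL) {
  stopifnot(inherits(record, "data.frame"), nrow(record) > 0)
  t_max <- max(record$time_s)
  if (is.null(window)) window <- c(t_max / 3, t_max)
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- record$time_s >= window[1] - 1e-9 & record$time_s <= window[2] + 1e-9
  x <- record$frame_temp_C[sel]
  x <- x[is.finite(x)]
  if (length(x) == 0) {
    stop("analysis window contains no samples", call. = FALSE)
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(mean = mean(x), sd = stats::sd(x), min = min(x),
         q1 = q[1], median = q[2], q3 = q[3], max = max(x),
         n_samples = length(x), window = window),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "<run_summary> window %.0f-%.0f s (n = %d)\n  mean %.2f +/- %.2f degC; min %.2f, Q1 %.2f, median %.2f, Q3 %.2f, max %.2f\n",
    x$window[1], x$window[2], x$n_samples, x$mean,
    if (is.na(x$sd)) 0 else x$sd, x$min, x$q1, x$median, x$q3, x$max))
  invisible(x)
}

#' Arrhenius thermal-damage integral
#'
#' Cumulative damage
#' \deqn{\Omega(t) = \int_0^t A \exp\left(\frac{-E_a}{R\,T(\tau)}\right)
#'   d\tau,}
#' with `T` in kelvin and `R` the gas constant, integrated by the trapezoidal
#' rule over the measured temperature trace. At constant temperature the
#' damage accrues exactly linearly in time; under a linearly rising
#' temperature it grows super-linearly — the rationale for regulating
#' temperature rather than power. `Omega = 1` conventionally marks the
#' damage threshold (e.g. 63% protein denaturation for coagulation kinetics).
#'
#' @param record A `thermo_run` record, or a numeric vector of temperatures
#'   (degC) with `times` supplied.
#' @param A Frequency factor, 1/s.
#' @param Ea Activation energy, J/mol.
#' @param times Sample times, s (required when `record` is a bare vector).
#' @return Numeric vector `Omega(t)` at the record's time points
#'   (monotone non-decreasing, starting at 0).
#' @seealso [arrhenius_presets()]
#' @export
#' @examples
#' arrhenius_damage(rep(60, 5), times = 0:4,
#'                  A = arrhenius_presets()$liver$A,
#'                  Ea = arrhenius_presets()$liver$Ea)
arrhenius_damage <- function(record, A, Ea, times = NULL) {
  if (inherits(record, "data.frame")) {
    temps <- record$frame_temp_C
    times <- record$time_s
  } else {
    temps <- record
    if (is.null(times)) stop("supply times for a bare temperature vector",
                             call. = FALSE)
  }
  stopifnot(length(temps) == length(times), length(temps) >= 2,
            is.finite(A), is.finite(Ea), A > 0, Ea > 0)
  if (any(!is.finite(temps)) || any(temps <= -273.15)) {
    stop("temperatures must be finite and above absolute zero", call. = FALSE)
  }
  gas_const <- 8.314462618  # J/(mol K)
  rate <- A * exp(-Ea / (gas_const * (temps + 273.15)))
  as.vector(pracma::cumtrapz(times, rate))
}

#' Arrhenius kinetics presets
#'
#' Commonly used damage-kinetics parameter sets. `skin` is the classic
#' Henriques-Moritz fit for thermal injury of skin; `liver` is a
#' literature-typical coagulation fit for liver tissue. The bench device these
#' simulations emulate does not fix kinetics; choose (or supply) parameters
#' appropriate to the tissue.
#'
#' @return A named list of lists with elements `A` (1/s) and `Ea` (J/mol).
#' @export
#' @examples
#' arrhenius_presets()$skin
arrhenius_presets <- function() {
  list(
    skin = list(A = 3.1e98, Ea = 6.28e5),
    liver = list(A = 7.39e39, Ea = 2.577e5)
  )
}

#' Write and read run records
#'
#' A run is stored as a CSV of the per-tick log plus a JSON sidecar
#' (`<path>.json`) holding the metadata (mode, material, seed, configuration,
#' schema version). The round trip is lossless for all logged fields; columns
#' the reader does not know are preserved.
#'
#' @param record A `thermo_run` record.
#' @param path CSV file path; metadata goes to `paste0(path, ".json")`.
#' @return `write_run()` returns `path` invisibly; `read_run()` returns the
#'   `thermo_run`.
#' @export
write_run <- function(record, path) {
  stopifnot(inherits(record, "thermo_run"))
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  meta <- attr(record, "meta")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) {
                   stop(sprintf("malformed run file '%s': %s", path,
                                conditionMessage(e)), call. = FALSE)
                 })
  required <- c("time_s", "frame_temp_C", "output_percent", "power_W",
                "current_A")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("run file '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop(sprintf("run file '%s': time_s must be strictly increasing", path),
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(mode = "unknown", config = NULL)
  }
  attr(df, "meta") <- meta
  class(df) <- c("thermo_run", "data.frame")
  df
}

#' Dual-axis run plot
#'
#' Temperature (left axis) and drive current (right axis) against time, the
#' standard way closed-loop photothermal runs are displayed.
#'
#' @param x A `thermo_run` record.
#' @param target Optional target temperature to mark, degC.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.thermo_run <- function(x, target = attr(x, "meta")$target_temp, ...) {
  old <- graphics::par(mar = c(4.5, 4.5, 2, 4.5))
  on.exit(graphics::par(old))
  graphics::plot(x$time_s, x$frame_temp_C, type = "l", col = "firebrick",
                 xlab = "time (s)", ylab = "temperature (degC)", ...)
  if (!is.null(target) && is.finite(target)) {
    graphics::abline(h = target, lty = 3, col = "grey40")
  }
  graphics::par(new = TRUE)
  graphics::plot(x$time_s, x$current_A, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", lty = 2)
  graphics::axis(4)
  graphics::mtext("current (A)", side = 4, line = 3)
  invisible(x)
}
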