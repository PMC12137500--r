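#' Controller configuration
#'
#' Parameters of the temperature-feedback laser controller. The control law is
#' a proportional formula with two threshold overrides, evaluated on a ~350 ms
#' loop against the sensor's four-center-pixel average:
#' \itemize{
#'   \item difference below `low_threshold` (default -1.0 degC, i.e. sample
#'     colder than `target - 1`): full power (100%);
#'   \item difference above `high_threshold` (default +0.6 degC): drive reduced
#'     to `floor_percent` (default 0, laser off);
#'   \item otherwise: `output = (50 + g) - diff * (50 - g)` percent, clamped to
#'     `[0, 100]`, where `diff = measured - target` and `g` is the gain
#'     coefficient selected by the sample-discrimination step.
#' }
#' Discrimination compares the temperature rise over the first
#' `discrimination_window` seconds of irradiation with `discrimination_delta`:
#' a faster rise selects `g_fast` (default 0, the strongly-absorbing-sample
#' law), otherwise `g_slow` (default 30, the weakly-absorbing-sample law).
#' At `g = 0` the formula spans the whole output range across the band; at
#' `g = 30` it is offset high with a gentler slope, compensating the weaker
#' photothermal coupling.
#'
#' @param target_temp Target temperature, degC.
#' @param low_threshold,high_threshold Signed temperature-difference
#'   thresholds, degC; ties fall into the formula branch (the overrides use
#'   strict inequalities).
#' @param discrimination_window Length of the discrimination phase, s.
#' @param discrimination_delta Temperature-rise threshold, degC (strict: the
#'   fast law requires a rise strictly greater than this).
#' @param g_fast,g_slow Gain coefficient for fast/slow-heating samples.
#' @param loop_period Control-loop refresh period, s.
#' @param max_power Laser power at 100% output, W.
#' @param floor_percent Output used above `high_threshold`, percent. The
#'   physical device only states that drive is reduced; 0 (off) is the
#'   conservative default.
#' @param threshold_current,max_current Diode calibration anchors for
#'   [power_to_current()]: drive current at zero optical power and at
#'   `max_power`, in device units (A).
#' @return An object of class `controller_config`.
#' @export
#' @examples
#' controller_config(42.5)
controller_config <- function(target_temp,
                              low_threshold = -1.0, high_threshold = 0.6,
                              discrimination_window = 5,
                              discrimination_delta = 5,
                              g_fast = 0, g_slow = 30,
                              loop_period = 0.350, max_power = 3,
                              floor_percent = 0,
                              threshold_current = 0.4, max_current = 4.0) {
  stopifnot(is.finite(target_temp))
  if (!(low_threshold < high_threshold)) {
    stop("low_threshold must be < high_threshold", call. = FALSE)
  }
  if (g_fast < 0 || g_fast > 50 || g_slow < 0 || g_slow > 50) {
    stop("gain coefficients must lie in [0, 50]", call. = FALSE)
  }
  if (loop_period <= 0) stop("loop_period must be > 0", call. = FALSE)
  if (floor_percent < 0 || floor_percent > 100) {
    stop("floor_percent must lie in [0, 100]", call. = FALSE)
  }
  stopifnot(max_power > 0, max_current > threshold_current)
  structure(
    list(target_temp = target_temp, low_threshold = low_threshold,
         high_threshold = high_threshold,
         discrimination_window = discrimination_window,
         discrimination_delta = discrimination_delta,
         g_fast = g_fast, g_slow = g_slow, loop_period = loop_period,
         max_power = max_power, floor_percent = floor_percent,
         threshold_current = threshold_current, max_current = max_current),
    class = "controller_config"
  )
}

#' @export
print.controller_config <- function(x, ...) {
  cat(sprintf(
    "<controller_config> target %.1f degC, band [%+.1f, %+.1f] degC, g %g/%g, loop %g ms, max %g W\n",
    x$target_temp, x$low_threshold, x$high_threshold, x$g_fast, x$g_slow,
    x$loop_period * 1e3, x$max_power))
  invisible(x)
}

#' Sample-type discrimination
#'
#' Selects the gain coefficient from the temperature rise over the
#' discrimination window: if `t5_temp - t0_temp` is strictly greater than
#' `discrimination_delta` (default 5 degC) the sample heats fast and the
#' fast law (`g_fast`, default 0) is kept; otherwise the slow law (`g_slow`,
#' default 30) is selected.
#'
#' @param t0_temp Measured temperature at the start of irradiation, degC.
#' @param t5_temp Measured temperature at the end of the window, degC.
#' @param config A [controller_config()].
#' @return The selected gain coefficient (dimensionless).
#' @export
#' @examples
#' cfg <- controller_config(42.5)
#' classify_sample(25, 32, cfg)  # 7 degC rise -> 0
#' classify_sample(25, 28, cfg)  # 3 degC rise -> 30
classify_sample <- function(t0_temp, t5_temp, config) {
  stopifnot(inherits(config, "controller_config"))
  if (!is.finite(t0_temp) || !is.finite(t5_temp)) {
    stop("discrimination temperatures must be finite", call. = FALSE)
  }
  if (t5_temp - t0_temp > config$discrimination_delta) config$g_fast
  else config$g_slow
}

#' Proportional control step
#'
#' Evaluates the control law for a measured temperature (vectorized). The
#' signed difference `measured - target` below `low_threshold` commands 100%,
#' above `high_threshold` commands `floor_percent`, and in between the
#' proportional formula `(50 + g) - diff * (50 - g)` applies, clamped to
#' `[0, 100]`. At the lower band edge the formula itself reaches 100 for any
#' `g`, so the full-power override is continuous with the formula.
#'
#' @param measured_temp Measured temperature(s), degC. Non-finite values
#'   return `NA` (the loop holds the previous command and flags a fault).
#' @param config A [controller_config()].
#' @param g Gain coefficient, as selected by [classify_sample()].
#' @return Commanded output, percent of `max_power`.
#' @export
#' @examples
#' cfg <- controller_config(42.5)
#' control_step(41.0, cfg, g = 0)   # below band: 100
#' control_step(42.5, cfg, g = 0)   # on target: 50
#' control_step(42.5, cfg, g = 30)  # slow law on target: 80
control_step <- function(measured_temp, config, g) {
  stopifnot(inherits(config, "controller_config"), is.finite(g))
  diff <- measured_temp - config$target_temp
  formula_val <- (50 + g) - diff * (50 - g)
  out <- pmin(100, pmax(0, formula_val))
  out[diff < config$low_threshold] <- 100
  out[diff > config$high_threshold] <- config$floor_percent
  out[!is.finite(measured_temp)] <- NA_real_
  out
}

#' Output percent / power / drive current conversions
#'
#' Power is linear in commanded percent (`100% = max_power`, the 3 W default).
#' Drive current follows the usual laser-diode shape above threshold:
#' `current = I_th + (I_max - I_th) * power / max_power`. Both maps are
#' invertible on their range.
#'
#' @param percent Commanded output, percent in `[0, 100]`.
#' @param power Optical power, W.
#' @param current Drive current, device units (A).
#' @param config A [controller_config()] (supplies `max_power`,
#'   `threshold_current`, `max_current`).
#' @return The converted quantity (vectorized).
#' @export
#' @examples
#' cfg <- controller_config(42.5)
#' percent_to_power(100, cfg)  # 3 W
percent_to_power <- function(percent, config) {
  stopifnot(inherits(config, "controller_config"))
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) {
    stop("percent must lie in [0, 100]", call. = FALSE)
  }
  config$max_power * percent / 100
}

#' @rdname percent_to_power
#' @export
power_to_percent <- function(power, config) {
  stopifnot(inherits(config, "controller_config"))
  if (any(power < 0 | power > config$max_power + 1e-12, na.rm = TRUE)) {
    stop("power must lie in [0, max_power]", call. = FALSE)
  }
  100 * power / config$max_power
}

#' @rdname percent_to_power
#' @export
power_to_current <- function(power, config) {
  stopifnot(inherits(config, "controller_config"))
  if (any(power < 0 | power > config$max_power + 1e-12, na.rm = TRUE)) {
    stop("power must lie in [0, max_power]", call. = FALSE)
  }
  config$threshold_current +
    (config$max_current - config$threshold_current) * power / config$max_power
}

#' @rdname percent_to_power
#' @export
current_to_power <- function(current, config) {
  stopifnot(inherits(config, "controller_config"))
  pw <- config$max_power * (current - config$threshold_current) /
    (config$max_current - config$threshold_current)
  if (any(pw < -1e-9 | pw > config$max_power + 1e-9, na.rm = TRUE)) {
    stop("current outside the calibrated range", call. = FALSE)
  }
  pmin(config$max_power, pmax(0, pw))
}

#' Run the control loop
#'
#' Executes the full control algorithm against abstract frame-source and
#' command-sink interfaces, so the same loop drives the thermal simulator or a
#' replayed frame log. The loop ticks every `loop_period` seconds and always
#' reads the most recent completed frame (zero-order hold; the 3 Hz sensor and
#' the 350 ms loop are asynchronous). During the discrimination window the
#' loop is active with `g = g_fast`; at the first tick at or after the end of
#' the window the gain is set once by [classify_sample()] from the first and
#' latest measurements, and never changes again.
#'
#' @param config A [controller_config()].
#' @param frame_source Function `function(t) -> sensor_frame | NULL` returning
#'   the latest frame with timestamp `<= t` (see [replay_frame_source()]).
#' @param command_sink Optional function called as
#'   `command_sink(time, power_W)` after every tick (e.g. to set the
#'   simulator's beam power).
#' @param duration Run length, s. `0` yields an empty record.
#' @return A run-record data frame (class `thermo_run`): columns `time_s`,
#'   `frame_time_s`, `frame_temp_C`, `g_coefficient`, `output_percent`,
#'   `power_W`, `current_A`, `stale` (frame reused from the previous tick) and
#'   `fault` (non-finite measurement; previous command held). Metadata is
#'   attached as the `meta` attribute.
#' @export
run_loop <- function(config, frame_source, command_sink = NULL, duration) {
  stopifnot(inherits(config, "controller_config"), is.function(frame_source),
            duration >= 0)
  ticks <- if (duration > 0) {
    seq(0, duration - 1e-9, by = config$loop_period)
  } else numeric(0)
  n <- length(ticks)
  rec <- data.frame(time_s = ticks, frame_time_s = rep(NA_real_, n),
                    frame_temp_C = rep(NA_real_, n),
                    g_coefficient = rep(NA_real_, n),
                    output_percent = rep(NA_real_, n),
                    power_W = rep(NA_real_, n),
                    current_A = rep(NA_real_, n),
                    stale = rep(FALSE, n), fault = rep(FALSE, n))
  g <- config$g_fast
  g_set <- FALSE
  t0_temp <- NA_real_
  last_out <- config$floor_percent
  last_frame_time <- -Inf
  for (i in seq_len(n)) {
    t <- ticks[i]
    frame <- frame_source(t)
    if (is.null(frame)) {
      if (i == 1L) {
        stop("no sensor frame available at loop start: timing error",
             call. = FALSE)
      }
      frame <- list(timestamp = last_frame_time, pixels = NA_real_)
      measured <- rec$frame_temp_C[i - 1L]
      rec$stale[i] <- TRUE
    } else {
      measured <- center_average(frame)
      rec$stale[i] <- frame$timestamp <= last_frame_time
      last_frame_time <- frame$timestamp
    }
    if (i == 1L) t0_temp <- measured
    if (!g_set && t >= config$discrimination_window - 1e-9) {
      g <- classify_sample(t0_temp, measured, config)
      g_set <- TRUE
    }
    if (is.finite(measured)) {
      last_out <- control_step(measured, config, g)
    } else {
      rec$fault[i] <- TRUE   # hold the previous command
    }
    pw <- percent_to_power(last_out, config)
    rec$frame_time_s[i] <- frame$timestamp
    rec$frame_temp_C[i] <- measured
    rec$g_coefficient[i] <- g
    rec$output_percent[i] <- last_out
    rec$power_W[i] <- pw
    rec$current_A[i] <- power_to_current(pw, config)
    if (!is.null(command_sink)) command_sink(t, pw)
  }
  new_run_record(rec, meta = list(mode = "closed_loop",
                                  target_temp = config$target_temp,
                                  config = unclass(config)))
}

new_run_record <- function(df, meta) {
  meta$schema_version <- 1L
  meta$config_hash <- fnv1a(paste(deparse(meta$config), collapse = ""))
  attr(df, "meta") <- meta
  class(df) <- c("thermo_run", "data.frame")
  df
}

# FNV-1a 32-bit hash over a string; fingerprints run configurations.
# Arithmetic in doubles, split into 16-bit halves to stay exact.
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @export
print.thermo_run <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<thermo_run> %s, %d ticks over %.1f s\n",
              meta$mode, nrow(x),
              if (nrow(x)) max(x$time_s) else 0))
  if (nrow(x)) {
    cat(sprintf("  temperature %.2f-%.2f degC, mean power %.2f W\n",
                min(x$frame_temp_C, na.rm = TRUE),
                max(x$frame_temp_C, na.rm = TRUE),
                mean(x$power_W, na.rm = TRUE)))
  }
  invisible(x)
}
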