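# Co-simulation plumbing: a mutable environment couples the bioheat field to
# the sensor and controller. Laser-power commands are queued with their
# timestamps and applied piecewise-exactly while the field advances, so a
# command issued between two sensor frames takes effect at its own time, not
# at the next frame boundary.
new_sim_env <- function(material, beam, field, sensor) {
  env <- new.env(parent = emptyenv())
  env$field <- field
  env$sensor <- sensor
  # source map scales linearly with power; deposit once at max power
  ref <- laser_beam(beam$max_power, spot_area = beam$spot_area,
                    profile = beam$profile, max_power = beam$max_power)
  env$q_unit <- deposit_energy(field, material, ref) / beam$max_power
  env$power <- 0
  env$pending <- list()            # queued (time, power) commands
  env$frames <- list()
  env$latest <- NULL
  env$next_frame_time <- 0
  env
}

sim_advance_to <- function(env, t_target) {
  while (length(env$pending) > 0 && env$pending[[1]]$time < t_target - 1e-12) {
    cmd <- env$pending[[1]]
    env$pending <- env$pending[-1]
    if (cmd$time > env$field$clock + 1e-12) {
      env$field <- advance_field(env$field, env$q_unit * env$power,
                                 cmd$time - env$field$clock)
    }
    env$power <- cmd$power
  }
  if (t_target > env$field$clock + 1e-12) {
    env$field <- advance_field(env$field, env$q_unit * env$power,
                               t_target - env$field$clock)
  }
  invisible(env)
}

sim_frame_source <- function(env) {
  frame_dt <- 1 / env$sensor$frame_rate
  function(t) {
    while (env$next_frame_time <= t + 1e-9) {
      sim_advance_to(env, env$next_frame_time)
      surf <- surface_temperature(env$field)
      frame <- capture_frame(surf, env$sensor,
                             timestamp = env$next_frame_time)
      env$frames[[length(env$frames) + 1L]] <- frame
      env$latest <- frame
      env$next_frame_time <- env$next_frame_time + frame_dt
    }
    env$latest
  }
}

sim_command_sink <- function(env) {
  function(t, power_w) {
    env$pending[[length(env$pending) + 1L]] <- list(time = t, power = power_w)
    invisible(NULL)
  }
}

#' Temperature-controlled irradiation run
#'
#' Full closed-loop co-simulation: the bioheat solver heats the sample under
#' the commanded laser power, the virtual infrared array images the surface at
#' its frame rate, and the controller (discrimination phase followed by the
#' proportional law) updates the power every loop period from the
#' four-center-pixel average.
#'
#' @param material A [material()] (e.g. [liver_material()]).
#' @param target Target temperature, degC.
#' @param duration Irradiation time, s.
#' @param seed Integer seed for the sensor-noise stream.
#' @param beam A [laser_beam()]; its `power` field is ignored (commanded by
#'   the controller) but spot, profile and maximum matter.
#' @param sensor A [sensor_config()].
#' @param control A [controller_config()]; defaults to the standard controller
#'   at `target`.
#' @param field A [thermal_field()]; defaults to the standard grid for
#'   `material`.
#' @param keep_frames If `TRUE`, the full frame log is attached as the
#'   `frames` attribute (for replay through [run_loop()]).
#' @return A `thermo_run` record (see [run_loop()]) with run metadata in the
#'   `meta` attribute.
#' @export
#' @examples
#' \donttest{
#' rec <- run_temperature_controlled(liver_material(), target = 42.5,
#'                                   duration = 30, seed = 1)
#' summarize_run(rec)
#' }
run_temperature_controlled <- function(material, target, duration = 300,
                                       seed = 1,
                                       beam = laser_beam(0),
                                       sensor = sensor_config(),
                                       control = controller_config(target),
                                       field = thermal_field(material),
                                       keep_frames = FALSE) {
  stopifnot(inherits(material, "material"),
            duration > control$discrimination_window)
  set.seed(seed)
  env <- new_sim_env(material, beam, field, sensor)
  rec <- run_loop(control, sim_frame_source(env), sim_command_sink(env),
                  duration)
  meta <- attr(rec, "meta")
  meta$mode <- "temperature_controlled"
  meta$material <- material$name
  meta$target_temp <- target
  meta$seed <- seed
  meta$duration <- duration
  meta$sensor <- unclass(sensor)
  meta$material_props <- unclass(material)
  attr(rec, "meta") <- meta
  if (keep_frames) attr(rec, "frames") <- env$frames
  attr(rec, "final_field") <- env$field
  rec
}

#' Fixed-power irradiation run
#'
#' Open-loop counterpart of [run_temperature_controlled()]: the laser runs at
#' a constant power for the whole duration while the sensor still images the
#' surface, and the record is logged on the same tick cadence and schema so
#' controlled and fixed-power runs are directly comparable.
#'
#' @inheritParams run_temperature_controlled
#' @param power Constant laser power, W (`0 < power <= max_power`, except that
#'   `power = 0` is allowed for baseline runs).
#' @param control A [controller_config()] used only for logging cadence and
#'   the power/current calibration.
#' @return A `thermo_run` record.
#' @export
run_fixed_power <- function(material, power, duration = 300, seed = 1,
                            beam = laser_beam(0),
                            sensor = sensor_config(),
                            control = controller_config(42.5),
                            field = thermal_field(material),
                            keep_frames = FALSE) {
  stopifnot(inherits(material, "material"), duration > 0)
  if (power < 0 || power > beam$max_power + 1e-12) {
    stop("power must lie in [0, max_power]", call. = FALSE)
  }
  set.seed(seed)
  env <- new_sim_env(material, beam, field, sensor)
  env$power <- power
  src <- sim_frame_source(env)
  ticks <- seq(0, duration - 1e-9, by = control$loop_period)
  pct <- power_to_percent(power, control)
  cur <- power_to_current(power, control)
  n <- length(ticks)
  temp <- numeric(n); ft <- numeric(n); stale <- logical(n)
  last_ft <- -Inf
  for (i in seq_len(n)) {
    frame <- src(ticks[i])
    temp[i] <- center_average(frame)
    ft[i] <- frame$timestamp
    stale[i] <- frame$timestamp <= last_ft
    last_ft <- frame$timestamp
  }
  rec <- data.frame(time_s = ticks, frame_time_s = ft, frame_temp_C = temp,
                    g_coefficient = NA_real_, output_percent = pct,
                    power_W = power, current_A = cur, stale = stale,
                    fault = FALSE)
  rec <- new_run_record(rec, meta = list(
    mode = "fixed_power", power_W = power, material = material$name,
    seed = seed, duration = duration, config = unclass(control),
    sensor = unclass(sensor), material_props = unclass(material)))
  if (keep_frames) attr(rec, "frames") <- env$frames
  attr(rec, "final_field") <- env$field
  rec
}

#' Equivalent fixed drive from a controlled run
#'
#' The constant drive that delivers the same integrated current as a
#' temperature-controlled run: the current-versus-time trace is integrated by
#' the trapezoidal rule and divided by the run duration.
#' `equivalent_fixed_power()` maps that average current back to optical power
#' through the inverse diode calibration.
#'
#' @param record A `thermo_run` record.
#' @param config A [controller_config()] for the calibration; defaults to the
#'   configuration stored in the record's metadata.
#' @return Average current (device units) or power (W).
#' @export
#' @examples
#' \donttest{
#' rec <- run_temperature_controlled(liver_material(), 42.5, duration = 30)
#' equivalent_fixed_power(rec)
#' }
equivalent_fixed_current <- function(record) {
  stopifnot(inherits(record, "data.frame"), nrow(record) > 1)
  span <- max(record$time_s) - min(record$time_s)
  if (span <= 0) stop("record spans zero duration", call. = FALSE)
  pracma::trapz(record$time_s, record$current_A) / span
}

#' @rdname equivalent_fixed_current
#' @export
equivalent_fixed_power <- function(record, config = NULL) {
  if (is.null(config)) {
    meta <- attr(record, "meta")
    stopifnot(!is.null(meta$config))
    config <- structure(meta$config, class = "controller_config")
  }
  current_to_power(equivalent_fixed_current(record), config)
}

#' Replicate runs
#'
#' Repeats a run function `n` times with distinct, reproducible seeds
#' (`seed + 0:(n-1)`), mirroring the three independent repeats of the bench
#' experiments. Identical seeds give bit-identical records.
#'
#' @param n Number of replicates (>= 1).
#' @param seed Base seed; replicate `i` uses `seed + i - 1`.
#' @param fun Run function, e.g. [run_temperature_controlled()].
#' @param ... Arguments passed to `fun` (everything except `seed`).
#' @return A list of `thermo_run` records.
#' @export
run_replicates <- function(n = 3, seed = 1, fun = run_temperature_controlled,
                           ...) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) fun(..., seed = seed + i - 1L))
}
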