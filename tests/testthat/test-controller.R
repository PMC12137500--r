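cfg <- controller_config(42.5)

test_that("controller configuration enforces its invariants", {
  expect_error(controller_config(42.5, low_threshold = 1, high_threshold = 0),
               "low_threshold")
  expect_error(controller_config(42.5, g_slow = 60), "\\[0, 50\\]")
  expect_error(controller_config(42.5, loop_period = 0), "loop_period")
  expect_equal(cfg$low_threshold, -1.0)
  expect_equal(cfg$high_threshold, 0.6)
  expect_equal(cfg$max_power, 3)
})

test_that("sample discrimination follows the strict 5-degree rule", {
  expect_equal(classify_sample(25.0, 32.0, cfg), 0)   # 7 degC rise: fast
  expect_equal(classify_sample(25.0, 28.0, cfg), 30)  # 3 degC rise: slow
  expect_equal(classify_sample(25.0, 30.0, cfg), 30)  # exactly 5 is not > 5
  expect_error(classify_sample(NA, 28, cfg), "finite")
})

test_that("the control step reproduces the worked examples", {
  for (g in c(0, 30)) {
    expect_equal(control_step(41.0, cfg, g), 100)  # below target - 1.0
  }
  expect_equal(control_step(42.5, cfg, g = 0), 50)
  expect_equal(control_step(42.5, cfg, g = 30), 80)
  expect_equal(control_step(41.5, cfg, g = 0), 100)  # formula reaches 100
  expect_equal(control_step(43.2, cfg, g = 0), 0)    # above band: floor
  cfg_floor <- controller_config(42.5, floor_percent = 10)
  expect_equal(control_step(43.2, cfg_floor, g = 0), 10)
})

test_that("the formula is continuous with the full-power override at the lower band edge", {
  for (g in c(0, 15, 30, 50)) {
    # algebraic identity: (50 + g) - low_threshold (50 - g) = 100 at -1.0
    val <- (50 + g) - cfg$low_threshold * (50 - g)
    expect_equal(val, 100)
    expect_equal(control_step(42.5 + cfg$low_threshold, cfg, g), 100)
  }
})

test_that("control output is non-increasing in temperature and bounded", {
  temps <- seq(39, 46, by = 0.05)
  for (g in c(0, 30, 50)) {
    out <- control_step(temps, cfg, g)
    expect_true(all(diff(out) <= 1e-12))
    expect_true(all(out >= cfg$floor_percent & out <= 100))
  }
})

test_that("control_step agrees with a naive reference implementation", {
  naive <- function(measured, target, g, low, high, floor) {
    d <- measured - target
    if (d < low) return(100)
    if (d > high) return(floor)
    min(100, max(0, (50 + g) - d * (50 - g)))
  }
  diffs <- seq(-2, 2, by = 0.05)
  for (g in c(0, 10, 30, 50)) {
    ref <- vapply(42.5 + diffs, naive, numeric(1), target = 42.5, g = g,
                  low = -1, high = 0.6, floor = 0)
    expect_equal(control_step(42.5 + diffs, cfg, g), ref, tolerance = 1e-12)
  }
})

test_that("percent, power and current conversions are consistent and invertible", {
  expect_equal(percent_to_power(100, cfg), 3)
  expect_equal(percent_to_power(0, cfg), 0)
  expect_equal(power_to_current(0, cfg), cfg$threshold_current)
  expect_equal(power_to_current(3, cfg), cfg$max_current)
  pw <- seq(0, 3, by = 0.25)
  expect_equal(current_to_power(power_to_current(pw, cfg), cfg), pw,
               tolerance = 1e-9)
  expect_equal(power_to_percent(percent_to_power(37.5, cfg), cfg), 37.5,
               tolerance = 1e-12)
  expect_error(percent_to_power(101, cfg), "\\[0, 100\\]")
  expect_error(percent_to_power(-1, cfg), "\\[0, 100\\]")
  expect_error(power_to_current(4, cfg), "max_power")
})

test_that("the loop settles to the in-band formula value on a constant source", {
  rec <- run_loop(cfg, const_frame_source(42.5), NULL, duration = 20)
  # zero rise in the window selects the slow law; at zero difference -> 80
  post <- rec[rec$time_s > cfg$discrimination_window, ]
  expect_true(all(post$g_coefficient == 30))
  expect_true(all(post$output_percent == 80))
  expect_true(all(post$power_W == 2.4))
  # during the window the loop runs with the fast gain
  pre <- rec[rec$time_s < cfg$discrimination_window - 0.35, ]
  expect_true(all(pre$g_coefficient == 0))
  expect_true(all(pre$output_percent == 50))
})

test_that("the gain coefficient changes exactly once, at the end of the window", {
  rec <- run_loop(cfg, const_frame_source(41.8), NULL, duration = 15)
  change_ticks <- which(diff(rec$g_coefficient) != 0)
  expect_length(change_ticks, 1)
  t_change <- rec$time_s[change_ticks + 1]
  expect_gte(t_change, cfg$discrimination_window)
  expect_lt(t_change, cfg$discrimination_window + cfg$loop_period)
})

test_that("stale frames are held (zero-order hold) and flagged", {
  frozen <- make_frame(42.0, t = 0)
  rec <- run_loop(cfg, function(t) frozen, NULL, duration = 3)
  expect_true(all(rec$stale[-1]))
  expect_false(rec$stale[1])
  expect_equal(unique(rec$output_percent), control_step(42.0, cfg, 0))
  expect_true(all(rec$frame_time_s == 0))
})

test_that("degenerate loop inputs are handled per contract", {
  expect_equal(nrow(run_loop(cfg, const_frame_source(42.5), NULL, 0)), 0)
  expect_error(run_loop(cfg, function(t) NULL, NULL, 10), "timing")
})

test_that("non-finite measurements hold the previous command and flag a fault", {
  src <- function(t) {
    if (t >= 1 & t < 2) make_frame(NaN, t) else make_frame(42.5, t)
  }
  rec <- run_loop(cfg, src, NULL, duration = 3)
  bad <- rec$time_s >= 1 & rec$time_s < 2
  expect_true(all(rec$fault[bad]))
  expect_true(all(!rec$fault[!bad]))
  held <- rec$output_percent[max(which(rec$time_s < 1))]
  expect_true(all(rec$output_percent[bad] == held))
})

test_that("commands are logged with calibrated power and current", {
  rec <- run_loop(cfg, const_frame_source(42.5), NULL, duration = 10)
  expect_equal(rec$power_W, percent_to_power(rec$output_percent, cfg))
  expect_equal(rec$current_A, power_to_current(rec$power_W, cfg))
  expect_true(all(diff(rec$time_s) > 0))
  meta <- attr(rec, "meta")
  expect_equal(meta$schema_version, 1L)
  expect_match(meta$config_hash, "^[0-9a-f]{8}$")
})
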