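test_that("material and beam constructors enforce their invariants", {
  expect_error(material("x", mu_a = -1, k = 0.5, rho = 1000, c = 4000),
               "mu_a")
  expect_error(material("x", mu_a = 0.5, k = 0, rho = 1000, c = 4000),
               "> 0")
  expect_error(laser_beam(-0.1), "power")
  expect_error(laser_beam(3.5, max_power = 3), "exceeds")
  m <- liver_material()
  expect_equal(m$mu_a_si, 90)            # 0.9/cm in SI
  expect_equal(agar_material()$mu_a, 0.15)
})

test_that("Beer-Lambert deposition integrates to the closed-form absorbed power", {
  m <- liver_material()                   # mu_a = 0.9/cm, thickness 6.5 mm
  fld <- small_field(m, nr = 48, nz = 24)
  beam <- laser_beam(3)

  # zero power gives an all-zero source map
  src0 <- deposit_energy(fld, m, laser_beam(0))
  expect_true(all(src0 == 0))
  expect_identical(attr(src0, "absorbed_power"), 0)

  src <- deposit_energy(fld, m, beam)
  total <- sum(src * matrix(fld$vol, fld$nr, fld$nz))
  # closed form P (1 - exp(-mu_a L)), cross-checked by numerical quadrature
  closed <- 3 * (1 - exp(-90 * 0.0065))
  quad <- stats::integrate(function(z) (3 / beam$spot_area_m2) * 90 *
                             exp(-90 * z), 0, 0.0065)$value * beam$spot_area_m2
  expect_equal(closed, 1.3286817, tolerance = 1e-6)
  expect_equal(quad, closed, tolerance = 1e-8)
  expect_equal(total, closed, tolerance = 1e-10)
  expect_equal(attr(src, "absorbed_power"), closed, tolerance = 1e-10)
  expect_lte(total, beam$power)

  # deposition confined to the spot radius for a flat-top beam
  r_spot <- sqrt(beam$spot_area_m2 / pi)
  outside <- fld$r - fld$dr / 2 > r_spot  # rings wholly outside
  expect_true(all(src[outside, ] == 0))
  expect_true(all(src[!outside, 1] > 0))
})

test_that("doubling mu_a increases total absorbed power but sub-doubles the surface layer", {
  fld <- small_field(liver_material())
  beam <- laser_beam(3)
  m1 <- material("a", mu_a = 0.9, k = 0.52, rho = 1060, c = 3600)
  m2 <- material("b", mu_a = 1.8, k = 0.52, rho = 1060, c = 3600)
  s1 <- deposit_energy(fld, m1, beam)
  s2 <- deposit_energy(fld, m2, beam)
  expect_gt(attr(s2, "absorbed_power"), attr(s1, "absorbed_power"))
  layer1 <- sum(s1[, 1] * fld$vol)
  layer2 <- sum(s2[, 1] * fld$vol)
  expect_gt(layer2, layer1)
  expect_lt(layer2, 2 * layer1)
})

test_that("gaussian profile conserves beam power and peaks on axis", {
  fld <- small_field(liver_material(), nr = 64)
  beam <- laser_beam(3, profile = "gaussian")
  src <- deposit_energy(fld, liver_material(), beam)
  expect_lte(attr(src, "absorbed_power"), 3)
  expect_equal(attr(src, "absorbed_power"), 3 * (1 - exp(-90 * 0.0065)),
               tolerance = 1e-3)          # spot well inside the grid
  expect_true(all(diff(src[, 1]) <= 1e-12))  # radially non-increasing
})

test_that("a uniform field with no source and insulated boundaries is an equilibrium", {
  fld <- small_field(h = 0, side_bc = "insulated", bottom_bc = "insulated")
  out <- step_field(fld, NULL, dt = fld$dt_stable * 0.5)
  expect_equal(out$temp, fld$temp, tolerance = 1e-14)
  expect_equal(out$clock, fld$dt_stable * 0.5)
})

test_that("the step conserves thermal energy with insulated boundaries", {
  fld <- small_field(h = 0, side_bc = "insulated", bottom_bc = "insulated")
  set.seed(11)
  fld$temp <- matrix(25 + 10 * runif(fld$nr * fld$nz), fld$nr, fld$nz)
  u0 <- sum(fld$heat_cap * fld$temp)
  for (i in 1:20) fld <- step_field(fld, NULL, dt = fld$dt_stable * 0.9)
  expect_equal(sum(fld$heat_cap * fld$temp) / u0, 1, tolerance = 1e-6)
})

test_that("unstable explicit time steps are rejected", {
  fld <- small_field()
  expect_error(step_field(fld, NULL, dt = fld$dt_stable * 1.5), "unstable")
})

test_that("surface temperature matches the constant-flux conduction solution", {
  # 1-D analogue: uniform flux on an insulated deep slab; the surface rise of
  # a semi-infinite body is (2q/k) sqrt(alpha t / pi). Compared at the first
  # cell-center depth to match what the node represents.
  m <- material("deep", mu_a = 0, k = 0.52, rho = 1060, c = 3600,
                thickness = 0.02)
  fld <- thermal_field(m, radius = 0.02, nr = 8, nz = 128, ambient = 25,
                       h = 0, side_bc = "insulated", bottom_bc = "insulated")
  q <- 2000
  alpha <- m$k / (m$rho * m$c)
  analytic <- function(z, t) {
    2 * q / m$k * sqrt(alpha * t / pi) * exp(-z^2 / (4 * alpha * t)) -
      q * z / m$k * pracma::erfc(z / (2 * sqrt(alpha * t)))
  }
  for (t_end in c(10, 30)) {
    f2 <- advance_field(fld, NULL, t_end, flux_top = q)
    rise <- surface_temperature(f2)$temp[1] - 25
    expect_equal(rise, analytic(f2$dz / 2, t_end), tolerance = 0.02)
  }
})

test_that("energy balance holds over a heated, convecting window", {
  m <- liver_material()
  fld <- thermal_field(m)
  src <- deposit_energy(fld, m, laser_beam(2))
  out <- advance_field(fld, src, 10)
  e <- attr(out, "energy")
  expect_equal(e$source_in - e$boundary_out, e$internal_change,
               tolerance = 0.01 * e$source_in)
})

test_that("halving the grid spacing changes the 60 s surface temperature by < 1%", {
  m <- liver_material()
  run_at <- function(nr, nz) {
    fld <- thermal_field(m, nr = nr, nz = nz)
    src <- deposit_energy(fld, m, laser_beam(2))
    surface_temperature(advance_field(fld, src, 60))$temp[1]
  }
  t_coarse <- run_at(64, 32)
  t_fine <- run_at(128, 64)
  expect_lt(abs(t_coarse - t_fine) / (t_fine - 25), 0.01)
})

test_that("with the source off the field relaxes monotonically toward ambient", {
  m <- liver_material()
  fld <- small_field(m)
  src <- deposit_energy(fld, m, laser_beam(3))
  fld <- advance_field(fld, src, 20)
  prev_max <- max(fld$temp)
  for (i in 1:10) {
    fld <- advance_field(fld, NULL, 5)
    cur_max <- max(fld$temp)
    expect_lt(cur_max, prev_max)
    expect_gte(min(fld$temp), fld$ambient - 1e-9)
    prev_max <- cur_max
  }
})

test_that("a centered flat-top beam produces an on-axis, radially non-increasing surface maximum", {
  m <- liver_material()
  fld <- small_field(m, nr = 32, nz = 16)
  src <- deposit_energy(fld, m, laser_beam(3))
  fld <- advance_field(fld, src, 15)
  surf <- surface_temperature(fld)
  expect_equal(which.max(surf$temp), 1L)
  expect_true(all(diff(surf$temp) <= 1e-12))
})

test_that("field snapshots export one row per cell", {
  fld <- small_field(nr = 4, nz = 3)
  df <- field_to_df(fld)
  expect_equal(nrow(df), 12)
  expect_named(df, c("r_m", "z_m", "temp_C"))
  expect_true(all(df$temp_C == 25))
})
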