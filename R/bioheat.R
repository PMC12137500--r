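#' Create the simulated thermal field
#'
#' Sets up an axisymmetric r-z finite-volume grid over a disc-shaped slab of
#' the given material. The heat equation solved is the ex vivo bioheat
#' equation (conduction plus a volumetric laser source; no perfusion, no
#' metabolic term):
#' \deqn{\rho c \, \partial T/\partial t = k \nabla^2 T + Q(r, z, t).}
#' The top surface exchanges heat with the surroundings through a convective
#' film coefficient `h`; the bottom and side boundaries are held at ambient
#' temperature by default (the sample sits on a large bath), but can be made
#' insulated for verification runs.
#'
#' Cells are centered at `r_i = (i - 1/2) dr`, `z_j = (j - 1/2) dz` with the
#' surface at `z = 0`. The finite-volume conductances make the scheme exactly
#' conservative: with insulated boundaries and no source, the volume integral
#' of `rho c T` is constant to machine precision.
#'
#' @param material A [material()] object; `thickness` sets the grid depth.
#' @param radius Slab radius, m.
#' @param nr,nz Number of radial and axial cells.
#' @param ambient Ambient (and boundary) temperature, degC.
#' @param initial Initial sample temperature, degC (defaults to ambient).
#' @param h Surface convection coefficient, W/(m2 K). `0` insulates the top.
#' @param side_bc,bottom_bc `"dirichlet"` (held at ambient) or `"insulated"`.
#' @return An object of class `thermal_field`.
#' @export
#' @examples
#' fld <- thermal_field(liver_material(), nr = 16, nz = 8)
#' range(fld$temp)
thermal_field <- function(material, radius = 0.02, nr = 64L, nz = 32L,
                          ambient = 25, initial = ambient, h = 10,
                          side_bc = c("dirichlet", "insulated"),
                          bottom_bc = c("dirichlet", "insulated")) {
  stopifnot(inherits(material, "material"), nr >= 2L, nz >= 2L,
            radius > 0, h >= 0, is.finite(ambient), is.finite(initial))
  side_bc <- match.arg(side_bc)
  bottom_bc <- match.arg(bottom_bc)
  L <- material$thickness
  dr <- radius / nr
  dz <- L / nz
  r <- (seq_len(nr) - 0.5) * dr
  k <- material$k
  vol <- 2 * pi * r * dr * dz               # cell volume, same every layer
  area_z <- 2 * pi * r * dr                 # horizontal face area per ring
  g_r <- k * 2 * pi * seq_len(nr - 1) * dr * dz / dr  # faces at r = i*dr
  g_z <- k * area_z / dz
  # convective film in series with conduction through the half-cell
  g_top <- if (h > 0) area_z / (1 / h + dz / (2 * k)) else rep(0, nr)
  g_bot <- if (bottom_bc == "dirichlet") k * area_z / (dz / 2) else rep(0, nr)
  g_side <- if (side_bc == "dirichlet") k * 2 * pi * radius * dz / (dr / 2) else 0

  # explicit-Euler stability bound of the finite-volume system
  g_sum <- matrix(0, nr, nz)
  g_sum[-nr, ] <- g_sum[-nr, ] + g_r
  g_sum[-1, ] <- g_sum[-1, ] + g_r
  g_sum[, -nz] <- g_sum[, -nz] + g_z
  g_sum[, -1] <- g_sum[, -1] + g_z
  g_sum[, 1] <- g_sum[, 1] + g_top
  g_sum[, nz] <- g_sum[, nz] + g_bot
  g_sum[nr, ] <- g_sum[nr, ] + g_side
  heat_cap <- material$rho * material$c * matrix(vol, nr, nz)
  dt_stable <- min(heat_cap / g_sum)

  structure(
    list(temp = matrix(initial, nr, nz),
         material = material, radius = radius, nr = nr, nz = nz,
         dr = dr, dz = dz, r = r, z = (seq_len(nz) - 0.5) * dz,
         vol = vol, heat_cap = heat_cap,
         g_r = g_r, g_z = g_z, g_top = g_top, g_bot = g_bot, g_side = g_side,
         ambient = ambient, h = h, side_bc = side_bc, bottom_bc = bottom_bc,
         dt_stable = dt_stable, clock = 0),
    class = "thermal_field"
  )
}

#' @export
print.thermal_field <- function(x, ...) {
  cat(sprintf(
    "<thermal_field> %s, %d x %d cells (r <= %.3g mm, z <= %.3g mm), t = %.2f s, T in [%.2f, %.2f] degC\n",
    x$material$name, x$nr, x$nz, x$radius * 1e3,
    x$material$thickness * 1e3, x$clock, min(x$temp), max(x$temp)))
  invisible(x)
}

#' Beer-Lambert volumetric laser deposition
#'
#' Maps the beam onto the grid as a volumetric heat source
#' `Q(r, z) = mu_a I(r) exp(-mu_a z)` (W/m3). Scattering is ignored: the
#' samples are characterized by their absorption coefficient alone. Each
#' cell receives the exact integral of the deposition over its volume, so the
#' total absorbed power equals `P (1 - exp(-mu_a L))` (for a flat-top beam
#' fully inside the grid) and never exceeds the incident power.
#'
#' @param field A [thermal_field()].
#' @param material A [material()]; supplies `mu_a` (1/cm at the interface,
#'   converted internally).
#' @param beam A [laser_beam()].
#' @return An `nr x nz` source matrix in W/m3, with attribute
#'   `absorbed_power` (W).
#' @export
#' @examples
#' fld <- thermal_field(liver_material(), nr = 16, nz = 8)
#' src <- deposit_energy(fld, liver_material(), laser_beam(3))
#' attr(src, "absorbed_power")
deposit_energy <- function(field, material, beam) {
  stopifnot(inherits(field, "thermal_field"), inherits(material, "material"),
            inherits(beam, "laser_beam"))
  if (beam$power < 0) stop("beam power must be >= 0", call. = FALSE)
  mu <- material$mu_a_si
  nr <- field$nr; nz <- field$nz
  if (beam$power == 0 || mu == 0) {
    q <- matrix(0, nr, nz)
    attr(q, "absorbed_power") <- 0
    return(q)
  }
  z_lo <- (seq_len(nz) - 1L) * field$dz
  z_hi <- z_lo + field$dz
  # absorbed power per unit surface area within each layer (per unit I0)
  layer_frac <- exp(-mu * z_lo) - exp(-mu * z_hi)
  r_in <- (seq_len(nr) - 1L) * field$dr
  r_out <- r_in + field$dr
  ring_area <- pi * (r_out^2 - r_in^2)
  a_m2 <- beam$spot_area_m2
  if (beam$profile == "flat_top") {
    r_spot <- sqrt(a_m2 / pi)
    i0 <- beam$power / a_m2
    # area of each annulus inside the spot
    ring_power <- i0 * pi * (pmin(r_out, r_spot)^2 - pmin(r_in, r_spot)^2)
  } else {
    w <- sqrt(2 * a_m2 / pi)               # 1/e^2 radius
    ring_power <- beam$power * (exp(-2 * r_in^2 / w^2) - exp(-2 * r_out^2 / w^2))
  }
  q <- outer(ring_power, layer_frac) / field$vol   # vol recycles along rows
  absorbed <- sum(ring_power) * sum(layer_frac)
  stopifnot(absorbed <= beam$power + 1e-9)
  attr(q, "absorbed_power") <- absorbed
  q
}

#' Advance the thermal field in time
#'
#' Integrates the discretized heat equation with explicit Euler sub-steps.
#' The sub-step is chosen automatically from the finite-volume stability bound
#' (with a safety factor) and the requested duration is hit exactly, so
#' sensor and controller event times never drift. Energy bookkeeping is exact
#' per step and returned for balance checks.
#'
#' @param field A [thermal_field()].
#' @param source Volumetric source matrix (W/m3) as from [deposit_energy()],
#'   or `NULL` for no heating.
#' @param duration Time to advance, s (>= 0).
#' @param flux_top Optional imposed surface heat flux (W/m2), a scalar or a
#'   length-`nr` vector; used mainly for verification against analytic
#'   conduction solutions.
#' @param safety Fraction of the stability bound used for the sub-step.
#' @return The advanced `thermal_field`, with an `energy` attribute: a list
#'   with `source_in`, `flux_in`, `boundary_out` (J, net over the call) and
#'   `internal_change` (J).
#' @export
advance_field <- function(field, source = NULL, duration, flux_top = NULL,
                          safety = 0.9) {
  stopifnot(inherits(field, "thermal_field"), duration >= 0)
  if (duration == 0) {
    attr(field, "energy") <- list(source_in = 0, flux_in = 0,
                                  boundary_out = 0, internal_change = 0)
    return(field)
  }
  n <- max(1L, ceiling(duration / (safety * field$dt_stable)))
  dt <- duration / n
  field <- step_field_n(field, source, dt, n, flux_top)
  field
}

#' Single explicit time step
#'
#' Low-level advance by one step of exactly `dt`. Rejects `dt` beyond the
#' explicit stability bound. Most callers should use [advance_field()], which
#' sub-steps automatically.
#'
#' @inheritParams advance_field
#' @param dt Time step, s; must satisfy `dt <= field$dt_stable`.
#' @return The advanced `thermal_field` (with the same `energy` attribute as
#'   [advance_field()]).
#' @export
step_field <- function(field, source = NULL, dt, flux_top = NULL) {
  stopifnot(inherits(field, "thermal_field"), dt > 0)
  if (dt > field$dt_stable * (1 + 1e-12)) {
    stop(sprintf(
      "dt = %.4g s is unstable for the explicit scheme (bound %.4g s)",
      dt, field$dt_stable), call. = FALSE)
  }
  step_field_n(field, source, dt, 1L, flux_top)
}

# n explicit sub-steps of size dt with exact energy accounting
step_field_n <- function(field, source, dt, n, flux_top) {
  nr <- field$nr; nz <- field$nz
  temp <- field$temp
  amb <- field$ambient
  heat_cap <- field$heat_cap
  q_pow <- if (is.null(source)) NULL else source * matrix(field$vol, nr, nz)
  flux_pow <- if (is.null(flux_top)) NULL else flux_top * (2 * pi * field$r * field$dr)
  e_src <- 0; e_flux <- 0; e_out <- 0
  u0 <- sum(heat_cap * temp)
  for (s in seq_len(n)) {
    pow <- matrix(0, nr, nz)
    d <- field$g_r * (temp[-1, , drop = FALSE] - temp[-nr, , drop = FALSE])
    pow[-nr, ] <- pow[-nr, ] + d
    pow[-1, ] <- pow[-1, ] - d
    d <- (temp[, -1, drop = FALSE] - temp[, -nz, drop = FALSE]) *
      matrix(field$g_z, nr, nz - 1)
    pow[, -nz] <- pow[, -nz] + d
    pow[, -1] <- pow[, -1] - d
    b_top <- field$g_top * (amb - temp[, 1])
    b_bot <- field$g_bot * (amb - temp[, nz])
    b_side <- field$g_side * (amb - temp[nr, ])
    pow[, 1] <- pow[, 1] + b_top
    pow[, nz] <- pow[, nz] + b_bot
    pow[nr, ] <- pow[nr, ] + b_side
    e_out <- e_out - (sum(b_top) + sum(b_bot) + sum(b_side)) * dt
    if (!is.null(q_pow)) {
      pow <- pow + q_pow
      e_src <- e_src + sum(q_pow) * dt
    }
    if (!is.null(flux_pow)) {
      pow[, 1] <- pow[, 1] + flux_pow
      e_flux <- e_flux + sum(flux_pow) * dt
    }
    temp <- temp + dt * pow / heat_cap
  }
  if (!all(is.finite(temp))) {
    stop("thermal field became non-finite: simulation unstable", call. = FALSE)
  }
  field$temp <- temp
  field$clock <- field$clock + dt * n
  attr(field, "energy") <- list(source_in = e_src, flux_in = e_flux,
                                boundary_out = e_out,
                                internal_change = sum(heat_cap * temp) - u0)
  field
}

#' Surface temperature map
#'
#' Projects the top cell layer (the `z = 0` face side of the grid) as the
#' radial surface-temperature profile the infrared sensor images. Because the
#' field is axisymmetric, the 2-D surface is fully described by temperature
#' versus radius; [capture_frame()] resamples it onto the sensor's square
#' pixel grid.
#'
#' @param field A [thermal_field()].
#' @return An object of class `surface_map`: list with `r` (cell-center radii,
#'   m), `temp` (degC, top-layer node temperatures), `radius` (map extent, m)
#'   and `time` (s).
#' @export
surface_temperature <- function(field) {
  stopifnot(inherits(field, "thermal_field"))
  structure(
    list(r = field$r, temp = field$temp[, 1], radius = field$radius,
         time = field$clock),
    class = "surface_map"
  )
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("<surface_map> t = %.2f s, T in [%.2f, %.2f] degC over r <= %.3g mm\n",
              x$time, min(x$temp), max(x$temp), x$radius * 1e3))
  invisible(x)
}

# linear interpolation of the radial profile at arbitrary radii; constant
# beyond the last cell center (the boundary ring is ambient-clamped anyway)
surface_at <- function(surface, radii) {
  stats::approx(surface$r, surface$temp, xout = radii, rule = 2)$y
}

#' Export a field snapshot as a data frame
#'
#' One row per cell with cell-center coordinates, suitable for
#' [utils::write.csv()].
#'
#' @param field A [thermal_field()].
#' @return A data frame with columns `r_m`, `z_m`, `temp_C`.
#' @export
field_to_df <- function(field) {
  stopifnot(inherits(field, "thermal_field"))
  data.frame(r_m = rep(field$r, times = field$nz),
             z_m = rep(field$z, each = field$nr),
             temp_C = as.vector(field$temp))
}
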