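#' Define a sample material
#'
#' Bundles the optical and thermal properties of a slab sample. The absorption
#' coefficient is given in 1/cm, the unit in which tissue optical properties
#' are usually tabulated, and converted to SI internally.
#'
#' @param name Character label used in run metadata.
#' @param mu_a Absorption coefficient at the laser wavelength, 1/cm.
#' @param k Thermal conductivity, W/(m K).
#' @param rho Density, kg/m3.
#' @param c Specific heat capacity, J/(kg K).
#' @param thickness Slab thickness, m.
#' @return An object of class `material`.
#' @seealso [agar_material()], [liver_material()]
#' @export
#' @examples
#' material("gel", mu_a = 0.15, k = 0.6, rho = 1000, c = 4186,
#'          thickness = 0.0065)
material <- function(name, mu_a, k, rho, c, thickness = 0.0065) {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(mu_a = mu_a, k = k, rho = rho, c = c, thickness = thickness)
  if (any(!is.finite(vals))) {
    stop("material properties must be finite numbers", call. = FALSE)
  }
  if (mu_a < 0) stop("mu_a must be >= 0", call. = FALSE)
  if (any(vals[c("k", "rho", "c", "thickness")] <= 0)) {
    stop("k, rho, c and thickness must be > 0", call. = FALSE)
  }
  structure(
    list(name = name,
         mu_a = mu_a,          # 1/cm, as supplied
         mu_a_si = mu_a * 100, # 1/m
         k = k, rho = rho, c = c, thickness = thickness),
    class = "material"
  )
}

#' Built-in sample materials
#'
#' Presets for the two sample types the testbed emulates: a weakly absorbing
#' agar gel (absorption coefficient below 0.2/cm at 800 nm; water-like thermal
#' constants) and ex vivo liver tissue (absorption 0.8-0.99/cm at 808 nm
#' depending on species; 0.9/cm is used as the midpoint, with
#' literature-typical thermal constants). Every property can be overridden.
#'
#' @param mu_a Absorption coefficient, 1/cm.
#' @param k,rho,c,thickness Thermal properties, see [material()].
#' @return A `material` object.
#' @export
agar_material <- function(mu_a = 0.15, k = 0.6, rho = 1000, c = 4186,
                          thickness = 0.0065) {
  material("agar", mu_a = mu_a, k = k, rho = rho, c = c, thickness = thickness)
}

#' @rdname agar_material
#' @export
liver_material <- function(mu_a = 0.9, k = 0.52, rho = 1060, c = 3600,
                           thickness = 0.0065) {
  material("liver", mu_a = mu_a, k = k, rho = rho, c = c, thickness = thickness)
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: mu_a = %.3g /cm, k = %.3g W/(m K), rho = %.4g kg/m3, c = %.4g J/(kg K), thickness = %.3g mm\n",
              x$name, x$mu_a, x$k, x$rho, x$c, x$thickness * 1e3))
  invisible(x)
}

#' Define the laser beam
#'
#' @param power Optical output power, W.
#' @param spot_area Spot area on the sample surface, cm2. The default 0.85 cm2
#'   matches the irradiation geometry the testbed emulates.
#' @param profile `"flat_top"` (uniform irradiance over the spot) or
#'   `"gaussian"` (irradiance `2P/(pi w^2) exp(-2 r^2/w^2)` with `w` chosen so
#'   that `pi w^2 / 2` equals `spot_area`, i.e. the same effective area).
#' @param max_power Hard upper limit for `power`, W.
#' @return An object of class `laser_beam`.
#' @export
#' @examples
#' laser_beam(3)
laser_beam <- function(power, spot_area = 0.85,
                       profile = c("flat_top", "gaussian"), max_power = 3) {
  profile <- match.arg(profile)
  if (!is.finite(power) || power < 0) {
    stop("beam power must be finite and >= 0", call. = FALSE)
  }
  if (power > max_power + 1e-12) {
    stop(sprintf("beam power %.3g W exceeds max_power %.3g W", power,
                 max_power), call. = FALSE)
  }
  if (!is.finite(spot_area) || spot_area <= 0) {
    stop("spot_area must be > 0", call. = FALSE)
  }
  structure(
    list(power = power, spot_area = spot_area,
         spot_area_m2 = spot_area * 1e-4, profile = profile,
         max_power = max_power),
    class = "laser_beam"
  )
}

#' @export
print.laser_beam <- function(x, ...) {
  cat(sprintf("<laser_beam> %.3g W %s over %.3g cm2 (max %.3g W)\n",
              x$power, x$profile, x$spot_area, x$max_power))
  invisible(x)
}
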