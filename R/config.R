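#' Load a simulation configuration from YAML
#'
#' Reads a YAML file with optional top-level sections `material`, `beam`,
#' `sensor`, `controller` and `simulation`, each holding keyword arguments for
#' the corresponding constructor ([material()], [laser_beam()],
#' [sensor_config()], [controller_config()]). `material` may instead be the
#' string `"agar"` or `"liver"` to use the built-in presets. Unset sections
#' fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A list with elements `material`, `beam`, `sensor`, `controller`
#'   (constructed objects) and `simulation` (a plain list of run settings such
#'   as `target`, `duration`, `seed`).
#' @export
#' @examples
#' cfg_file <- tempfile(fileext = ".yaml")
#' writeLines(c("material: liver", "controller:", "  target_temp: 50"),
#'            cfg_file)
#' cfg <- load_config(cfg_file)
#' cfg$controller$target_temp
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mat <- raw$material
  mat_obj <- if (is.null(mat)) {
    liver_material()
  } else if (is.character(mat)) {
    switch(mat,
           agar = agar_material(),
           liver = liver_material(),
           stop(sprintf("unknown material preset '%s'", mat), call. = FALSE))
  } else {
    do.call(material, mat)
  }
  beam <- if (is.null(raw$beam)) laser_beam(0) else {
    do.call(laser_beam, utils::modifyList(list(power = 0), raw$beam))
  }
  sensor <- do.call(sensor_config, as.list(raw$sensor))
  ctl_args <- as.list(raw$controller)
  if (is.null(ctl_args$target_temp)) ctl_args$target_temp <- 42.5
  controller <- do.call(controller_config, ctl_args)
  list(material = mat_obj, beam = beam, sensor = sensor,
       controller = controller, simulation = as.list(raw$simulation))
}
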