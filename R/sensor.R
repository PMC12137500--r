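#' Configure the virtual infrared array
#'
#' Models a low-resolution thermopile imaging array looking straight down at
#' the sample surface. The imaged footprint is a square of side
#' `2 * distance * tan(fov / 2)` centered on the beam axis (about 14.8 mm for
#' the default 25 mm working distance and 33 degree field of view); the
#' mounting-angle perspective distortion of the physical setup is ignored,
#' since the device is used only after manual centering on the spot. Each
#' pixel reads the area-average of the true surface temperature over its
#' footprint cell plus independent Gaussian noise.
#'
#' @param resolution Pixels per side (the emulated device is 32 x 32).
#' @param frame_rate Frames per second; the device supports 2-27 Hz and is
#'   operated at 3 Hz.
#' @param fov Full field of view, degrees.
#' @param distance Sensor-to-sample distance, m.
#' @param noise_sd Per-pixel Gaussian noise standard deviation, degC. The
#'   device datasheet does not state one; 0.1 degC is the default.
#' @param subsamples Sub-sampling points per pixel side used for the
#'   area-average (>= 1).
#' @return An object of class `sensor_config`.
#' @export
#' @examples
#' cfg <- sensor_config()
#' cfg$footprint_side * 1e3  # mm
sensor_config <- function(resolution = 32L, frame_rate = 3, fov = 33,
                          distance = 0.025, noise_sd = 0.1, subsamples = 3L) {
  stopifnot(resolution >= 2L, resolution %% 2L == 0L, subsamples >= 1L)
  if (frame_rate < 2 || frame_rate > 27) {
    stop("frame_rate must be within the device range [2, 27] Hz", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  footprint <- 2 * distance * tan(fov / 2 * pi / 180)
  structure(
    list(resolution = as.integer(resolution), frame_rate = frame_rate,
         fov = fov, distance = distance, noise_sd = noise_sd,
         footprint_side = footprint, subsamples = as.integer(subsamples)),
    class = "sensor_config"
  )
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config> %dx%d @ %g Hz, footprint %.1f mm, noise sd %g degC\n",
              x$resolution, x$resolution, x$frame_rate,
              x$footprint_side * 1e3, x$noise_sd))
  invisible(x)
}

# radii of all subsample points, one row per subsample, one column per pixel
# (pixels in column-major order of the resolution x resolution grid)
pixel_sample_radii <- function(config) {
  n <- config$resolution
  s <- config$footprint_side
  px <- s / n
  centers <- (seq_len(n) - (n + 1) / 2) * px
  m <- config$subsamples
  offs <- ((seq_len(m) - 0.5) / m - 0.5) * px
  xs <- as.vector(outer(offs, centers, "+"))   # m*n sample x-coordinates
  # all (x, y) combinations: radii for pixel (i, j) use xs block i, j
  r2x <- matrix(xs^2, nrow = m)  # m x n
  out <- matrix(0, m * m, n * n)
  for (j in seq_len(n)) {
    y2 <- r2x[, j]
    for (i in seq_len(n)) {
      out[, (j - 1L) * n + i] <- sqrt(outer(r2x[, i], y2, "+"))
    }
  }
  out
}

#' Capture one sensor frame
#'
#' Samples the surface-temperature map into a `resolution x resolution` image.
#' Each pixel is the average over `subsamples^2` points of its footprint cell,
#' with independent Gaussian noise of sd `noise_sd` added per pixel (drawn
#' from the current R random-number stream; seed the stream for
#' reproducibility). With `noise_sd = 0` the capture is deterministic and
#' monotone in the surface temperatures.
#'
#' @param surface A `surface_map` from [surface_temperature()].
#' @param config A [sensor_config()].
#' @param timestamp Frame time, s (defaults to the surface map's time).
#' @return An object of class `sensor_frame`: list with `timestamp` (s) and
#'   `pixels` (matrix, degC; rows index the first image axis).
#' @export
capture_frame <- function(surface, config, timestamp = surface$time) {
  stopifnot(inherits(surface, "surface_map"), inherits(config, "sensor_config"))
  half_diag <- config$footprint_side / sqrt(2)
  if (half_diag > surface$radius + 1e-12) {
    stop(sprintf(
      "sensor footprint (corner radius %.1f mm) exceeds the simulated surface (radius %.1f mm)",
      half_diag * 1e3, surface$radius * 1e3), call. = FALSE)
  }
  key <- paste(config$resolution, config$footprint_side, config$subsamples)
  radii <- sensor_cache_get(key, config)
  n <- config$resolution
  px <- colMeans(matrix(surface_at(surface, radii), nrow = nrow(radii)))
  pixels <- matrix(px, n, n)
  if (config$noise_sd > 0) {
    pixels <- pixels + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  }
  structure(list(timestamp = timestamp, pixels = pixels),
            class = "sensor_frame")
}

# memoize the subsample geometry; it depends only on the config
sensor_cache <- new.env(parent = emptyenv())
sensor_cache_get <- function(key, config) {
  if (is.null(sensor_cache[[key]])) {
    sensor_cache[[key]] <- pixel_sample_radii(config)
  }
  sensor_cache[[key]]
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame> t = %.2f s, %dx%d px, T in [%.2f, %.2f] degC\n",
              x$timestamp, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Average of the four central pixels
#'
#' The controller's process variable: the arithmetic mean of the 2x2 pixel
#' block at the center of the image (rows 16-17, columns 16-17 of the 32 x 32
#' frame in 1-based indexing). After the spot is centered, these pixels cover
#' the hottest region of the surface.
#'
#' @param frame A [capture_frame()] result.
#' @return The mean temperature, degC.
#' @export
#' @examples
#' f <- structure(list(timestamp = 0, pixels = matrix(40, 32, 32)),
#'                class = "sensor_frame")
#' center_average(f)
center_average <- function(frame) {
  stopifnot(inherits(frame, "sensor_frame"))
  n <- nrow(frame$pixels)
  i <- c(n %/% 2L, n %/% 2L + 1L)
  mean(frame$pixels[i, i])
}

#' Write or read a frame log
#'
#' Serializes a list of frames as CSV with one row per frame: `timestamp`
#' followed by the pixels in column-major order (`px0001` ... `px1024` for a
#' 32 x 32 frame), so logged runs can be replayed through the controller.
#'
#' @param frames A list of `sensor_frame` objects.
#' @param path CSV file path.
#' @return `write_frames()` returns `path` invisibly; `read_frames()` returns
#'   a list of `sensor_frame` objects.
#' @export
write_frames <- function(frames, path) {
  stopifnot(length(frames) > 0, all(vapply(frames, inherits, TRUE, "sensor_frame")))
  n <- length(frames[[1]]$pixels)
  mat <- t(vapply(frames, function(f) c(f$timestamp, as.vector(f$pixels)),
                  numeric(n + 1)))
  colnames(mat) <- c("timestamp", sprintf("px%04d", seq_len(n)))
  utils::write.csv(as.data.frame(mat), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  df <- utils::read.csv(path)
  if (!"timestamp" %in% names(df) || ncol(df) < 2) {
    stop("malformed frame log: need a 'timestamp' column plus pixel columns",
         call. = FALSE)
  }
  npx <- ncol(df) - 1L
  n <- sqrt(npx)
  if (n != round(n)) {
    stop(sprintf("malformed frame log: %d pixel columns is not a square image",
                 npx), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(timestamp = df$timestamp[i],
                   pixels = matrix(as.numeric(df[i, -1]), n, n)),
              class = "sensor_frame")
  })
}

#' Frame source backed by recorded frames
#'
#' Builds the `frame_source` function [run_loop()] consumes from a list of
#' frames (e.g. read back with [read_frames()]): called with a time `t`, it
#' returns the most recent frame with `timestamp <= t`, or `NULL` if none.
#'
#' @param frames A list of `sensor_frame` objects, in time order.
#' @return A function `function(t) -> sensor_frame | NULL`.
#' @export
replay_frame_source <- function(frames) {
  stopifnot(length(frames) > 0)
  times <- vapply(frames, `[[`, numeric(1), "timestamp")
  stopifnot(!is.unsorted(times))
  function(t) {
    i <- findInterval(t + 1e-9, times)
    if (i < 1L) NULL else frames[[i]]
  }
}
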