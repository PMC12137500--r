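# Shared fixtures: coarse grids and hand-built frames keep unit tests fast;
# the full-size study conditions are exercised in test-acceptance.R.

small_field <- function(material = liver_material(), nr = 16, nz = 8, ...) {
  thermal_field(material, nr = nr, nz = nz, ...)
}

make_frame <- function(pixels, t = 0) {
  if (length(pixels) == 1) pixels <- matrix(pixels, 32, 32)
  structure(list(timestamp = t, pixels = pixels), class = "sensor_frame")
}

# frame source delivering a constant uniform temperature at the sensor cadence
const_frame_source <- function(temp, frame_rate = 3) {
  function(t) {
    ts <- floor(t * frame_rate + 1e-9) / frame_rate
    if (t < 0) return(NULL)
    make_frame(temp, ts)
  }
}

# memoized heavy runs shared by the acceptance-level tests
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}
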