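#' Define a micropillar array specification
#'
#' Describes one micropillar array as designed on the mold plus the hydrogel
#' swelling expected on immersion. Polyacrylamide features swell in aqueous
#' buffer, so the realized pillar diameter is `mold_diameter_um * (1 +
#' swelling_fraction)` and the center-to-center grid pitch is the realized
#' diameter plus the edge-to-edge interpillar distance.
#'
#' @param mold_diameter_um Circle diameter on the mold (D), in micrometers.
#' @param interpillar_um Edge-to-edge spacing between pillars (d), in
#'   micrometers.
#' @param height_um Pillar height (h), in micrometers.
#' @param swelling_fraction Fractional diameter increase on immersion (s),
#'   in `[0, 1)`. Defaults to 0.26, the typical swelling of polyacrylamide
#'   pillars in PBS relative to mold dimensions.
#' @param rows,cols Number of pillar rows and columns in the field.
#' @param pixel_size_um Lateral pixel size of rendered/acquired images.
#' @param z_step_um Axial step between z-slices.
#'
#' @return An object of class `array_spec`: a list with the supplied fields
#'   plus `realized_diameter_um` and `pitch_um`.
#' @examples
#' spec <- array_spec(5, 10, 22)
#' spec$realized_diameter_um # 6.3
#' spec$pitch_um # 16.3
#' @export
array_spec <- function(mold_diameter_um, interpillar_um, height_um,
                       swelling_fraction = 0.26, rows = 15L, cols = 15L,
                       pixel_size_um = 0.25, z_step_um = 2) {
  check_positive(mold_diameter_um, "mold_diameter_um")
  check_positive(interpillar_um, "interpillar_um")
  check_positive(height_um, "height_um")
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(z_step_um, "z_step_um")
  if (!is.numeric(swelling_fraction) || swelling_fraction < 0 ||
    swelling_fraction >= 1) {
    abort_validation("`swelling_fraction` must lie in [0, 1).")
  }
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) {
    abort_validation("`rows` and `cols` must be >= 1.")
  }
  realized <- mold_diameter_um * (1 + swelling_fraction)
  structure(
    list(
      mold_diameter_um = mold_diameter_um,
      interpillar_um = interpillar_um,
      height_um = height_um,
      swelling_fraction = swelling_fraction,
      rows = rows,
      cols = cols,
      pixel_size_um = pixel_size_um,
      z_step_um = z_step_um,
      realized_diameter_um = realized,
      pitch_um = realized + interpillar_um
    ),
    class = "array_spec"
  )
}

#' @export
print.array_spec <- function(x, ...) {
  cat(
    sprintf(
      paste0(
        "<array_spec> %d x %d pillars\n",
        "  mold D = %.2f um, interpillar d = %.2f um, height = %.1f um\n",
        "  swelling = %.0f%% -> realized D = %.2f um, pitch = %.2f um\n",
        "  raster: %.3f um/px, z-step %.2f um\n"
      ),
      x$rows, x$cols, x$mold_diameter_um, x$interpillar_um, x$height_um,
      100 * x$swelling_fraction, x$realized_diameter_um, x$pitch_um,
      x$pixel_size_um, x$z_step_um
    )
  )
  invisible(x)
}
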