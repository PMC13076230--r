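#' Construct a calibrated multi-channel image stack
#'
#' A thin container for a 4-D intensity array in `(y, x, z, channel)` order
#' with physical calibration. Pixel centers sit at `(index - 1) *
#' pixel_size_um` laterally and `(slice - 1) * z_step_um` axially; z index 1
#' is the gel base.
#'
#' @param data Numeric 4-D array `(y, x, z, channel)`, intensities >= 0.
#' @param channels Character vector of channel roles, one per channel plane
#'   (e.g. `c("PILLAR", "MBP", "NUCLEI")`). Roles must be unique.
#' @param pixel_size_um Lateral pixel size in micrometers.
#' @param z_step_um Axial slice spacing in micrometers.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, channels, pixel_size_um, z_step_um) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort_validation("`data` must be a 4-D array (y, x, z, channel).")
  }
  if (any(data < 0)) {
    abort_validation("Stack intensities must be non-negative.")
  }
  if (dim(data)[3] < 1L) {
    abort_validation("Stack must contain at least one z-slice.")
  }
  channels <- as.character(channels)
  if (length(channels) != dim(data)[4] || anyDuplicated(channels)) {
    abort_validation(
      "`channels` must name each channel plane exactly once."
    )
  }
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(z_step_um, "z_step_um")
  dimnames(data) <- list(NULL, NULL, NULL, channels)
  structure(
    list(
      data = data,
      channels = channels,
      pixel_size_um = pixel_size_um,
      z_step_um = z_step_um
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d px, %d z-slices, channels: %s\n  %.3f um/px, z-step %.2f um\n",
    d[2], d[1], d[3], paste(x$channels, collapse = "/"),
    x$pixel_size_um, x$z_step_um
  ))
  invisible(x)
}

stack_channel <- function(stack, channel_role) {
  if (!channel_role %in% stack$channels) {
    abort_validation(sprintf(
      "Channel role '%s' not present (have: %s).",
      channel_role, paste(stack$channels, collapse = ", ")
    ))
  }
  stack$data[, , , channel_role, drop = FALSE][, , , 1, drop = TRUE]
}

slice_centers_um <- function(stack) {
  (seq_len(dim(stack$data)[3]) - 1) * stack$z_step_um
}

#' Maximum-intensity projection over a z-range
#'
#' Projects one channel of a stack over the half-open axial interval
#' `[z_lo, z_hi)`. A slice is included when its center position falls in the
#' interval. The full-height projection (`z_lo = 0`, `z_hi = Inf`) is used
#' for counting cell bodies; a base-excluded projection (`z_lo` above the
#' gel base, default 4 um in the downstream drivers) isolates myelin wrapped
#' around the pillar shafts from signal at the gel surface.
#'
#' @param stack An [image_stack()].
#' @param channel_role Channel to project (e.g. `"MBP"`).
#' @param z_lo,z_hi Axial range in micrometers, half-open `[z_lo, z_hi)`.
#'   `z_hi = Inf` means "to the top of the stack".
#'
#' @return An object of class `projection2d`: the 2-D intensity matrix plus
#'   the source channel, the z-range used and the pixel size.
#' @export
max_project <- function(stack, channel_role, z_lo = 0, z_hi = Inf) {
  if (!inherits(stack, "image_stack")) {
    abort_validation("`stack` must be an image_stack.")
  }
  if (!is.numeric(z_lo) || !is.numeric(z_hi) || z_lo >= z_hi) {
    abort_validation("`z_lo` must be strictly less than `z_hi`.")
  }
  ch <- stack_channel(stack, channel_role)
  if (length(dim(ch)) == 2L) {
    ch <- array(ch, dim = c(dim(ch), 1L))
  }
  zc <- slice_centers_um(stack)
  sel <- which(zc >= z_lo & zc < z_hi)
  if (length(sel) == 0L) {
    abort_validation("No z-slices fall in [z_lo, z_hi).")
  }
  planes <- lapply(sel, function(k) ch[, , k])
  intensity <- Reduce(pmax, planes)
  new_projection2d(
    intensity,
    channel_role = channel_role,
    z_range_um = c(z_lo, min(z_hi, max(zc) + stack$z_step_um)),
    pixel_size_um = stack$pixel_size_um
  )
}

new_projection2d <- function(intensity, channel_role, z_range_um,
                             pixel_size_um) {
  structure(
    list(
      intensity = intensity,
      channel_role = channel_role,
      z_range_um = z_range_um,
      pixel_size_um = pixel_size_um
    ),
    class = "projection2d"
  )
}

#' @export
print.projection2d <- function(x, ...) {
  cat(sprintf(
    "<projection2d> %s channel, %d x %d px, z in [%.1f, %.1f) um, %.3f um/px\n",
    x$channel_role, ncol(x$intensity), nrow(x$intensity),
    x$z_range_um[1], x$z_range_um[2], x$pixel_size_um
  ))
  invisible(x)
}

#' Reinterpret a 2-D projection as a single-slice stack
#'
#' Useful for idempotence checks and for feeding a projection back through
#' stack-level operations.
#'
#' @param projection A `projection2d`.
#' @param z_step_um Axial step to attach to the single slice.
#' @return An [image_stack()] with one slice and one channel.
#' @export
as_image_stack <- function(projection, z_step_um = 1) {
  m <- projection$intensity
  image_stack(
    array(m, dim = c(nrow(m), ncol(m), 1L, 1L)),
    channels = projection$channel_role,
    pixel_size_um = projection$pixel_size_um,
    z_step_um = z_step_um
  )
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Planes are written z-major (all channels of slice 1, then slice 2, ...)
#' as 32-bit float, scaled into `[0, 1]` by the stack-wide maximum. The
#' sidecar `<path>.json` records the channel roles, calibration and the
#' intensity scale so [read_stack()] restores the original values.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) {
    abort_validation("`stack` must be an image_stack.")
  }
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  planes <- vector("list", d[3] * d[4])
  idx <- 1L
  for (z in seq_len(d[3])) {
    for (ch in seq_len(d[4])) {
      planes[[idx]] <- stack$data[, , z, ch] / scale
      idx <- idx + 1L
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "deflate")
  meta <- list(
    channels = stack$channels,
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um,
    n_z = d[3],
    intensity_scale = scale,
    plane_order = "z-major, channel-minor"
  )
  jsonlite::write_json(meta, sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.tiff?$", "", path), ".json")
}

#' Read a calibrated image stack
#'
#' Reads a multi-page TIFF written by [write_stack()] (or any z-major,
#' channel-minor plane sequence) together with its JSON sidecar. When the
#' sidecar is absent, calibration and channel roles must be supplied as
#' overrides; reading fails if the pixel size cannot be resolved.
#'
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um Calibration overrides (micrometers).
#' @param channels Channel-role override, one name per channel plane.
#' @param n_z Number of z-slices override (required without a sidecar when
#'   the file holds more than one channel).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL,
                       channels = NULL, n_z = NULL) {
  if (!file.exists(path)) {
    abort_validation(sprintf("File not found: %s", path))
  }
  meta <- NULL
  scp <- sidecar_path(path)
  if (file.exists(scp)) {
    meta <- jsonlite::read_json(scp, simplifyVector = TRUE)
  }
  pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  z_step_um <- z_step_um %||% meta$z_step_um %||% 1
  channels <- channels %||% meta$channels
  n_z <- n_z %||% meta$n_z
  scale <- meta$intensity_scale %||% 1
  if (is.null(pixel_size_um)) {
    abort_validation(
      "No pixel-size metadata found and no `pixel_size_um` override given."
    )
  }
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  n_planes <- length(planes)
  if (is.null(channels)) {
    channels <- "CH1"
  }
  n_ch <- length(channels)
  if (is.null(n_z)) n_z <- n_planes / n_ch
  if (n_ch * n_z != n_planes) {
    abort_validation(sprintf(
      "%d planes cannot be split into %d channels x %s slices.",
      n_planes, n_ch, format(n_z)
    ))
  }
  ny <- nrow(planes[[1]])
  nx <- ncol(planes[[1]])
  data <- array(0, dim = c(ny, nx, n_z, n_ch))
  idx <- 1L
  for (z in seq_len(n_z)) {
    for (ch in seq_len(n_ch)) {
      data[, , z, ch] <- planes[[idx]] * scale
      idx <- idx + 1L
    }
  }
  image_stack(data, channels, pixel_size_um, z_step_um)
}

#' Write a projection as a single-plane TIFF
#'
#' @param projection A `projection2d`.
#' @param path Output TIFF path; a JSON sidecar records the channel role,
#'   z-range, pixel size and intensity scale.
#' @return `path`, invisibly.
#' @export
write_projection <- function(projection, path) {
  stopifnot(inherits(projection, "projection2d"))
  scale <- max(projection$intensity, 1e-12)
  tiff::writeTIFF(projection$intensity / scale, path,
    bits.per.sample = 32L, compression = "deflate"
  )
  jsonlite::write_json(
    list(
      channel_role = projection$channel_role,
      z_range_um = projection$z_range_um,
      pixel_size_um = projection$pixel_size_um,
      intensity_scale = scale
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
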