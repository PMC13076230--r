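#' Noise model for synthetic field rendering
#'
#' Defaults emulate a plausible confocal acquisition: Gaussian optical blur
#' of 0.4 um, a flat background at 5% of the signal peak and Gaussian read
#' noise at 2% of the peak. Photon (Poisson) noise is off by default;
#' setting `poisson_scale` to the expected peak photon count enables it.
#'
#' @param background Flat background level, as a fraction of the signal peak.
#' @param gaussian_sd Read-noise standard deviation, fraction of the peak.
#' @param poisson_scale Photon count corresponding to peak intensity; 0
#'   disables shot noise.
#' @param blur_sd_um Gaussian blur standard deviation in micrometers.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background = 0.05, gaussian_sd = 0.02,
                        poisson_scale = 0, blur_sd_um = 0.4) {
  check_non_negative(background, "background")
  check_non_negative(gaussian_sd, "gaussian_sd")
  check_non_negative(poisson_scale, "poisson_scale")
  check_non_negative(blur_sd_um, "blur_sd_um")
  structure(
    list(
      background = background, gaussian_sd = gaussian_sd,
      poisson_scale = poisson_scale, blur_sd_um = blur_sd_um
    ),
    class = "noise_model"
  )
}

#' Zero-noise model (no blur, no background, no read noise)
#' @return A `noise_model` with every component at zero.
#' @export
noise_model_none <- function() {
  noise_model(background = 0, gaussian_sd = 0, poisson_scale = 0, blur_sd_um = 0)
}

#' Draw a ground-truth description of one pillar field
#'
#' Places pillars on the regular lattice defined by `spec` and draws, per
#' pillar, a myelin coverage fraction, a ring thickness and a random arc
#' start angle; nuclei centers are scattered uniformly over the field with a
#' minimum separation. The returned truth drives [render_field()] and is
#' the reference that recovery tests compare against.
#'
#' @param spec An [array_spec()].
#' @param coverage Per-pillar coverage fractions in `[0, 1]`. Either a
#'   single value, a vector of length `rows * cols`, or a vector to sample
#'   from (with replacement) when `sample_coverage = TRUE`.
#' @param thickness_um Myelin ring thickness per pillar (recycled).
#' @param n_nuclei Number of nuclei to place.
#' @param absent_sites Integer pillar indices (row-major) left unrendered.
#' @param split_arc Logical; when `TRUE` the covered fraction is split into
#'   two opposite arcs instead of one contiguous arc.
#' @param sample_coverage When `TRUE`, `coverage` is a pool sampled per
#'   pillar.
#' @param margin_um Blank border around the pillar lattice.
#' @param myelin_z_lo_um Height above the gel base below which no myelin is
#'   placed (the base-exclusion height the projection relies on).
#' @param seed Integer seed; fixes all random choices.
#'
#' @return An object of class `field_truth`: list with tibbles `pillars`
#'   (pillar_id, row, col, x_um, y_um, coverage, thickness_um,
#'   arc_start_deg, split_arc, present) and `nuclei` (x_um, y_um, z_um),
#'   plus the field extent and generation parameters.
#' @export
simulate_field_truth <- function(spec, coverage = 0.5, thickness_um = 0.66,
                                 n_nuclei = 10, absent_sites = integer(0),
                                 split_arc = FALSE, sample_coverage = FALSE,
                                 margin_um = NULL, myelin_z_lo_um = 4,
                                 seed = 1L) {
  stopifnot(inherits(spec, "array_spec"))
  if (any(coverage < 0 | coverage > 1)) {
    abort_validation("`coverage` values must lie in [0, 1].")
  }
  check_non_negative(thickness_um, "thickness_um")
  if (n_nuclei < 0) abort_validation("`n_nuclei` must be >= 0.")
  margin_um <- margin_um %||% (spec$pitch_um / 2 + spec$realized_diameter_um)
  n_sites <- spec$rows * spec$cols
  r <- spec$realized_diameter_um / 2

  with_seed_(seed, {
    grid <- expand.grid(col = seq_len(spec$cols), row = seq_len(spec$rows))
    grid <- grid[order(grid$row, grid$col), ]
    x <- margin_um + r + (grid$col - 1) * spec$pitch_um
    y <- margin_um + r + (grid$row - 1) * spec$pitch_um
    cov <- if (sample_coverage) {
      sample(coverage, n_sites, replace = TRUE)
    } else {
      rep_len(coverage, n_sites)
    }
    pillars <- tibble::tibble(
      pillar_id = seq_len(n_sites),
      row = grid$row,
      col = grid$col,
      x_um = x,
      y_um = y,
      coverage = cov,
      thickness_um = rep_len(thickness_um, n_sites),
      arc_start_deg = stats::runif(n_sites, 0, 360),
      split_arc = rep_len(split_arc, n_sites),
      present = !(seq_len(n_sites) %in% absent_sites)
    )
    extent_um <- c(
      x = 2 * margin_um + (spec$cols - 1) * spec$pitch_um + 2 * r,
      y = 2 * margin_um + (spec$rows - 1) * spec$pitch_um + 2 * r
    )
    nuclei <- place_nuclei(n_nuclei, extent_um, min_sep_um = 9)
    structure(
      list(
        pillars = pillars,
        nuclei = nuclei,
        extent_um = extent_um,
        margin_um = margin_um,
        myelin_z_lo_um = myelin_z_lo_um,
        seed = as.integer(seed)
      ),
      class = "field_truth"
    )
  })
}

# Poisson-disc-like dart throwing: uniform proposals, rejected when closer
# than min_sep_um to an accepted nucleus; gives well-separated somata.
place_nuclei <- function(n, extent_um, min_sep_um, max_tries = 4000L) {
  xs <- numeric(0)
  ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1L
    px <- stats::runif(1, min_sep_um / 2, extent_um[["x"]] - min_sep_um / 2)
    py <- stats::runif(1, min_sep_um / 2, extent_um[["y"]] - min_sep_um / 2)
    if (length(xs) == 0 || min((xs - px)^2 + (ys - py)^2) >= min_sep_um^2) {
      xs <- c(xs, px)
      ys <- c(ys, py)
    }
  }
  tibble::tibble(
    x_um = xs, y_um = ys,
    z_um = stats::runif(length(xs), 1, 3)
  )
}

#' Render a synthetic three-channel pillar-field stack
#'
#' Produces a calibrated `(y, x, z, channel)` stack with channels
#' `PILLAR` (FITC-labeled hydrogel cylinders spanning the full height),
#' `MBP` (myelin: annular arcs of the configured coverage and thickness at
#' the pillar surface, present only above the base-exclusion height) and
#' `NUCLEI` (Hoechst: ellipsoidal blobs near the gel base), then applies
#' Gaussian blur, background, shot noise and read noise per the
#' [noise_model()]. Identical `(spec, truth, noise, seed)` give bit-identical
#' output.
#'
#' @param spec An [array_spec()].
#' @param truth A [simulate_field_truth()] result.
#' @param noise A [noise_model()].
#' @param seed Integer seed for the noise draws.
#' @return A list with elements `stack` ([image_stack()]) and `truth`.
#' @export
render_field <- function(spec, truth, noise = noise_model(), seed = 1L) {
  stopifnot(inherits(spec, "array_spec"), inherits(truth, "field_truth"))
  px <- spec$pixel_size_um
  nx <- as.integer(ceiling(truth$extent_um[["x"]] / px)) + 1L
  ny <- as.integer(ceiling(truth$extent_um[["y"]] / px)) + 1L
  nz <- as.integer(floor(spec$height_um / spec$z_step_um)) + 1L
  r_um <- spec$realized_diameter_um / 2
  pil <- truth$pillars[truth$pillars$present, , drop = FALSE]
  if (nrow(pil) > 0 &&
    (max(pil$x_um) + r_um > (nx - 1) * px ||
      max(pil$y_um) + r_um > (ny - 1) * px)) {
    abort_computation("Field extent is smaller than the pillar-grid footprint.")
  }

  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px

  pillar2d <- matrix(0, ny, nx)
  myelin2d <- matrix(0, ny, nx)
  for (i in seq_len(nrow(pil))) {
    p <- pil[i, ]
    box <- pixel_box(p$x_um, p$y_um, r_um + p$thickness_um + 2, xs, ys)
    dx <- outer(rep(1, length(box$iy)), xs[box$ix] - p$x_um)
    dy <- outer(ys[box$iy] - p$y_um, rep(1, length(box$ix)))
    rr <- sqrt(dx^2 + dy^2)
    pillar2d[box$iy, box$ix] <- pmax(pillar2d[box$iy, box$ix], (rr <= r_um) * 1)
    if (p$coverage > 0 && p$thickness_um > 0) {
      th <- (atan2(dy, dx) * 180 / pi) %% 360
      ring <- rr >= r_um & rr <= r_um + p$thickness_um
      in_arc <- arc_mask(th, p$arc_start_deg, p$coverage, p$split_arc)
      myelin2d[box$iy, box$ix] <- pmax(
        myelin2d[box$iy, box$ix], (ring & in_arc) * 1
      )
    }
  }

  zc <- (seq_len(nz) - 1) * spec$z_step_um
  data <- array(0, dim = c(ny, nx, nz, 3))
  for (k in seq_len(nz)) {
    if (zc[k] <= spec$height_um) {
      data[, , k, 1] <- pillar2d
      if (zc[k] >= truth$myelin_z_lo_um) {
        data[, , k, 2] <- myelin2d
      }
    }
    data[, , k, 3] <- nuclei_slice(truth$nuclei, zc[k], xs, ys)
  }

  data <- apply_noise(data, noise, px, seed)
  list(
    stack = image_stack(data, c("PILLAR", "MBP", "NUCLEI"), px, spec$z_step_um),
    truth = truth
  )
}

pixel_box <- function(cx, cy, radius, xs, ys) {
  list(
    ix = which(xs >= cx - radius & xs <= cx + radius),
    iy = which(ys >= cy - radius & ys <= cy + radius)
  )
}

# TRUE where angle `th` (degrees) lies inside the covered arc(s).
arc_mask <- function(th, start_deg, coverage, split) {
  if (coverage >= 1) {
    return(th >= 0)
  }
  rel <- (th - start_deg) %% 360
  if (!split) {
    rel < coverage * 360
  } else {
    half <- coverage * 180
    (rel < half) | (rel >= 180 & rel < 180 + half)
  }
}

nuclei_slice <- function(nuclei, z_um, xs, ys, ax_um = 3.5, az_um = 2.5) {
  m <- matrix(0, length(ys), length(xs))
  if (nrow(nuclei) == 0) {
    return(m)
  }
  for (i in seq_len(nrow(nuclei))) {
    nzr <- (z_um - nuclei$z_um[i]) / az_um
    if (abs(nzr) >= 1) next
    # lateral radius of the ellipsoid at this slice
    rl <- ax_um * sqrt(1 - nzr^2)
    box <- pixel_box(nuclei$x_um[i], nuclei$y_um[i], rl, xs, ys)
    if (length(box$ix) == 0 || length(box$iy) == 0) next
    dx <- outer(rep(1, length(box$iy)), xs[box$ix] - nuclei$x_um[i])
    dy <- outer(ys[box$iy] - nuclei$y_um[i], rep(1, length(box$ix)))
    m[box$iy, box$ix] <- pmax(
      m[box$iy, box$ix], (dx^2 + dy^2 <= rl^2) * 1
    )
  }
  m
}

apply_noise <- function(data, noise, pixel_size_um, seed) {
  with_seed_(seed, {
    d <- dim(data)
    if (noise$blur_sd_um > 0) {
      sigma_px <- noise$blur_sd_um / pixel_size_um
      for (ch in seq_len(d[4])) {
        for (k in seq_len(d[3])) {
          if (any(data[, , k, ch] > 0)) {
            data[, , k, ch] <- EBImage::gblur(data[, , k, ch], sigma = sigma_px)
          }
        }
      }
    }
    if (noise$background > 0) data <- data + noise$background
    if (noise$poisson_scale > 0) {
      data <- array(
        stats::rpois(length(data), data * noise$poisson_scale) /
          noise$poisson_scale,
        dim = d
      )
    }
    if (noise$gaussian_sd > 0) {
      data <- data + array(
        stats::rnorm(length(data), 0, noise$gaussian_sd),
        dim = d
      )
    }
    pmax(data, 0)
  })
}
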