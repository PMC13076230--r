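#' Detect the pillar grid on a pillar-channel projection
#'
#' Segments the FITC pillar channel by global threshold (Otsu by default),
#' labels connected components, takes intensity-weighted-free centroids and
#' equivalent-disc diameters, then fits an axis-aligned rectangular lattice
#' to the centroids by least squares. Lattice sites inside the fitted grid
#' with no detected disc are reported as absent. Components touching the
#' image border are flagged (`border = TRUE`) and excluded from swelling
#' statistics downstream.
#'
#' @param projection A `projection2d` of the PILLAR channel.
#' @param expected_pitch_um Approximate center-to-center pitch (within a
#'   factor of about 2 of the truth).
#' @param expected_diameter_um Approximate realized pillar diameter; used
#'   only to reject sub-pillar specks.
#' @param threshold `"otsu"` (default) or a fixed numeric intensity.
#'
#' @return A tibble of class `pillar_grid` with columns `pillar_id`, `row`,
#'   `col`, `x_um`, `y_um`, `diameter_um`, `present`, `border`; attributes
#'   `pitch_um` (fitted `c(x, y)` pitch) and `threshold`.
#' @export
detect_pillars <- function(projection, expected_pitch_um,
                           expected_diameter_um, threshold = "otsu") {
  stopifnot(inherits(projection, "projection2d"))
  check_positive(expected_pitch_um, "expected_pitch_um")
  check_positive(expected_diameter_um, "expected_diameter_um")
  px <- projection$pixel_size_um
  img <- projection$intensity
  th <- resolve_threshold(threshold, img)
  comps <- label_components(img > th, px)
  comps <- comps[comps$diameter_um >= 0.4 * expected_diameter_um, ,
    drop = FALSE
  ]
  if (nrow(comps) < 4L) {
    abort_computation(
      "Fewer than 4 pillar candidates found: no grid detected."
    )
  }

  fit_x <- fit_lattice_axis(comps$x_um, expected_pitch_um)
  fit_y <- fit_lattice_axis(comps$y_um, expected_pitch_um)
  cols <- fit_x$index - min(fit_x$index) + 1L
  rows <- fit_y$index - min(fit_y$index) + 1L
  key <- paste(rows, cols)
  if (anyDuplicated(key)) {
    abort_computation("Lattice fit assigned two pillars to one site.")
  }

  full <- expand.grid(col = seq_len(max(cols)), row = seq_len(max(rows)))
  full <- full[order(full$row, full$col), ]
  fkey <- paste(full$row, full$col)
  m <- match(fkey, key)
  out <- tibble::tibble(
    pillar_id = seq_len(nrow(full)),
    row = full$row,
    col = full$col,
    x_um = ifelse(is.na(m),
      fit_x$origin + (full$col - 1) * fit_x$pitch, comps$x_um[m]
    ),
    y_um = ifelse(is.na(m),
      fit_y$origin + (full$row - 1) * fit_y$pitch, comps$y_um[m]
    ),
    diameter_um = ifelse(is.na(m), NA_real_, comps$diameter_um[m]),
    present = !is.na(m),
    border = ifelse(is.na(m), FALSE, comps$border[m])
  )
  structure(
    out,
    class = c("pillar_grid", class(out)),
    pitch_um = c(x = fit_x$pitch, y = fit_y$pitch),
    threshold = th
  )
}

# Connected components of a binary mask with centroid (um), equivalent-disc
# diameter (um) and border contact.
label_components <- function(mask, pixel_size_um) {
  lab <- EBImage::bwlabel(mask * 1)
  n <- max(lab)
  if (n == 0) {
    return(tibble::tibble(
      x_um = numeric(0), y_um = numeric(0),
      diameter_um = numeric(0), border = logical(0)
    ))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- factor(lab[lab > 0], levels = seq_len(n))
  area <- tabulate(labv, n)
  sx <- tapply(idx[, 2], labv, sum)
  sy <- tapply(idx[, 1], labv, sum)
  on_border <- idx[, 1] == 1 | idx[, 1] == nrow(mask) |
    idx[, 2] == 1 | idx[, 2] == ncol(mask)
  border <- tapply(on_border, labv, any)
  tibble::tibble(
    x_um = (as.numeric(sx) / area - 1) * pixel_size_um,
    y_um = (as.numeric(sy) / area - 1) * pixel_size_um,
    diameter_um = sqrt(4 * area / pi) * pixel_size_um,
    border = as.logical(border)
  )
}

# One-axis lattice fit: assign integer indices with the expected pitch,
# then refine origin and pitch by least squares and re-assign once.
fit_lattice_axis <- function(pos, expected_pitch) {
  index <- round((pos - min(pos)) / expected_pitch)
  for (rep in 1:2) {
    if (length(unique(index)) > 1) {
      fit <- stats::lm.fit(cbind(1, index), pos)
      origin <- fit$coefficients[1]
      pitch <- fit$coefficients[2]
    } else {
      origin <- mean(pos)
      pitch <- expected_pitch
    }
    index <- round((pos - origin) / pitch)
  }
  list(index = as.integer(index), origin = unname(origin), pitch = unname(pitch))
}

#' Measure the equivalent-disc diameter at a position
#'
#' Thresholds the projection, takes the connected component containing (or
#' nearest within one expected radius of) the given center, and returns its
#' equivalent-disc diameter `sqrt(4 * area / pi)`. Components touching the
#' image border are flagged; flagged measurements are excluded from swelling
#' statistics.
#'
#' @param projection A `projection2d` of the PILLAR channel.
#' @param center_x_um,center_y_um Pillar center, micrometers.
#' @param threshold `"otsu"` or fixed numeric.
#' @return A one-row tibble: `diameter_um`, `border`.
#' @export
measure_diameter <- function(projection, center_x_um, center_y_um,
                             threshold = "otsu") {
  stopifnot(inherits(projection, "projection2d"))
  px <- projection$pixel_size_um
  img <- projection$intensity
  if (center_x_um < 0 || center_y_um < 0 ||
    center_x_um > (ncol(img) - 1) * px || center_y_um > (nrow(img) - 1) * px) {
    abort_validation("Center lies outside the image.")
  }
  th <- resolve_threshold(threshold, img)
  comps <- label_components(img > th, px)
  if (nrow(comps) == 0) {
    return(tibble::tibble(diameter_um = NA_real_, border = FALSE))
  }
  d2 <- (comps$x_um - center_x_um)^2 + (comps$y_um - center_y_um)^2
  i <- which.min(d2)
  tibble::tibble(diameter_um = comps$diameter_um[i], border = comps$border[i])
}

#' Swelling factor of measured pillars relative to the mold
#'
#' The swelling factor of one pillar is `(measured - mold_D) / mold_D`; the
#' field-level statistic is the mean and standard deviation over unflagged
#' pillars, comparable to the reported diameter increase of polyacrylamide
#' pillars in PBS relative to mold dimensions.
#'
#' @param measured_um Measured realized diameters, micrometers.
#' @param mold_diameter_um Mold-side circle diameter D, micrometers.
#' @return A one-row tibble: `mean`, `sd` (NA for a single measurement),
#'   `n`.
#' @export
swelling_factor <- function(measured_um, mold_diameter_um) {
  check_positive(mold_diameter_um, "mold_diameter_um")
  measured_um <- measured_um[!is.na(measured_um)]
  if (length(measured_um) == 0) {
    abort_validation("At least one unflagged diameter measurement is required.")
  }
  s <- (measured_um - mold_diameter_um) / mold_diameter_um
  tibble::tibble(mean = mean(s), sd = stats::sd(s), n = length(s))
}
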