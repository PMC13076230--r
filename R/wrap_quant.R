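#' Wrapping-score bin definition
#'
#' The ordinal 0-3 wrapping score grades how much of a pillar's
#' circumference carries myelin: 0 = no wrapping, 3 = a fully closed ring.
#' The endpoints are fixed by that definition; the intermediate coverage
#' edges and the ring-closure gap tolerance are explicit, reportable
#' parameters of this implementation.
#'
#' @param edges Increasing coverage-fraction cut points `(e1, e2, e3)`:
#'   score 0 when `c < e1`, 1 when `e1 <= c < e2`, 2 when `e2 <= c < e3`,
#'   3 when `c >= e3` and the ring closes.
#' @param gap_tolerance_deg Largest angular gap (degrees) a score-3 ring
#'   may contain; larger gaps demote the score to 2.
#' @return An object of class `score_bins`.
#' @export
score_bins <- function(edges = c(0.05, 0.45, 0.95), gap_tolerance_deg = 18) {
  if (length(edges) != 3L || any(diff(edges) <= 0) ||
    edges[1] <= 0 || edges[3] >= 1) {
    abort_validation("`edges` must be three strictly increasing values in (0, 1).")
  }
  check_non_negative(gap_tolerance_deg, "gap_tolerance_deg")
  structure(
    list(edges = edges, gap_tolerance_deg = gap_tolerance_deg),
    class = "score_bins"
  )
}

#' Angular myelin coverage around one pillar
#'
#' Samples the base-excluded MBP projection in `n_bins` equal angular
#' sectors of an annulus around the pillar. Each radial ray of a sector is
#' reduced to its maximum intensity across the annulus (so rings thinner
#' than the annulus are not diluted), and a sector counts as covered when
#' the mean over its rays exceeds the field threshold. Coverage is the covered
#' sector fraction; the maximum gap is the longest circular run of
#' uncovered sectors, in degrees.
#'
#' @param projection A `projection2d` of the MBP channel (base excluded).
#' @param center_x_um,center_y_um Pillar center, micrometers.
#' @param annulus_inner_um Inner annulus radius; at least the pillar radius.
#' @param annulus_outer_um Outer annulus radius.
#' @param n_bins Number of angular sectors (>= 36).
#' @param threshold Field threshold: `"otsu"` (computed on the projection)
#'   or a fixed numeric intensity.
#' @return A one-row tibble: `coverage`, `max_gap_deg`, `flagged`
#'   (TRUE when the annulus leaves the image, in which case coverage is NA).
#' @export
angular_coverage <- function(projection, center_x_um, center_y_um,
                             annulus_inner_um, annulus_outer_um,
                             n_bins = 72, threshold = "otsu") {
  stopifnot(inherits(projection, "projection2d"))
  if (n_bins < 36) abort_validation("`n_bins` must be >= 36.")
  if (annulus_outer_um <= annulus_inner_um || annulus_inner_um < 0) {
    abort_validation("Annulus radii must satisfy 0 <= inner < outer.")
  }
  th <- resolve_threshold(threshold, projection$intensity)
  sect <- sector_means(
    projection, center_x_um, center_y_um,
    annulus_inner_um, annulus_outer_um, n_bins
  )
  if (sect$flagged) {
    return(tibble::tibble(
      coverage = NA_real_, max_gap_deg = NA_real_, flagged = TRUE
    ))
  }
  covered <- sect$means > th
  gap_bins <- longest_false_run_circular(covered)
  tibble::tibble(
    coverage = mean(covered),
    max_gap_deg = gap_bins * 360 / n_bins,
    flagged = FALSE
  )
}

# Per-sector annulus statistic by dense radial/angular sampling with
# bilinear interpolation (sub-pixel steps so thin rings are not missed
# between pixel centers). Each ray contributes its radial maximum -- "does
# this ray cross myelin" -- so a ring much thinner than the annulus is not
# diluted below the intensity threshold; the sector value is the mean over
# its rays.
sector_means <- function(projection, cx, cy, r_in, r_out, n_bins) {
  px <- projection$pixel_size_um
  img <- projection$intensity
  if (cx - r_out < 0 || cy - r_out < 0 ||
    cx + r_out > (ncol(img) - 1) * px || cy + r_out > (nrow(img) - 1) * px) {
    return(list(means = NULL, flagged = TRUE))
  }
  radii <- seq(r_in, r_out, by = px / 2)
  # angular step fine enough to place several samples per sector even at
  # the inner radius
  n_theta <- max(n_bins * 4L, ceiling(2 * pi * r_out / (px / 2)))
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  xs <- cx + outer(cos(theta), radii)
  ys <- cy + outer(sin(theta), radii)
  vals <- matrix(
    interp_bilinear(img, as.vector(xs), as.vector(ys), px),
    nrow = n_theta
  )
  ray_mean <- apply(vals, 1, max)
  bin <- floor((theta / (2 * pi)) * n_bins) + 1L
  bin[bin > n_bins] <- n_bins
  means <- as.numeric(tapply(ray_mean, factor(bin, levels = seq_len(n_bins)),
    mean,
    na.rm = TRUE
  ))
  list(means = means, flagged = FALSE)
}

#' Assign the 0-3 wrapping score
#'
#' Coverage is binned by the configured edges; a candidate score of 3
#' additionally requires the largest angular gap not to exceed the bin
#' tolerance (the ring must close), otherwise the pillar scores 2.
#'
#' @param coverage Coverage fraction(s) in `[0, 1]`.
#' @param max_gap_deg Largest angular gap(s), degrees.
#' @param bins A [score_bins()].
#' @return Integer score(s) in `{0, 1, 2, 3}` (NA for NA coverage).
#' @export
assign_score <- function(coverage, max_gap_deg, bins = score_bins()) {
  stopifnot(inherits(bins, "score_bins"))
  if (any(coverage < 0 | coverage > 1, na.rm = TRUE)) {
    abort_validation("`coverage` must lie in [0, 1].")
  }
  s <- findInterval(coverage, bins$edges)
  demote <- !is.na(s) & s == 3L & max_gap_deg > bins$gap_tolerance_deg
  s[demote] <- 2L
  as.integer(s)
}

#' Myelin ring thickness at one pillar
#'
#' For each covered angular sector, the radial intensity profile outward
#' from the pillar edge is sampled and its full width at half maximum
#' (above the field threshold) taken as the local ring thickness; the
#' pillar-level thickness is the median over covered sectors. Values below
#' one pixel are floored at the pixel size and flagged as
#' resolution-limited.
#'
#' @inheritParams angular_coverage
#' @param pillar_radius_um Radius of the pillar (profile start).
#' @param max_extent_um How far beyond the pillar edge to profile.
#' @return A one-row tibble: `thickness_um`, `resolution_limited`,
#'   `flagged` (TRUE when no covered sector exists; thickness NA).
#' @export
ring_thickness <- function(projection, center_x_um, center_y_um,
                           pillar_radius_um, max_extent_um = 4,
                           n_bins = 72, threshold = "otsu") {
  stopifnot(inherits(projection, "projection2d"))
  px <- projection$pixel_size_um
  img <- projection$intensity
  th <- resolve_threshold(threshold, img)
  radii <- seq(
    max(pillar_radius_um - px, 0), pillar_radius_um + max_extent_um,
    by = px / 4
  )
  centers <- (seq_len(n_bins) - 0.5) * 2 * pi / n_bins
  widths <- vapply(centers, function(a) {
    prof <- interp_bilinear(
      img, center_x_um + cos(a) * radii, center_y_um + sin(a) * radii, px
    )
    fwhm_width(radii, prof, th)
  }, numeric(1))
  widths <- widths[!is.na(widths)]
  if (length(widths) == 0) {
    return(tibble::tibble(
      thickness_um = NA_real_, resolution_limited = FALSE, flagged = TRUE
    ))
  }
  t_um <- stats::median(widths)
  limited <- t_um < px
  tibble::tibble(
    thickness_um = max(t_um, px),
    resolution_limited = limited,
    flagged = FALSE
  )
}

# FWHM of the above-threshold portion of a radial profile; NA when the
# profile never exceeds the threshold.
fwhm_width <- function(r, v, threshold) {
  ok <- !is.na(v)
  r <- r[ok]
  v <- v[ok]
  if (length(v) < 3 || max(v) <= threshold) {
    return(NA_real_)
  }
  half <- max(v) / 2
  above <- v >= half
  if (!any(above)) {
    return(NA_real_)
  }
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  # linear interpolation of the crossing positions
  left <- if (i1 > 1) {
    r[i1 - 1] + (half - v[i1 - 1]) / (v[i1] - v[i1 - 1]) * (r[i1] - r[i1 - 1])
  } else {
    r[1]
  }
  right <- if (i2 < length(v)) {
    r[i2] + (v[i2] - half) / (v[i2] - v[i2 + 1]) * (r[i2 + 1] - r[i2])
  } else {
    r[length(v)]
  }
  right - left
}

#' g-ratio of a wrapped pillar
#'
#' `g = D / (D + 2 t)` where `D` is the (swollen) pillar diameter and `t`
#' the myelin ring thickness. An unwrapped structure (t = 0) has g = 1;
#' thicker myelin pushes g toward 0.
#'
#' @param diameter_um Pillar diameter D, micrometers (> 0).
#' @param thickness_um Myelin thickness t, micrometers (>= 0).
#' @return Numeric g-ratio(s) in `(0, 1]`.
#' @examples
#' g_ratio(5, 0.6646) # ~0.79, the range reported for 5-um pillars
#' @export
g_ratio <- function(diameter_um, thickness_um) {
  check_positive(diameter_um, "diameter_um")
  if (any(thickness_um < 0, na.rm = TRUE)) {
    abort_validation("`thickness_um` must be >= 0.")
  }
  diameter_um / (diameter_um + 2 * thickness_um)
}

#' Invert the g-ratio for thickness
#'
#' Solves `g = D / (D + 2 t)` for `t`.
#'
#' @param diameter_um Pillar diameter D, micrometers.
#' @param g g-ratio in `(0, 1]`.
#' @return Thickness `t = D (1 - g) / (2 g)`, micrometers.
#' @export
g_ratio_thickness <- function(diameter_um, g) {
  check_positive(diameter_um, "diameter_um")
  if (any(g <= 0 | g > 1)) abort_validation("`g` must lie in (0, 1].")
  diameter_um * (1 - g) / (2 * g)
}

#' Per-pillar wrapping measurements for a detected grid
#'
#' Runs [angular_coverage()], [assign_score()], [ring_thickness()] and
#' [g_ratio()] for every present pillar of a grid on the base-excluded MBP
#' projection. The annulus defaults to `[pillar radius, pillar radius +
#' annulus_width_um]` per pillar, using the measured diameter (falling back
#' to the field median for pillars without one). The g-ratio uses the
#' measured (swollen) diameter.
#'
#' @param projection A `projection2d` of the MBP channel (base excluded).
#' @param pillars A `pillar_grid` tibble from [detect_pillars()] (or any
#'   tibble with `pillar_id`, `x_um`, `y_um`, `diameter_um`, `present`).
#' @param bins A [score_bins()].
#' @param annulus_width_um Radial width of the sampling annulus.
#' @param n_bins Angular sectors per pillar.
#' @param threshold Field threshold (`"otsu"` computed once on the
#'   projection, or fixed numeric).
#' @return A tibble with one row per present pillar: `pillar_id`,
#'   `coverage`, `max_gap_deg`, `score`, `thickness_um`, `g_ratio`,
#'   `flagged`, `resolution_limited`.
#' @export
measure_wrapping <- function(projection, pillars, bins = score_bins(),
                             annulus_width_um = 2, n_bins = 72,
                             threshold = "otsu") {
  stopifnot(inherits(projection, "projection2d"))
  th <- resolve_threshold(threshold, projection$intensity)
  pres <- pillars[pillars$present, , drop = FALSE]
  med_d <- stats::median(pres$diameter_um, na.rm = TRUE)
  purrr::pmap_dfr(
    list(pres$pillar_id, pres$x_um, pres$y_um, pres$diameter_um),
    function(id, x, y, d) {
      if (is.na(d)) d <- med_d
      r <- d / 2
      cov <- angular_coverage(
        projection, x, y, r, r + annulus_width_um,
        n_bins = n_bins, threshold = th
      )
      if (cov$flagged || is.na(cov$coverage)) {
        return(tibble::tibble(
          pillar_id = id, coverage = NA_real_, max_gap_deg = NA_real_,
          score = NA_integer_, thickness_um = NA_real_, g_ratio = NA_real_,
          flagged = TRUE, resolution_limited = FALSE
        ))
      }
      sc <- assign_score(cov$coverage, cov$max_gap_deg, bins)
      if (cov$coverage > 0) {
        tk <- ring_thickness(
          projection, x, y, r,
          max_extent_um = annulus_width_um + 2,
          n_bins = n_bins, threshold = th
        )
      } else {
        tk <- tibble::tibble(
          thickness_um = NA_real_, resolution_limited = FALSE, flagged = TRUE
        )
      }
      tibble::tibble(
        pillar_id = id,
        coverage = cov$coverage,
        max_gap_deg = cov$max_gap_deg,
        score = sc,
        thickness_um = tk$thickness_um,
        g_ratio = if (is.na(tk$thickness_um)) NA_real_ else g_ratio(d, tk$thickness_um),
        flagged = FALSE,
        resolution_limited = tk$resolution_limited
      )
    }
  )
}
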