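#' Construct an AFM force curve
#'
#' An approach force-distance record: piezo position (increasing toward the
#' sample) and measured cantilever force, plus the probe constants needed
#' for the spherical Hertz analysis.
#'
#' @param z_m Piezo positions, meters, strictly monotone increasing toward
#'   the sample; at least 100 samples.
#' @param force_n Measured forces, newtons.
#' @param k Cantilever spring constant, N/m.
#' @param bead_radius_m Radius of the glued polystyrene bead, meters (half
#'   the stated bead diameter, e.g. 12.5 um for a 25-um bead).
#' @param nu Sample Poisson ratio; 0.5 for incompressible hydrogel.
#' @return A tibble (`z_m`, `force_n`) of class `force_curve` with the
#'   probe constants as attributes.
#' @export
force_curve <- function(z_m, force_n, k, bead_radius_m, nu = 0.5) {
  check_positive(k, "k")
  check_positive(bead_radius_m, "bead_radius_m")
  if (nu < 0 || nu > 0.5) abort_validation("`nu` must lie in [0, 0.5].")
  if (length(z_m) != length(force_n) || length(z_m) < 100) {
    abort_validation("A force curve needs >= 100 (z, F) samples.")
  }
  if (any(diff(z_m) <= 0)) {
    abort_validation("`z_m` must be strictly monotone increasing.")
  }
  out <- tibble::tibble(z_m = z_m, force_n = force_n)
  structure(out,
    class = c("force_curve", class(out)),
    k = k, bead_radius_m = bead_radius_m, nu = nu
  )
}

hertz_prefactor <- function(E, bead_radius_m, nu) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(bead_radius_m)
}

#' Hertz force at a given indentation
#'
#' `F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2)` for a sphere of radius
#' `R` indenting a half-space of modulus `E` by `delta`.
#'
#' @param delta_m Indentation depth(s), meters (negative values give 0).
#' @param E Young's modulus, Pa.
#' @param bead_radius_m Sphere radius, meters.
#' @param nu Poisson ratio.
#' @return Force(s), newtons.
#' @export
hertz_force <- function(delta_m, E, bead_radius_m, nu = 0.5) {
  check_positive(E, "E")
  check_positive(bead_radius_m, "bead_radius_m")
  hertz_prefactor(E, bead_radius_m, nu) * pmax(delta_m, 0)^1.5
}

#' Simulate an AFM approach curve on a Hertzian sample
#'
#' For piezo positions beyond the contact point the indentation satisfies
#' `delta = (z - z0) - F/k` with `F = (4/3)(E/(1-nu^2)) sqrt(R) delta^(3/2)`
#' solved self-consistently (the cantilever bends by `F/k`, so the tip
#' advances less than the piezo). The pre-contact region is a flat baseline.
#' Gaussian force noise of `noise_sd` is added throughout.
#'
#' @param E True Young's modulus, Pa.
#' @param bead_radius_m Bead radius, meters.
#' @param k Spring constant, N/m.
#' @param nu Poisson ratio.
#' @param contact_z_m Contact point z0 within the sweep, meters.
#' @param z_span_m Total piezo travel; the sweep runs `[0, z_span_m]` and
#'   must leave >= 2 um beyond the contact point.
#' @param n Number of evenly spaced samples.
#' @param noise_sd Gaussian force noise, newtons.
#' @param baseline_n Constant force offset of the uncorrected baseline.
#' @param seed Integer seed.
#' @return A [force_curve()] with attributes `true_E` and `true_contact_z`.
#' @export
simulate_force_curve <- function(E, bead_radius_m = 12.5e-6, k = 0.1,
                                 nu = 0.5, contact_z_m = 2e-6,
                                 z_span_m = contact_z_m + 2e-6, n = 1024,
                                 noise_sd = 0, baseline_n = 0, seed = 1L) {
  check_positive(E, "E")
  check_positive(bead_radius_m, "bead_radius_m")
  check_positive(k, "k")
  if (nu < 0 || nu >= 0.5 + 1e-12) {
    abort_validation("`nu` must lie in [0, 0.5].")
  }
  z <- seq(0, z_span_m, length.out = n)
  A <- hertz_prefactor(E, bead_radius_m, nu)
  f <- vapply(z, function(zi) {
    s <- zi - contact_z_m
    if (s <= 0) {
      return(0)
    }
    solve_indentation(s, A, k)
  }, numeric(1))
  force <- A * f^1.5 + baseline_n
  force <- with_seed_(seed, force + stats::rnorm(n, 0, noise_sd))
  out <- force_curve(z, force, k = k, bead_radius_m = bead_radius_m, nu = nu)
  attr(out, "true_E") <- E
  attr(out, "true_contact_z") <- contact_z_m
  out
}

# Solve delta + (A/k) delta^(3/2) = s for delta by Newton iteration
# (monotone, unique root).
solve_indentation <- function(s, A, k) {
  delta <- s
  for (i in 1:60) {
    g <- delta + (A / k) * delta^1.5 - s
    gp <- 1 + 1.5 * (A / k) * sqrt(delta)
    step <- g / gp
    delta <- max(delta - step, 0)
    if (abs(step) < 1e-18) break
  }
  delta
}

#' Read a force curve from two-column delimited text
#'
#' The file holds piezo position (m) and force (N), whitespace- or
#' comma-delimited. Probe constants may be given as header comment lines
#' (`# k: 0.1`, `# bead_radius_m: 12.5e-6`, `# nu: 0.5`) or as arguments;
#' arguments win.
#'
#' @param path File path.
#' @param k,bead_radius_m,nu Probe constants (override header values).
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, k = NULL, bead_radius_m = NULL, nu = NULL) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    mkv <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(\\S+)", h))[[1]]
    if (length(mkv) == 3) meta[[mkv[2]]] <- as.numeric(mkv[3])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(
    text = body,
    sep = if (grepl(",", body[1])) "," else "",
    col.names = c("z_m", "force_n")
  )
  force_curve(
    df$z_m, df$force_n,
    k = k %||% meta$k,
    bead_radius_m = bead_radius_m %||% meta$bead_radius_m,
    nu = nu %||% meta$nu %||% 0.5
  )
}

#' Write a force curve to delimited text
#' @param curve A [force_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  hdr <- sprintf(
    "# k: %.6g\n# bead_radius_m: %.6g\n# nu: %.6g",
    attr(curve, "k"), attr(curve, "bead_radius_m"), attr(curve, "nu")
  )
  writeLines(c(hdr, sprintf("%.9e,%.9e", curve$z_m, curve$force_n)), path)
  invisible(path)
}

#' Preprocess a force curve: smooth, de-baseline, find contact, correct bending
#'
#' The processing chain applied before the Hertz fit: moving-average
#' smoothing; straight-line baseline fitted on the pre-contact segment and
#' subtracted; contact point chosen by a two-segment piecewise fit (flat
#' baseline + Hertz-shaped rise) minimizing total squared residual over a
#' coarse grid of candidates, refined by local optimization; cantilever
#' bending removed via the vertical tip position, `delta = (z - z0) - F/k`.
#'
#' @param curve A [force_curve()].
#' @param smooth_window Moving-average window, samples (odd; 1 = off).
#' @return An object of class `hertz_prep`: list with tibble `data`
#'   (`delta_m`, `force_n`, post-contact only), `contact_z_m`,
#'   `baseline_rms_n`, and the probe constants.
#' @export
preprocess_curve <- function(curve, smooth_window = 11) {
  stopifnot(inherits(curve, "force_curve"))
  k <- attr(curve, "k")
  R <- attr(curve, "bead_radius_m")
  nu <- attr(curve, "nu")
  z <- curve$z_m
  f <- smooth_ma(curve$force_n, smooth_window)
  n <- length(z)
  lo <- max(ceiling(0.1 * n), 20L)
  hi <- n - 20L
  if (hi <= lo) abort_validation("Curve too short for contact-point search.")

  cand <- unique(round(seq(lo, hi, length.out = 160)))
  ss <- vapply(cand, function(j) segment_ss(z, f, z[j], k), numeric(1))
  j_best <- cand[which.min(ss)]
  # continuous refinement of z0 between the neighbouring grid candidates
  step <- max(diff(cand)[1], 1)
  lo_z <- z[max(lo, j_best - step)]
  hi_z <- z[min(hi, j_best + step)]
  # refine against the raw forces: smoothing smears the contact kink and
  # would bias z0 early by about half the smoothing window
  opt <- stats::optimize(
    function(z0) segment_ss(z, curve$force_n, z0, k), c(lo_z, hi_z),
    tol = 1e-11
  )
  z0 <- opt$minimum
  j0 <- max(which(z <= z0))

  pre <- seq_len(j0)
  bl <- stats::lm.fit(cbind(1, z[pre]), f[pre])
  f_corr <- f - (bl$coefficients[1] + bl$coefficients[2] * z)
  baseline_rms <- sqrt(mean(bl$residuals^2))

  post <- which(z > z0)
  if (length(post) < 10 ||
    max(f_corr[post]) < max(5 * baseline_rms, 1e-15)) {
    abort_computation("No contact detected: curve is baseline only.")
  }
  delta <- (z[post] - z0) - f_corr[post] / k
  keep <- delta > 0
  structure(
    list(
      data = tibble::tibble(
        delta_m = delta[keep], force_n = f_corr[post][keep]
      ),
      contact_z_m = z0,
      baseline_rms_n = baseline_rms,
      k = k, bead_radius_m = R, nu = nu
    ),
    class = "hertz_prep"
  )
}

smooth_ma <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) {
    return(x)
  }
  if (window %% 2L == 0L) window <- window + 1L
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  # fall back to the raw values at the ends where the window is incomplete
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

# Total squared residual of a two-segment model: straight-line baseline up
# to z0, plus a Hertz-shaped rise beyond it. The rise is fitted against the
# bending-corrected indentation delta = (z - z0) - F/k (F from the
# baseline-subtracted curve), so the search is self-consistent with the
# downstream fit; the model is linear in the Hertz prefactor.
segment_ss <- function(z, f, z0, k) {
  pre <- which(z <= z0)
  post <- which(z > z0)
  if (length(pre) < 5 || length(post) < 5) {
    return(Inf)
  }
  blfit <- stats::lm.fit(cbind(1, z[pre]), f[pre])
  b0 <- blfit$coefficients[1] + blfit$coefficients[2] * z
  y <- f[post] - b0[post]
  x <- pmax((z[post] - z0) - y / k, 0)^1.5
  sxx <- sum(x * x)
  cx <- if (sxx > 0) max(sum(x * y) / sxx, 0) else 0
  sum(blfit$residuals^2) + sum((y - cx * x)^2)
}

#' Fit the spherical Hertz model to processed indentation data
#'
#' Least-squares fit of `F = (4/3)(E/(1-nu^2)) sqrt(R) delta^(3/2)` for the
#' Young's modulus `E`; linear in `E` given the indentation, so the
#' estimate is closed-form. Only indentations up to `delta_max_fit_m` are
#' used (shallow-indentation validity of the Hertz contact model; default
#' 10% of the bead radius).
#'
#' @param prep A `hertz_prep` from [preprocess_curve()].
#' @param delta_max_fit_m Largest indentation included in the fit.
#' @return An object of class `hertz_fit`: `E_pa`, `contact_z_m`,
#'   `rms_residual_n`, `delta_range_m`, `n_points`, plus the probe
#'   constants and the fitted data for plotting.
#' @export
fit_hertz <- function(prep, delta_max_fit_m = 0.1 * prep$bead_radius_m) {
  stopifnot(inherits(prep, "hertz_prep"))
  d <- prep$data[prep$data$delta_m <= delta_max_fit_m, , drop = FALSE]
  if (nrow(d) < 20) {
    abort_computation(
      "Insufficient post-contact data below `delta_max_fit_m` (need >= 20 samples)."
    )
  }
  x <- d$delta_m^1.5
  cc <- sum(x * d$force_n) / sum(x * x)
  pref <- (4 / 3) * sqrt(prep$bead_radius_m) / (1 - prep$nu^2)
  E <- cc / pref
  if (!is.finite(E) || E <= 0) {
    abort_computation("Hertz fit failed: non-positive modulus.")
  }
  resid <- d$force_n - cc * x
  structure(
    list(
      E_pa = E,
      contact_z_m = prep$contact_z_m,
      rms_residual_n = sqrt(mean(resid^2)),
      delta_range_m = range(d$delta_m),
      n_points = nrow(d),
      k = prep$k, bead_radius_m = prep$bead_radius_m, nu = prep$nu,
      data = d
    ),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.3g kPa (contact z0 = %.3g um, rms %.3g nN, %d pts)\n",
    x$E_pa / 1e3, x$contact_z_m * 1e6, x$rms_residual_n * 1e9, x$n_points
  ))
  invisible(x)
}

#' Process and fit one force curve
#'
#' Convenience wrapper: [preprocess_curve()] then [fit_hertz()].
#'
#' @inheritParams preprocess_curve
#' @inheritParams fit_hertz
#' @return A `hertz_fit`.
#' @export
fit_force_curve <- function(curve, smooth_window = 11,
                            delta_max_fit_m = NULL) {
  prep <- preprocess_curve(curve, smooth_window = smooth_window)
  fit_hertz(
    prep,
    delta_max_fit_m = delta_max_fit_m %||% (0.1 * prep$bead_radius_m)
  )
}

#' Per-gel stiffness aggregate
#'
#' The stiffness of one gel is the arithmetic mean of its indentation
#' measurements (a 3 x 3 grid, nine curves, in the standard protocol).
#'
#' @param E_pa Fitted Young's moduli for one gel, Pa.
#' @return A one-row tibble: `mean_E_pa`, `sd_E_pa` (NA for one value),
#'   `n`.
#' @export
aggregate_gel <- function(E_pa) {
  if (length(E_pa) < 1) abort_validation("At least one modulus is required.")
  tibble::tibble(
    mean_E_pa = mean(E_pa), sd_E_pa = stats::sd(E_pa), n = length(E_pa)
  )
}

#' Per-gel aggregates for a tidy table of fits
#'
#' @param data Data frame with one row per fitted curve.
#' @param E Column name (string) with moduli in Pa.
#' @param gel Column name (string) with the gel identifier.
#' @return A tibble with one row per gel: `gel`, `mean_E_pa`, `sd_E_pa`,
#'   `n`.
#' @export
aggregate_gels <- function(data, E = "E_pa", gel = "gel") {
  data |>
    dplyr::group_by(gel = .data[[gel]]) |>
    dplyr::summarise(
      mean_E_pa = mean(.data[[E]]),
      sd_E_pa = stats::sd(.data[[E]]),
      n = dplyr::n(),
      .groups = "drop"
    )
}
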