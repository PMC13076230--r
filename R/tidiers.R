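#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Hertz fit
#'
#' @param x A `hertz_fit`.
#' @param ... Ignored.
#' @return One-row tibble: `E_pa`, `contact_z_m`, `rms_residual_n`,
#'   `n_points`.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(
    E_pa = x$E_pa,
    contact_z_m = x$contact_z_m,
    rms_residual_n = x$rms_residual_n,
    n_points = x$n_points
  )
}

#' @rdname tidy.hertz_fit
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(
    E_pa = x$E_pa,
    k = x$k,
    bead_radius_m = x$bead_radius_m,
    nu = x$nu,
    delta_min_m = x$delta_range_m[1],
    delta_max_m = x$delta_range_m[2],
    n_points = x$n_points
  )
}

#' Tidy a thickness-versus-layers regression
#'
#' @param x A `lamella_regression`.
#' @param ... Ignored.
#' @return `tidy()`: the term-level coefficient table; `glance()`: a
#'   one-row model summary with `slope_nm_per_layer`, `intercept_nm`,
#'   `r_squared`, `n`.
#' @export
tidy.lamella_regression <- function(x, ...) {
  co <- suppressWarnings(summary(x$fit)$coefficients)
  tibble::tibble(
    term = c("intercept_nm", "slope_nm_per_layer"),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.lamella_regression
#' @export
glance.lamella_regression <- function(x, ...) {
  tibble::tibble(
    slope_nm_per_layer = x$slope_nm_per_layer,
    intercept_nm = x$intercept_nm,
    r_squared = x$r_squared,
    n = x$n
  )
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Ignored.
#' @return `tidy()`: the Tukey pairwise table; `glance()`: the one-row
#'   ANOVA summary.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$tukey
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  x$anova
}
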