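#' Wrapping-score distribution plot
#'
#' Stacked percentage bars of the 0-3 wrapping score per condition, the
#' standard way score distributions are compared across stiffness, coating
#' or treatment groups.
#'
#' @param field_summaries Tibble from [summarize_field()] /
#'   [run_quantify()] (needs `condition` and the `pct_score*` columns).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(field_summaries) {
  long <- field_summaries |>
    tidyr::pivot_longer(
      cols = dplyr::starts_with("pct_score"),
      names_to = "score", values_to = "pct",
      names_prefix = "pct_score"
    ) |>
    dplyr::group_by(.data$condition, .data$score) |>
    dplyr::summarise(pct = mean(.data$pct, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$condition, y = .data$pct, fill = .data$score
    )
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_viridis_d(name = "Wrapping\nscore") +
    ggplot2::labs(
      x = NULL, y = "Pillars (%)",
      title = "Wrapping-score distribution"
    ) +
    ggplot2::theme_minimal()
}

#' g-ratio versus pillar diameter plot
#'
#' @param per_pillar Per-pillar tibble with `diameter_um` and `g_ratio`
#'   (e.g. from [run_quantify()]).
#' @return A ggplot object.
#' @export
plot_g_ratio <- function(per_pillar) {
  d <- per_pillar[!is.na(per_pillar$g_ratio), , drop = FALSE]
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$diameter_um, y = .data$g_ratio)
  ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "Pillar diameter (µm)", y = "g-ratio",
      title = "g-ratio by pillar diameter"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Per-gel Young's modulus plot
#'
#' @param gels Tibble from [aggregate_gels()].
#' @return A ggplot object.
#' @export
plot_modulus <- function(gels) {
  ggplot2::ggplot(
    gels,
    ggplot2::aes(x = factor(.data$gel), y = .data$mean_E_pa / 1e3)
  ) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = (.data$mean_E_pa - .data$sd_E_pa) / 1e3,
        ymax = (.data$mean_E_pa + .data$sd_E_pa) / 1e3
      ),
      width = 0.2
    ) +
    ggplot2::labs(
      x = "Gel", y = "Young's modulus (kPa)",
      title = "AFM stiffness per gel (mean ± s.d.)"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Hertz fit over its processed indentation data
#'
#' @param object A `hertz_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hertz_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    delta_m = seq(0, max(d$delta_m), length.out = 200)
  )
  curve$force_n <- hertz_force(
    curve$delta_m, object$E_pa, object$bead_radius_m, object$nu
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_m * 1e6, .data$force_n * 1e9)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_line(
      data = curve, color = "red"
    ) +
    ggplot2::labs(
      x = "Indentation (µm)", y = "Force (nN)",
      title = sprintf("Hertz fit: E = %.2f kPa", object$E_pa / 1e3)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a lamellar transect profile
#'
#' @param object A `lamella_profile`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.lamella_profile <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$radius_nm, .data$intensity)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Radial position (nm)", y = "Intensity",
      title = "Lamellar transect"
    ) +
    ggplot2::theme_minimal()
}
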