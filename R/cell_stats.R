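#' Count nuclei on a full-height projection
#'
#' Thresholds the Hoechst channel, splits touching blobs by watershed on
#' the distance transform and counts components above a minimum area.
#' Somata in these cultures are well separated at seeding density, so a
#' single watershed pass with mild tolerance suffices.
#'
#' @param projection A `projection2d` of the NUCLEI channel (full height).
#' @param min_area_um2 Minimum component area kept, square micrometers.
#' @param threshold `"otsu"` or a fixed numeric intensity.
#' @param watershed_tolerance Minimum depth (in distance-transform units,
#'   pixels) between two catchment basins kept separate.
#' @return A one-row tibble: `n_cells`, `flag` (`"ok"`, `"blank"` or
#'   `"saturated"`).
#' @export
count_nuclei <- function(projection, min_area_um2 = 12, threshold = "otsu",
                         watershed_tolerance = 1) {
  stopifnot(inherits(projection, "projection2d"))
  px <- projection$pixel_size_um
  img <- projection$intensity
  rng <- range(img)
  if (diff(rng) < 1e-9) {
    flag <- if (rng[1] > 0.5 * max(rng[2], 1)) "saturated" else "blank"
    return(tibble::tibble(n_cells = 0L, flag = flag))
  }
  th <- resolve_threshold(threshold, img)
  mask <- img > th
  if (!any(mask)) {
    return(tibble::tibble(n_cells = 0L, flag = "blank"))
  }
  dm <- EBImage::distmap(mask * 1)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  n <- max(lab)
  areas <- tabulate(lab[lab > 0], n) * px^2
  flag <- if (mean(mask) > 0.9) "saturated" else "ok"
  tibble::tibble(n_cells = sum(areas >= min_area_um2), flag = flag)
}

#' Field-level wrapping summary
#'
#' Aggregates per-pillar wrap measurements into the field statistics used
#' throughout the assay: counts and percentages per score, fully wrapped
#' (score 3) pillars per cell, and the pillar:cell ratio. Pillars flagged
#' by the wrap measurement are excluded from all denominators; their count
#' is reported so nothing is dropped silently.
#'
#' @param measurements Tibble from [measure_wrapping()].
#' @param n_cells Nuclei count for the field.
#' @param extent_um Field extent `c(x, y)` in micrometers (default the
#'   250 x 250 um quantification field).
#' @param field_id,condition Optional labels carried into the summary.
#' @return A one-row tibble with `field_id`, `condition`, `extent_x_um`,
#'   `extent_y_um`, `n_cells`, `n_pillars`, `n_flagged`, `n_score0` ...
#'   `n_score3`, `pct_score0` ... `pct_score3`, `score3_per_cell`,
#'   `pillar_to_cell_ratio`, `per_cell_defined`.
#' @export
summarize_field <- function(measurements, n_cells,
                            extent_um = c(250, 250),
                            field_id = 1L, condition = NA_character_) {
  if (nrow(measurements) == 0) {
    abort_validation("`measurements` must be non-empty.")
  }
  if (n_cells < 0) abort_validation("`n_cells` must be >= 0.")
  ok <- measurements[!measurements$flagged & !is.na(measurements$score), ,
    drop = FALSE
  ]
  n_flagged <- nrow(measurements) - nrow(ok)
  n_pillars <- nrow(ok)
  counts <- vapply(0:3, function(s) sum(ok$score == s), integer(1))
  pct <- if (n_pillars > 0) 100 * counts / n_pillars else rep(NA_real_, 4)
  per_cell_defined <- n_cells > 0
  tibble::tibble(
    field_id = field_id,
    condition = condition,
    extent_x_um = extent_um[1],
    extent_y_um = extent_um[2],
    n_cells = as.integer(n_cells),
    n_pillars = n_pillars,
    n_flagged = n_flagged,
    n_score0 = counts[1], n_score1 = counts[2],
    n_score2 = counts[3], n_score3 = counts[4],
    pct_score0 = pct[1], pct_score1 = pct[2],
    pct_score2 = pct[3], pct_score3 = pct[4],
    score3_per_cell = if (per_cell_defined) counts[4] / n_cells else NA_real_,
    pillar_to_cell_ratio = if (per_cell_defined) n_pillars / n_cells else NA_real_,
    per_cell_defined = per_cell_defined
  )
}

#' Fold change relative to a reference condition
#'
#' Divides values by the mean of the reference values (e.g. per-field cell
#' numbers normalized to flat-surface fields, or wrapped-pillars-per-cell
#' standardized on a vehicle control). When `reference` has length > 1 the
#' denominator is its mean, i.e. the ratio of condition mean to reference
#' mean rather than a mean of per-field ratios.
#'
#' @param values Numeric vector of condition values.
#' @param reference Reference value(s); mean must be > 0.
#' @return `values / mean(reference)`.
#' @export
fold_change <- function(values, reference) {
  ref <- mean(reference)
  if (!is.finite(ref) || ref <= 0) {
    abort_validation("The reference must have a positive mean.")
  }
  values / ref
}

#' One-way ANOVA with Tukey HSD across conditions
#'
#' Standard reporting statistics for per-field values grouped by condition:
#' one-way analysis of variance followed by Tukey's honestly-significant-
#' difference pairwise comparisons.
#'
#' @param data A data frame of per-field values.
#' @param value Column name (string) holding the response.
#' @param group Column name (string) holding the condition label.
#' @return An object of class `group_comparison` with elements `anova`
#'   (tibble: `f_statistic`, `df_between`, `df_within`, `p_value`) and
#'   `tukey` (tibble: `contrast`, `diff`, `conf_low`, `conf_high`,
#'   `p_adj`). Use [generics::tidy()] / [generics::glance()].
#' @export
compare_groups <- function(data, value, group) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) {
    abort_validation("At least two groups are required.")
  }
  if (any(table(g) < 2)) {
    abort_validation("Each group needs at least two observations.")
  }
  if (stats::sd(v) == 0) {
    abort_validation("Degenerate input: the response has zero variance.")
  }
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  comparison <- structure(
    list(
      anova = tibble::tibble(
        f_statistic = an[["F value"]][1],
        df_between = an[["Df"]][1],
        df_within = an[["Df"]][2],
        p_value = an[["Pr(>F)"]][1]
      ),
      tukey = tibble::tibble(
        contrast = rownames(tk),
        diff = tk[, "diff"],
        conf_low = tk[, "lwr"],
        conf_high = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
    ),
    class = "group_comparison"
  )
  comparison
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
    x$anova$df_between, x$anova$df_within,
    x$anova$f_statistic, x$anova$p_value
  ))
  print(x$tukey)
  invisible(x)
}
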