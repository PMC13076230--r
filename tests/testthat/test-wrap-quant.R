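test_that("angular coverage reads full rings, blanks and half arcs correctly", {
  spec <- tiny_spec(rows = 1, cols = 1, h = 8)
  r <- spec$realized_diameter_um / 2
  cases <- list(
    list(cov = 1, exp_cov = 1, exp_gap = 0),
    list(cov = 0, exp_cov = 0, exp_gap = 360),
    list(cov = 0.5, exp_cov = 0.5, exp_gap = 180)
  )
  for (cs in cases) {
    truth <- simulate_field_truth(spec,
      coverage = cs$cov, n_nuclei = 0,
      seed = 31
    )
    fx <- rendered_fixture(spec, truth)
    p <- truth$pillars
    got <- angular_coverage(fx$mbp, p$x_um, p$y_um, r, r + 2, threshold = 0.5)
    expect_equal(got$coverage, cs$exp_cov, tolerance = 1.01 / 72)
    expect_equal(got$max_gap_deg, cs$exp_gap, tolerance = 1.01 * 360 / 72)
    expect_false(got$flagged)
  }
})

test_that("annuli leaving the image are flagged, not measured", {
  pr <- pillarwrap:::new_projection2d(matrix(1, 20, 20), "MBP", c(4, 20), 0.25)
  got <- angular_coverage(pr, 0.5, 0.5, 1, 3, threshold = 0.5)
  expect_true(got$flagged)
  expect_true(is.na(got$coverage))
})

test_that("score assignment follows the bins and the ring-closure rule", {
  bins <- score_bins()
  expect_identical(assign_score(0, 360, bins), 0L)
  expect_identical(assign_score(1, 0, bins), 3L)
  expect_identical(assign_score(0.96, 30, bins), 2L)
  expect_identical(assign_score(0.96, 10, bins), 3L)
  expect_identical(assign_score(0.25, 270, bins), 1L)
  expect_identical(assign_score(0.5, 180, bins), 2L)
  # score is non-decreasing in coverage at fixed gap
  cov <- seq(0, 1, by = 0.01)
  expect_true(all(diff(assign_score(cov, 10, bins)) >= 0))
  expect_error(assign_score(1.2, 0, bins),
    class = "pillarwrap_validation_error"
  )
  expect_error(score_bins(edges = c(0.5, 0.4, 0.9)),
    class = "pillarwrap_validation_error"
  )
})

test_that("ring thickness is recovered within one pixel on noiseless rings", {
  spec <- tiny_spec(rows = 1, cols = 1, h = 8)
  truth <- simulate_field_truth(spec,
    coverage = 1, thickness_um = 0.66,
    n_nuclei = 0, seed = 32
  )
  fx <- rendered_fixture(spec, truth)
  p <- truth$pillars
  tk <- ring_thickness(
    fx$mbp, p$x_um, p$y_um,
    pillar_radius_um = spec$realized_diameter_um / 2, threshold = 0.5
  )
  expect_equal(tk$thickness_um, 0.66, tolerance = spec$pixel_size_um / 0.66)
  expect_false(tk$flagged)
})

test_that("bare-background profiles yield an undefined, flagged thickness", {
  pr <- pillarwrap:::new_projection2d(
    matrix(0, 60, 60), "MBP", c(4, 20), 0.25
  )
  tk <- ring_thickness(pr, 7.5, 7.5, 3, threshold = 0.5)
  expect_true(tk$flagged)
  expect_true(is.na(tk$thickness_um))
})

test_that("g-ratio matches its definition and is monotone", {
  expect_equal(g_ratio(5, 0), 1)
  expect_equal(g_ratio(5, 0.6646), 0.790, tolerance = 5e-4)
  expect_equal(g_ratio(3, 0.75), 2 / 3)
  t_grid <- seq(0, 3, by = 0.1)
  expect_true(all(diff(g_ratio(5, t_grid)) < 0))
  D_grid <- seq(1, 10, by = 0.5)
  expect_true(all(diff(g_ratio(D_grid, 0.66)) > 0))
  expect_error(g_ratio(5, -1), class = "pillarwrap_validation_error")
  expect_error(g_ratio(0, 1), class = "pillarwrap_validation_error")
})

test_that("g-ratio inversion round-trips to machine precision", {
  for (D in c(3, 5, 10)) {
    for (t in c(0.05, 0.5, 1.5)) {
      g <- g_ratio(D, t)
      expect_equal(g_ratio_thickness(D, g), t, tolerance = 1e-12)
    }
  }
})

test_that("measure_wrapping reproduces per-class truth on a mixed field", {
  spec <- tiny_spec(rows = 4, cols = 4, h = 8)
  classes <- c(0, 0.25, 0.6, 1)
  truth <- simulate_field_truth(spec,
    coverage = rep(classes, 4),
    n_nuclei = 0, seed = 33
  )
  fx <- rendered_fixture(spec, truth)
  grid <- detect_pillars(fx$pillar, spec$pitch_um, spec$realized_diameter_um)
  w <- measure_wrapping(fx$mbp, grid)
  j <- dplyr::inner_join(
    w, dplyr::select(truth$pillars, "pillar_id", true_cov = "coverage"),
    by = "pillar_id"
  )
  expect_lte(max(abs(j$coverage - j$true_cov)), 1 / 72 + 1e-9)
  expected_scores <- assign_score(
    j$true_cov, ifelse(j$true_cov >= 1, 0, 360 * (1 - j$true_cov))
  )
  expect_identical(j$score, expected_scores)
  # g-ratio present exactly where a ring was measured
  expect_true(all(is.na(j$g_ratio) == is.na(j$thickness_um)))
})
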