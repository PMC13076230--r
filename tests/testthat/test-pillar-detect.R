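test_that("noiseless grids are recovered with sub-pixel centers", {
  spec <- tiny_spec(rows = 5, cols = 5, h = 6)
  truth <- simulate_field_truth(spec, coverage = 0, n_nuclei = 0, seed = 21)
  fx <- rendered_fixture(spec, truth)
  grid <- detect_pillars(fx$pillar, spec$pitch_um, spec$realized_diameter_um)
  expect_identical(sum(grid$present), 25L)
  merged <- dplyr::inner_join(
    tibble::as_tibble(grid), truth$pillars,
    by = c("row", "col"), suffix = c("", "_true")
  )
  err <- sqrt((merged$x_um - merged$x_um_true)^2 +
    (merged$y_um - merged$y_um_true)^2)
  expect_lt(max(err), 0.5 * spec$pixel_size_um)
})

test_that("diameters are recovered within one pixel across the design grid", {
  for (D in c(3, 5, 10)) {
    for (d in c(5, 10, 15)) {
      spec <- tiny_spec(rows = 3, cols = 3, mold_D = D, d = d, h = 4, px = 0.3)
      truth <- simulate_field_truth(spec, coverage = 0, n_nuclei = 0, seed = D + d)
      fx <- rendered_fixture(spec, truth)
      grid <- detect_pillars(fx$pillar, spec$pitch_um, spec$realized_diameter_um)
      expect_identical(sum(grid$present), 9L)
      expect_lt(
        max(abs(grid$diameter_um - spec$realized_diameter_um)),
        spec$pixel_size_um
      )
    }
  }
})

test_that("detection is equivariant to whole-pixel translations", {
  spec <- tiny_spec(rows = 3, cols = 3, h = 6)
  truth <- simulate_field_truth(spec, coverage = 0, n_nuclei = 0, seed = 22)
  fx <- rendered_fixture(spec, truth)
  grid0 <- detect_pillars(fx$pillar, spec$pitch_um, spec$realized_diameter_um)
  shift_px <- 4L
  m <- fx$pillar$intensity
  shifted <- matrix(0, nrow(m), ncol(m))
  shifted[, (shift_px + 1):ncol(m)] <- m[, 1:(ncol(m) - shift_px)]
  pr <- pillarwrap:::new_projection2d(
    shifted, "PILLAR", fx$pillar$z_range_um, spec$pixel_size_um
  )
  grid1 <- detect_pillars(pr, spec$pitch_um, spec$realized_diameter_um)
  expect_equal(
    grid1$x_um[grid1$present],
    grid0$x_um[grid0$present] + shift_px * spec$pixel_size_um,
    tolerance = 1e-8
  )
  expect_equal(grid1$y_um[grid1$present], grid0$y_um[grid0$present])
})

test_that("a blank image raises a no-grid error", {
  pr <- pillarwrap:::new_projection2d(
    matrix(0, 50, 50), "PILLAR", c(0, 1), 0.25
  )
  expect_error(detect_pillars(pr, 16, 6),
    class = "pillarwrap_computation_error"
  )
})

test_that("border-clipped pillars are flagged", {
  spec <- tiny_spec(rows = 3, cols = 3, h = 4)
  truth <- simulate_field_truth(spec, coverage = 0, n_nuclei = 0, seed = 23)
  fx <- rendered_fixture(spec, truth)
  # crop through the last pillar column so its disc touches the border
  m <- fx$pillar$intensity
  cut_px <- round(max(truth$pillars$x_um) / spec$pixel_size_um) + 1L
  pr <- pillarwrap:::new_projection2d(
    m[, 1:cut_px], "PILLAR", fx$pillar$z_range_um, spec$pixel_size_um
  )
  grid <- detect_pillars(pr, spec$pitch_um, spec$realized_diameter_um)
  expect_true(any(grid$border))
  expect_false(all(grid$border))
})

test_that("swelling factor reproduces the defining arithmetic", {
  expect_equal(swelling_factor(6.3, 5)$mean, 0.26)
  sf <- swelling_factor(c(5, 5, 5), 5)
  expect_equal(sf$mean, 0)
  expect_equal(sf$sd, 0)
  expect_identical(sf$n, 3L)
  expect_error(swelling_factor(numeric(0), 5),
    class = "pillarwrap_validation_error"
  )
  expect_error(swelling_factor(c(NA_real_), 5),
    class = "pillarwrap_validation_error"
  )
})

test_that("rendered swelling is recovered from measured diameters", {
  spec <- tiny_spec(rows = 4, cols = 4, s = 0.26, h = 6)
  truth <- simulate_field_truth(spec, coverage = 0, n_nuclei = 0, seed = 24)
  fx <- rendered_fixture(spec, truth, noise = noise_model(), seed = 24)
  grid <- detect_pillars(fx$pillar, spec$pitch_um, spec$realized_diameter_um)
  d <- grid$diameter_um[grid$present & !grid$border]
  sf <- swelling_factor(d, spec$mold_diameter_um)
  expect_equal(sf$mean, 0.26, tolerance = 0.02 / 0.26)
})

test_that("measure_diameter matches the rendered footprint", {
  spec <- tiny_spec(rows = 1, cols = 1, h = 4)
  truth <- simulate_field_truth(spec, coverage = 0, n_nuclei = 0, seed = 25)
  fx <- rendered_fixture(spec, truth)
  p <- truth$pillars
  md <- measure_diameter(fx$pillar, p$x_um, p$y_um)
  expect_equal(md$diameter_um, spec$realized_diameter_um,
    tolerance = spec$pixel_size_um / spec$realized_diameter_um
  )
  expect_false(md$border)
  expect_error(measure_diameter(fx$pillar, -5, -5),
    class = "pillarwrap_validation_error"
  )
})
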