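test_that("the spherical Hertz force matches direct evaluation", {
  # E = 1 kPa, nu = 0.5, R = 12.5 um, delta = 1 um
  f <- hertz_force(1e-6, 1000, 12.5e-6, 0.5)
  expect_equal(f, (4 / 3) * (1000 / 0.75) * sqrt(12.5e-6) * 1e-9,
    tolerance = 1e-12
  )
  expect_equal(f * 1e9, 6.29, tolerance = 1e-3)
  expect_equal(hertz_force(0, 1000, 12.5e-6), 0)
  expect_equal(hertz_force(-1e-6, 1000, 12.5e-6), 0)
})

test_that("simulated curves respect the self-consistent bending relation", {
  E <- 5000
  cur <- simulate_force_curve(E, k = 0.1, noise_sd = 0, seed = 1)
  z0 <- attr(cur, "true_contact_z")
  post <- cur$z_m > z0 & cur$force_n > 0
  delta <- (cur$z_m[post] - z0) - cur$force_n[post] / attr(cur, "k")
  expect_equal(cur$force_n[post], hertz_force(delta, E, 12.5e-6, 0.5),
    tolerance = 1e-9
  )
  # very stiff cantilever: negligible bending, delta ~ z - z0
  stiff <- simulate_force_curve(E, k = 1e4, noise_sd = 0, seed = 1)
  post <- stiff$z_m > z0
  delta_stiff <- (stiff$z_m[post] - z0) - stiff$force_n[post] / 1e4
  expect_lt(max(abs(delta_stiff - (stiff$z_m[post] - z0))), 1e-11)
})

test_that("contact point is recovered within two sample spacings", {
  cur <- simulate_force_curve(5000, k = 0.1, noise_sd = 0, seed = 2)
  prep <- preprocess_curve(cur)
  spacing <- diff(cur$z_m)[1]
  expect_lt(abs(prep$contact_z_m - attr(cur, "true_contact_z")), 2 * spacing)
})

test_that("bending correction subtracts F/k from the tip position", {
  # 6 nN on a 0.6 N/m cantilever bends it by 10 nm
  expect_equal(6e-9 / 0.6, 10e-9)
  cur <- simulate_force_curve(20000, k = 0.6, noise_sd = 0, seed = 3)
  prep <- preprocess_curve(cur)
  z0 <- prep$contact_z_m
  post <- cur$z_m > z0
  i <- which.min(abs(prep$data$force_n - 6e-9))
  gap <- (cur$z_m[post][i] - z0) - prep$data$delta_m[i]
  expect_equal(gap, prep$data$force_n[i] / 0.6, tolerance = 1e-3)
})

test_that("baseline-only curves raise a no-contact error", {
  z <- seq(0, 4e-6, length.out = 512)
  flat <- force_curve(z, rep(1e-11, 512), k = 0.1, bead_radius_m = 12.5e-6)
  expect_error(preprocess_curve(flat),
    class = "pillarwrap_computation_error"
  )
})

test_that("noiseless moduli across the stiffness ladder fit within 1%", {
  for (E in c(500, 5000, 20000, 55000)) {
    fit <- fit_force_curve(
      simulate_force_curve(E, k = 0.3, noise_sd = 0, seed = 4)
    )
    expect_equal(fit$E_pa, E, tolerance = 0.01)
  }
})

test_that("the fit is linear in force scale", {
  cur <- simulate_force_curve(5000, k = 0.3, noise_sd = 0, seed = 5)
  prep <- preprocess_curve(cur)
  fit1 <- fit_hertz(prep)
  prep2 <- prep
  prep2$data$force_n <- 2 * prep2$data$force_n
  fit2 <- fit_hertz(prep2)
  expect_equal(fit2$E_pa / fit1$E_pa, 2, tolerance = 1e-9)
})

test_that("insufficient indentation data aborts the fit", {
  cur <- simulate_force_curve(5000, k = 0.3, noise_sd = 0, seed = 6)
  prep <- preprocess_curve(cur)
  expect_error(fit_hertz(prep, delta_max_fit_m = 1e-10),
    class = "pillarwrap_computation_error"
  )
})

test_that("per-gel aggregation is the plain mean and sd", {
  ag <- aggregate_gel(rep(5100, 9))
  expect_equal(ag$mean_E_pa, 5100)
  expect_equal(ag$sd_E_pa, 0)
  ag2 <- aggregate_gel(c(4000, 5000, 6000))
  expect_equal(ag2$mean_E_pa, 5000)
  expect_equal(ag2$sd_E_pa, 1000)
  expect_error(aggregate_gel(numeric(0)), class = "pillarwrap_validation_error")
  df <- tibble::tibble(E_pa = c(1, 2, 3, 4), gel = c("a", "a", "b", "b"))
  ags <- aggregate_gels(df)
  expect_equal(ags$mean_E_pa, c(1.5, 3.5))
})

test_that("force curves round-trip through delimited text with constants", {
  cur <- simulate_force_curve(5000, k = 0.25, noise_sd = 1e-11, seed = 7)
  path <- withr::local_tempfile(fileext = ".txt")
  write_force_curve(cur, path)
  rt <- read_force_curve(path)
  expect_equal(attr(rt, "k"), 0.25)
  expect_equal(attr(rt, "bead_radius_m"), 12.5e-6)
  expect_equal(rt$force_n, cur$force_n, tolerance = 1e-6)
  rt2 <- read_force_curve(path, k = 0.5)
  expect_equal(attr(rt2, "k"), 0.5)
})

test_that("curve validation rejects malformed input", {
  z <- seq(0, 4e-6, length.out = 200)
  expect_error(force_curve(z, rep(0, 200), k = -1, bead_radius_m = 1e-5),
    class = "pillarwrap_validation_error"
  )
  expect_error(force_curve(rev(z), rep(0, 200), k = 0.1, bead_radius_m = 1e-5),
    class = "pillarwrap_validation_error"
  )
  expect_error(force_curve(z[1:50], rep(0, 50), k = 0.1, bead_radius_m = 1e-5),
    class = "pillarwrap_validation_error"
  )
  expect_error(simulate_force_curve(-5), class = "pillarwrap_validation_error")
})
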