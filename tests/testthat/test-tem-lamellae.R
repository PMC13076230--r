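test_that("layer counting matches construction on clean and noisy profiles", {
  p4 <- simulate_lamella_profile(4, 13, noise_sd = 0, seed = 1)
  expect_identical(count_layers(p4)$n_layers, 4L)
  p1 <- simulate_lamella_profile(1, 13, noise_sd = 0, seed = 1)
  expect_identical(count_layers(p1)$n_layers, 1L)
  p3 <- simulate_lamella_profile(3, 13, noise_sd = 0.05, seed = 2)
  expect_identical(count_layers(p3)$n_layers, 3L)
  flat <- lamella_profile(seq(0, 100, by = 1), rep(0.2, 101))
  got <- count_layers(flat)
  expect_identical(got$n_layers, 0L)
  expect_identical(got$flag, "no_myelin")
})

test_that("profile determinism and validation hold", {
  a <- simulate_lamella_profile(3, 13, noise_sd = 0.05, seed = 9)
  b <- simulate_lamella_profile(3, 13, noise_sd = 0.05, seed = 9)
  expect_identical(a$intensity, b$intensity)
  expect_error(simulate_lamella_profile(0, 13),
    class = "pillarwrap_validation_error"
  )
  expect_error(lamella_profile(c(1, 1, 2), c(0, 0, 0)),
    class = "pillarwrap_validation_error"
  )
})

test_that("band thickness equals layers times period on clean profiles", {
  p <- simulate_lamella_profile(4, 13, noise_sd = 0, seed = 1)
  tt <- total_thickness(p)
  expect_equal(tt$thickness_nm, 52, tolerance = 2 / 52)
  p1 <- simulate_lamella_profile(1, 13, noise_sd = 0, seed = 1)
  tt1 <- total_thickness(p1)
  expect_equal(tt1$thickness_nm, 13, tolerance = 2 / 13)
  flat <- lamella_profile(seq(0, 100, by = 1), rep(0, 101))
  expect_true(is.na(total_thickness(flat)$thickness_nm))
})

test_that("noisy 46-nm bands are measured within 3 nm over replicates", {
  est <- vapply(1:8, function(s) {
    p <- simulate_lamella_profile(4, 11.5, noise_sd = 0.04, seed = 100 + s)
    total_thickness(p)$thickness_nm
  }, numeric(1))
  expect_equal(mean(est), 46, tolerance = 3 / 46)
})

test_that("per-lamella thickness closes the definition exactly", {
  profiles <- lapply(2:5, function(n) {
    simulate_lamella_profile(n, 13, noise_sd = 0.02, seed = n)
  })
  m <- measure_lamellae(profiles)
  expect_equal(m$per_lamella_nm * m$n_layers, m$thickness_nm)
})

test_that("thickness-layer regression matches a normal-equations oracle", {
  df <- tibble::tibble(n_layers = 1:6, thickness_nm = 13 * (1:6))
  reg <- thickness_layer_regression(df)
  expect_equal(reg$slope_nm_per_layer, 13, tolerance = 1e-10)
  expect_equal(reg$intercept_nm, 0, tolerance = 1e-9)
  expect_equal(reg$r_squared, 1, tolerance = 1e-12)

  set.seed(51)
  x <- sample(2:6, 10, replace = TRUE)
  y <- 13 * x + stats::rnorm(10, 0, 4)
  reg2 <- thickness_layer_regression(
    tibble::tibble(n_layers = x, thickness_nm = y)
  )
  # brute-force normal equations
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(reg2$intercept_nm, beta[1], tolerance = 1e-10)
  expect_equal(reg2$slope_nm_per_layer, beta[2], tolerance = 1e-10)
  expect_equal(reg2$r_squared, r2, tolerance = 1e-10)

  expect_error(
    thickness_layer_regression(
      tibble::tibble(n_layers = c(3, 3, 3), thickness_nm = c(1, 2, 3))
    ),
    class = "pillarwrap_validation_error"
  )
})

test_that("rescaling radial units rescales thickness and slope only", {
  profiles <- lapply(2:5, function(n) {
    simulate_lamella_profile(n, 13, noise_sd = 0.02, seed = 10 + n)
  })
  m1 <- measure_lamellae(profiles)
  alpha <- 2.5
  scaled <- lapply(profiles, function(p) {
    sp <- lamella_profile(p$radius_nm * alpha, p$intensity)
    sp
  })
  m2 <- measure_lamellae(scaled, min_spacing_nm = 5 * alpha)
  expect_identical(m2$n_layers, m1$n_layers)
  expect_equal(m2$thickness_nm, m1$thickness_nm * alpha, tolerance = 1e-6)
  r1 <- glance(thickness_layer_regression(m1))
  r2 <- glance(thickness_layer_regression(m2))
  expect_equal(r2$slope_nm_per_layer, alpha * r1$slope_nm_per_layer,
    tolerance = 1e-6
  )
  expect_equal(r2$r_squared, r1$r_squared, tolerance = 1e-9)
})

test_that("multilayer percentages follow the per-field definition", {
  df <- tibble::tibble(
    field_id = rep(1, 120),
    n_layers = rep(c(1, 3), times = c(60, 60))
  )
  mf <- multilayer_fraction(df)
  expect_equal(mf$pct_multilayer, 50)
  all1 <- tibble::tibble(field_id = 1, n_layers = rep(1, 10))
  expect_equal(multilayer_fraction(all1)$pct_multilayer, 0)
  expect_error(multilayer_fraction(all1[0, ]),
    class = "pillarwrap_validation_error"
  )
})

test_that("binomially sampled multilayer cohorts recover the generation rate", {
  set.seed(52)
  fields <- tibble::tibble(
    field_id = rep(1:3, each = 120),
    n_layers = 1L + stats::rbinom(360, 1, 0.52) * sample(1:4, 360, TRUE)
  )
  mf <- multilayer_fraction(fields)
  expect_equal(mean(mf$pct_multilayer), 52, tolerance = 9 / 52)
})
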