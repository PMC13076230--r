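nuclei_projection <- function(n_nuclei, extent = 120, seed = 41, px = 0.3,
                              nuclei = NULL) {
  spec <- array_spec(5, 10, 6,
    rows = 1, cols = 1,
    pixel_size_um = px, z_step_um = 2
  )
  truth <- simulate_field_truth(spec,
    coverage = 0, n_nuclei = n_nuclei,
    margin_um = extent / 2, seed = seed
  )
  truth$pillars$present <- FALSE
  if (!is.null(nuclei)) truth$nuclei <- nuclei
  rf <- render_field(spec, truth, noise_model(), seed = seed)
  list(
    proj = max_project(rf$stack, "NUCLEI", 0, Inf),
    truth = rf$truth
  )
}

test_that("blank fields count zero nuclei with a flag", {
  pr <- pillarwrap:::new_projection2d(matrix(0, 40, 40), "NUCLEI", c(0, 20), 0.3)
  got <- count_nuclei(pr)
  expect_identical(got$n_cells, 0L)
  expect_identical(got$flag, "blank")
})

test_that("well-separated nuclei are counted exactly", {
  for (n in c(12L, 40L)) {
    fx <- nuclei_projection(n, seed = 41 + n)
    expect_identical(nrow(fx$truth$nuclei), n) # placement succeeded
    got <- count_nuclei(fx$proj)
    expect_identical(got$n_cells, n)
    expect_identical(got$flag, "ok")
  }
})

test_that("touching nuclei are split by the watershed", {
  # two somata whose centers are 1.7 radii apart (30% radial overlap)
  nuc <- tibble::tibble(
    x_um = c(28, 28 + 1.7 * 3.5), y_um = c(30, 30), z_um = c(2, 2)
  )
  fx <- nuclei_projection(0, extent = 60, nuclei = nuc, seed = 43)
  got <- count_nuclei(fx$proj)
  expect_identical(got$n_cells, 2L)
})

test_that("field summaries reproduce counts, percentages and per-cell rates", {
  m <- tibble::tibble(
    pillar_id = 1:4,
    coverage = c(1, 1, 0, 0.2),
    max_gap_deg = c(0, 0, 360, 300),
    score = c(3L, 3L, 0L, 1L),
    thickness_um = c(0.6, 0.7, NA, 0.5),
    g_ratio = c(0.8, 0.8, NA, 0.85),
    flagged = FALSE, resolution_limited = FALSE
  )
  s <- summarize_field(m, n_cells = 2)
  expect_identical(s$n_pillars, 4L)
  expect_equal(
    c(s$pct_score0, s$pct_score1, s$pct_score2, s$pct_score3),
    c(25, 25, 0, 50)
  )
  expect_equal(s$score3_per_cell, 1.0)
  expect_equal(s$pillar_to_cell_ratio, 2.0)
  expect_equal(
    s$pct_score0 + s$pct_score1 + s$pct_score2 + s$pct_score3, 100
  )

  all3 <- tibble::tibble(
    pillar_id = 1:30, coverage = 1, max_gap_deg = 0, score = 3L,
    thickness_um = 0.6, g_ratio = 0.8, flagged = FALSE,
    resolution_limited = FALSE
  )
  expect_equal(summarize_field(all3, n_cells = 10)$score3_per_cell, 3.0)
})

test_that("zero-cell fields keep counts but flag per-cell metrics", {
  m <- tibble::tibble(
    pillar_id = 1:2, coverage = c(1, 0), max_gap_deg = c(0, 360),
    score = c(3L, 0L), thickness_um = c(0.6, NA), g_ratio = c(0.8, NA),
    flagged = FALSE, resolution_limited = FALSE
  )
  s <- summarize_field(m, n_cells = 0)
  expect_identical(s$n_score3, 2L - 1L)
  expect_true(is.na(s$score3_per_cell))
  expect_false(s$per_cell_defined)
})

test_that("flagged pillars are excluded from denominators but reported", {
  m <- tibble::tibble(
    pillar_id = 1:3, coverage = c(1, 1, NA), max_gap_deg = c(0, 0, NA),
    score = c(3L, 3L, NA), thickness_um = 0.6, g_ratio = 0.8,
    flagged = c(FALSE, FALSE, TRUE), resolution_limited = FALSE
  )
  s <- summarize_field(m, n_cells = 2)
  expect_identical(s$n_pillars, 2L)
  expect_identical(s$n_flagged, 1L)
  expect_equal(s$pct_score3, 100)
})

test_that("fold change divides by the reference mean", {
  expect_equal(fold_change(2, 1), 2)
  expect_equal(fold_change(1.5, 1.5), 1)
  expect_equal(fold_change(c(2, 4), c(1, 3)), c(1, 2))
  expect_error(fold_change(1, 0), class = "pillarwrap_validation_error")
  expect_error(fold_change(1, -2), class = "pillarwrap_validation_error")
})

test_that("group comparison detects large shifts and rejects degenerate input", {
  set.seed(44)
  df <- tibble::tibble(
    condition = rep(c("a", "b", "c"), each = 6),
    value = stats::rnorm(18) + rep(c(0, 5, 0), each = 6)
  )
  cmp <- compare_groups(df, "value", "condition")
  expect_lt(glance(cmp)$p_value, 1e-3)
  tk <- tidy(cmp)
  expect_identical(nrow(tk), 3L)
  expect_lt(tk$p_adj[tk$contrast == "b-a"], 1e-3)

  one <- df[df$condition == "a", ]
  expect_error(compare_groups(one, "value", "condition"),
    class = "pillarwrap_validation_error"
  )
  flat <- tibble::tibble(condition = rep(c("a", "b"), each = 3), value = 1)
  expect_error(compare_groups(flat, "value", "condition"),
    class = "pillarwrap_validation_error"
  )
})
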