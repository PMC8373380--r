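test_that("glucose titration matches brute-force enumeration of the series", {
  # frozen oracle_titration(1, 0.0039, 2): nine twofold steps
  expect_equal(
    glucose_titration(),
    c(1, 0.5, 0.25, 0.125, 0.0625, 0.03125, 0.015625, 0.0078125, 0.00390625)
  )
  expect_equal(glucose_titration(1, 1, 2), 1)
  # frozen: oracle gives 7 concentrations from 0.25 down past 0.0039
  expect_length(glucose_titration(0.25, 0.0039, 2), 7)
  for (args in list(c(1, 0.0039, 2), c(0.25, 0.0039, 2), c(2, 0.01, 3))) {
    expect_equal(
      glucose_titration(args[1], args[2], args[3]),
      oracle_titration(args[1], args[2], args[3])
    )
  }
  expect_error(glucose_titration(factor = 1), "factor")
  expect_error(glucose_titration(0.001, 1), "bottom")
  expect_error(glucose_titration(-1, -2), "top")
})

test_that("population sampling is seed-reproducible and conserves counts", {
  m <- gal_model(0.0625, 0.0625)
  s1 <- simulate_population(m, 0.0625, n_cells = 5000, seed = 42)
  s2 <- simulate_population(m, 0.0625, n_cells = 5000, seed = 42)
  expect_identical(s1$log_expression, s2$log_expression)
  expect_equal(nrow(s1), 5000)
  # induced + uninduced counts partition the population exactly, with the
  # induced count given by round-half-up of f * n
  f <- attr(s1, "true_fraction")
  expect_equal(sum(s1$induced), floor(f * 5000 + 0.5))
  expect_equal(sum(s1$induced) + sum(!s1$induced), 5000)
  expect_equal(mean(s1$induced), floor(f * 5000 + 0.5) / 5000)
  expect_error(simulate_population(m, 0.1, n_cells = 0), "n_cells")
  expect_error(simulate_population(m, -1), "glucose")
})

test_that("uninduced subpopulation sits at a relative expression of 1e-3", {
  m <- gal_model(0.0625, 0.0625)
  s <- simulate_population(m, 2, n_cells = 20000, seed = 7, induced_fraction = 0)
  geo_mean_log <- mean(s$log_expression)
  # sd 0.0875 over 20000 cells: 3 standard errors is about 0.002
  expect_lt(abs(geo_mean_log - (-3)), 0.01)
})

test_that("fully induced sample at zero glucose averages the curve maximum", {
  m <- gal_model(0.0625, 0.0625)
  s <- simulate_population(m, 0, n_cells = 20000, seed = 8, induced_fraction = 1)
  se <- 0.0875 / sqrt(20000)
  expect_lt(abs(mean(s$log_expression) - (-0.5)), 3 * se)
})

test_that("induced-cell mean converges to the model level at large n", {
  m <- gal_model(0.0625, 0.0625)
  g <- 0.03125
  s <- simulate_population(m, g, n_cells = 200000, seed = 11)
  lvl <- mean_induced_log_level(g, m)
  x <- s$log_expression[s$induced]
  se <- sd_of_log_level(lvl, m) / sqrt(length(x))
  expect_lt(abs(mean(x) - lvl), 3 * se)
})

test_that("profiles cover the titration with references and derived seeds", {
  m <- gal_model(0.0625, 0.0625)
  prof <- simulate_profile(m, n_cells = 500, seed = 3)
  expect_s3_class(prof, "induction_profile")
  expect_equal(nrow(prof$conditions), 9)
  expect_equal(sort(prof$conditions$glucose), sort(glucose_titration()))
  expect_equal(nrow(prof$cells), 9 * 500)
  expect_equal(attr(prof$uninduced_ref, "true_fraction"), 0)
  expect_equal(attr(prof$max_induction_ref, "true_fraction"), 1)
  prof1 <- simulate_profile(m, glucose = 0.1, n_cells = 500, seed = 3)
  expect_equal(nrow(prof1$conditions), 1)
  prof2 <- simulate_profile(m, n_cells = 500, seed = 3)
  expect_identical(prof$cells, prof2$cells)
  expect_identical(
    prof$uninduced_ref$log_expression,
    prof2$uninduced_ref$log_expression
  )
  expect_error(simulate_profile(m, glucose = numeric(0)), "non-empty")
})

test_that("profiles round-trip through event-table directories", {
  m <- gal_model(0.03, 0.2, n_frac = 2.2)
  prof <- simulate_profile(m, n_cells = 300, seed = 5)
  dir <- withr::local_tempdir()
  write_profile(prof, dir)
  back <- read_profile(dir)
  expect_equal(back$cells, prof$cells)
  expect_equal(back$conditions, prof$conditions)
  expect_equal(
    back$uninduced_ref$log_expression,
    prof$uninduced_ref$log_expression
  )
  expect_equal(unclass(back$model), unclass(m))
  expect_identical(back$replicate_id, prof$replicate_id)
})

test_that("a half-induced, well-separated condition is classified bimodal", {
  # fraction midpoint: glucose = alpha * F90; level stays high when E10 is
  # far above that point
  m <- gal_model(1, 0.01)
  g_mid <- hill_alpha(m$n_frac) * m$F90
  s <- simulate_population(m, g_mid, n_cells = 20000, seed = 21)
  expect_equal(attr(s, "true_fraction"), 0.5, tolerance = 1e-12)
  call <- classify_condition(s)
  expect_identical(call$status, "ok")
  expect_true(call$is_bimodal)
})
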