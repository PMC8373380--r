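test_that("a clean single Gaussian passes the adjusted R-squared gate", {
  x <- withr::with_seed(1, rnorm(20000, -1.5, 0.3))
  f1 <- fit_gaussians(x, 1)
  expect_true(f1$converged)
  expect_gte(f1$adj_r2, 0.99)
  call <- classify_condition(x)
  expect_identical(call$status, "ok")
  expect_false(call$is_bimodal)
})

test_that("a separated 50/50 mixture fails k=1 and is recovered by k=2", {
  x <- withr::with_seed(2, c(rnorm(10000, -3, 0.2), rnorm(10000, -0.5, 0.2)))
  f1 <- fit_gaussians(x, 1)
  expect_lt(f1$adj_r2, 0.99)
  f2 <- fit_gaussians(x, 2)
  expect_true(f2$converged)
  ord <- order(f2$means)
  expect_equal(f2$means[ord], c(-3, -0.5), tolerance = 0.1)
  expect_equal(f2$weights[ord], c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sum(f2$weights), 1, tolerance = 1e-9)
  expect_true(classify_condition(x)$is_bimodal)
})

test_that("the stated criteria decide the two-component branch", {
  # minor weight below 0.15, well separated: not bimodal
  x_w <- make_mixture(20000, sep = 6, w = 0.10, seed = 31)
  call_w <- classify_condition(x_w)
  expect_false(call_w$is_bimodal)
  # separation below twice the larger sd: not bimodal
  x_s <- make_mixture(20000, sep = 1.5, w = 0.5, seed = 32)
  call_s <- classify_condition(x_s)
  expect_false(call_s$is_bimodal)
  # both criteria clearly satisfied
  x_b <- make_mixture(20000, sep = 4, w = 0.5, seed = 33)
  call_b <- classify_condition(x_b)
  expect_true(call_b$is_bimodal)
  expect_gt(call_b$separation, 2 * call_b$max_sd)
  expect_gt(call_b$minor_fraction, 0.15)
})

test_that("bimodality criteria are symmetric under component relabelling", {
  x <- make_mixture(20000, sep = 4, w = 0.3, seed = 41)
  fit <- fit_gaussians(x, 2)
  swapped <- fit
  swapped$means <- rev(fit$means)
  swapped$sds <- rev(fit$sds)
  swapped$weights <- rev(fit$weights)
  swapped$amplitudes <- rev(fit$amplitudes)
  expect_identical(
    bimodality_criteria(fit)$is_bimodal,
    bimodality_criteria(swapped)$is_bimodal
  )
  # mirroring the data flips the sign of every mean but not the call
  expect_identical(
    classify_condition(x)$is_bimodal,
    classify_condition(-x)$is_bimodal
  )
})

test_that("raising either threshold can only retract bimodal calls", {
  xs <- lapply(1:6, function(i) {
    make_mixture(20000, sep = c(1.5, 2.5, 3, 4, 5, 2.2)[i],
                 w = c(0.5, 0.12, 0.2, 0.35, 0.16, 0.5)[i], seed = 50 + i)
  })
  for (x in xs) {
    calls_sep <- sapply(c(1.5, 2, 3, 4), function(sm) {
      isTRUE(classify_condition(x, sep_mult = sm)$is_bimodal)
    })
    expect_true(all(diff(as.integer(calls_sep)) <= 0))
    calls_w <- sapply(c(0.05, 0.15, 0.3, 0.45), function(mf) {
      isTRUE(classify_condition(x, min_fraction = mf)$is_bimodal)
    })
    expect_true(all(diff(as.integer(calls_w)) <= 0))
  }
})

test_that("degenerate and invalid inputs fail loudly", {
  expect_error(fit_gaussians(rep(-2, 500), 1), "zero variance")
  expect_error(fit_gaussians(rnorm(50), 1), "at least 100")
  expect_error(fit_gaussians(rnorm(500), 3), "must be 1 or 2")
  expect_error(fit_gaussians(data.frame(x = rnorm(500)), 1), "log_expression")
  call <- classify_condition(rep(-2, 500))
  expect_identical(call$status, "unclassifiable")
  expect_true(is.na(call$is_bimodal))
})

test_that("profile calls flag bimodality from a single condition", {
  m_uni <- gal_model(0.002, 0.5) # level shuts off long before the fraction
  m_bi <- gal_model(0.5, 0.01) # fraction transitions while level is high
  prof_uni <- simulate_profile(m_uni, n_cells = 20000, seed = 61)
  prof_bi <- simulate_profile(m_bi, n_cells = 20000, seed = 62)
  call_uni <- classify_profile(prof_uni)
  call_bi <- classify_profile(prof_bi)
  expect_false(call_uni$profile_is_bimodal)
  expect_true(call_bi$profile_is_bimodal)
  expect_equal(nrow(call_uni$per_condition), 9)
  expect_identical(glance(call_bi)$status, "ok")
  expect_gte(glance(call_bi)$n_bimodal, 1)

  # replicate aggregation: bimodal only when every replicate is bimodal
  expect_identical(aggregate_modality(list(call_bi, call_bi)), "bimodal")
  expect_identical(aggregate_modality(list(call_bi, call_uni)), "unimodal")
  expect_identical(aggregate_modality(list(call_uni)), "unimodal")
  expect_error(aggregate_modality(list()), "at least one")
})

test_that("tidy and glance expose fit and call tables", {
  x <- make_mixture(20000, sep = 4, w = 0.4, seed = 71)
  fit <- fit_gaussians(x, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_named(td, c("component", "mean", "sd", "weight", "amplitude"))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_true(gl$converged)
})
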