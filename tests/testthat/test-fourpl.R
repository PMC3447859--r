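test_that("noise-free 4PL parameters are recovered to 1e-3 relative", {
  truth <- fourpl(bottom = 0, top = 1000, ec50 = 1.24, hill = -1.5)
  d <- generate_dose_response(truth, doses = c(0, 0.1, 0.3, 1, 3, 10, 15),
                              cv = 0, n_reps = 3)
  fit <- fit_4pl(d, dose_uM, count)
  expect_true(fit$converged)
  expect_lt(abs(fit$bottom - 0), 1e-3 * 1000)  # bottom on the response scale
  expect_lt(abs(fit$top - 1000) / 1000, 1e-3)
  expect_lt(abs(fit$ec50 - 1.24) / 1.24, 1e-3)
  expect_lt(abs(fit$hill - (-1.5)) / 1.5, 1e-3)
})

test_that("4PL recovery holds across random parameter draws (noise-free)", {
  withr::with_seed(101, {
    for (i in 1:100) {
      bottom <- runif(1, 0, 100)
      top <- bottom + runif(1, 200, 2000)
      ec50 <- 10^runif(1, -1, 1)
      hill <- -runif(1, 0.5, 3)
      truth <- fourpl(bottom, top, ec50, hill)
      doses <- c(0, 10^seq(-2, 1.5, length.out = 7))
      d <- generate_dose_response(truth, doses, cv = 0, n_reps = 1, seed = i)
      fit <- fit_4pl(d, dose_uM, count)
      scale <- top - bottom
      expect_lt(abs(fit$bottom - bottom) / scale, 1e-3)
      expect_lt(abs(fit$top - top) / scale, 1e-3)
      expect_lt(abs(fit$ec50 - ec50) / ec50, 1e-3)
      expect_lt(abs(fit$hill - hill) / abs(hill), 1e-3)
    }
  })
})

test_that("degenerate designs fail loudly, never silently", {
  flat <- tibble::tibble(dose = c(0, 1, 3, 10), y = rep(500, 4))
  expect_error(fit_4pl(flat, dose, y), class = "ihcquant_fit_error")

  few <- tibble::tibble(dose = c(0, 1, 1), y = c(10, 5, 6))
  expect_error(fit_4pl(few, dose, y), class = "ihcquant_fit_error")

  no_control <- tibble::tibble(dose = c(0.1, 1, 3, 10), y = c(9, 7, 4, 1))
  expect_error(fit_4pl(no_control, dose, y), class = "ihcquant_fit_error")

  # two-level step: boundary flag (unbounded hill), not a quiet wrong answer
  step <- tibble::tibble(dose = c(0, 0.5, 1, 2, 4, 8),
                         y = c(1000, 1000, 1000, 0, 0, 0))
  res <- tryCatch(
    withCallingHandlers(
      fit_4pl(step, dose, y),
      ihcquant_boundary_fit = function(w) invokeRestart("muffleWarning")
    ),
    error = function(e) e
  )
  if (!inherits(res, "error")) expect_false(res$converged)
})

test_that("canonicalization leaves the curve unchanged and orients top >= bottom", {
  # ascending curve: generator hill > 0 maps dose 0 to bottom
  truth <- fourpl(bottom = 10, top = 800, ec50 = 2, hill = 1.2)
  doses <- c(0, 0.2, 0.5, 1, 2, 5, 10, 30)
  d <- tibble::tibble(dose = doses, y = predict(truth, doses))
  fit <- fit_4pl(d, dose, y)
  expect_gte(fit$top, fit$bottom)
  expect_equal(predict(fit, doses), d$y, tolerance = 1e-6)
})

test_that("gi50 equals ec50 when bottom = 0 and top = control", {
  for (hill in c(-0.7, -1, -2.3)) {
    p <- fourpl(bottom = 0, top = 400, ec50 = 2.5, hill = hill)
    expect_equal(gi50(p, control_mean = 400), 2.5, tolerance = 1e-12)
  }
})

test_that("gi50 fails when the curve never reaches half the control", {
  p <- fourpl(bottom = 0.6 * 400, top = 400, ec50 = 1, hill = -1)
  expect_error(gi50(p, control_mean = 400), class = "ihcquant_gi50_error")
  expect_error(gi50(p, control_mean = 400), "GI50 not reached")
})

test_that("gi50 inversion round-trips through the forward curve to 1e-9", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- fourpl(bottom = runif(1, 0, 50), top = runif(1, 500, 1500),
                  ec50 = 10^runif(1, -1, 1), hill = -runif(1, 0.5, 3))
      control <- p$top * runif(1, 0.9, 1)
      g <- tryCatch(gi50(p, control), error = function(e) NULL)
      if (!is.null(g)) {
        expect_lt(abs(predict(p, g) - control / 2) / (control / 2), 1e-9)
      }
    }
  })
})

test_that("GI50 median relative bias stays within 10% under assay-level noise", {
  true_gi50 <- 1.24
  truth <- fourpl(bottom = 0, top = 1000, ec50 = true_gi50, hill = -1.5)
  doses <- c(0, 0.1, 0.3, 1, 3, 10, 15)
  bias <- vapply(1:50, function(i) {
    d <- generate_dose_response(truth, doses, cv = 0.1, n_reps = 3, seed = 1000 + i)
    fit <- suppressWarnings(fit_4pl(d, dose_uM, count))
    g <- gi50(fit, mean(d$count[d$dose_uM == 0]))
    abs(g - true_gi50) / true_gi50
  }, numeric(1))
  expect_lte(median(bias), 0.10)
})

test_that("fourpl_fit methods expose tidy parameter and fit summaries", {
  d <- generate_dose_response(fourpl(0, 1000, 1.24, -1.5),
                              doses = c(0, 0.1, 0.3, 1, 3, 10, 15),
                              cv = 0, n_reps = 2)
  fit <- fit_4pl(d, dose_uM, count)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("bottom", "top", "ec50", "hill"))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(d))
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
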