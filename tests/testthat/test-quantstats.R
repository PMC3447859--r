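test_that("tumor volume follows the caliper formula with canonicalized radii", {
  expect_equal(tumor_volume(1.8, 1.8), 4 / 3 * pi * 1.8^3)
  expect_equal(tumor_volume(1, 2), 8 * pi / 3)
  expect_warning(v <- tumor_volume(2, 1), class = "ihcquant_canonicalized")
  expect_equal(v, tumor_volume(1, 2))
  expect_error(tumor_volume(0, 1), class = "ihcquant_bad_input")
  expect_error(tumor_volume(1, -2), class = "ihcquant_bad_input")
})

test_that("tumor volume grows in each radius and scales cubically", {
  withr::with_seed(3, {
    r1 <- runif(20, 0.5, 3); r2 <- r1 + runif(20, 0.15, 2); k <- runif(20, 0.5, 4)
    expect_true(all(tumor_volume(r1 + 0.1, r2) > tumor_volume(r1, r2)))
    expect_true(all(tumor_volume(r1, r2 + 0.1) > tumor_volume(r1, r2)))
    expect_equal(tumor_volume(k * r1, k * r2), k^3 * tumor_volume(r1, r2))
  })
})

test_that("percent cytotoxicity is the released-over-total percentage", {
  expect_equal(percent_cytotoxicity(1.8, 1.8), 100)
  expect_equal(percent_cytotoxicity(0, 1.8), 0)
  expect_equal(percent_cytotoxicity(0.15, 1), 15)
  expect_error(percent_cytotoxicity(0.1, 0), class = "ihcquant_bad_input")
  expect_error(percent_cytotoxicity(-0.1, 1), class = "ihcquant_bad_input")
  # linear in the numerator
  withr::with_seed(4, {
    rel <- runif(10); tot <- runif(10, 1, 2); k <- runif(1, 0.1, 3)
    expect_equal(percent_cytotoxicity(k * rel, tot),
                 k * percent_cytotoxicity(rel, tot))
  })
})

test_that("percent inhibition and percent of control behave as defined", {
  expect_equal(percent_inhibition(25, 25), 0)
  expect_equal(percent_inhibition(0, 25), 100)
  expect_equal(percent_inhibition(0.64 * 25, 25), 36)
  expect_lt(percent_inhibition(30, 25), 0)  # stimulation is negative
  expect_error(percent_inhibition(1, 0), class = "ihcquant_bad_input")

  expect_equal(percent_of_control(5, 5), 100)
  expect_equal(percent_of_control(2.1, 1), 210)
  expect_equal(percent_of_control(0, 5), 0)
  expect_error(percent_of_control(1, -1), class = "ihcquant_bad_input")
  withr::with_seed(5, {
    v <- runif(10); ctrl <- runif(10, 0.5, 2); k <- runif(1, 0.1, 3)
    expect_equal(percent_of_control(k * v, ctrl), k * percent_of_control(v, ctrl))
  })
})

test_that("significance stars follow the conventional thresholds", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.04, 0.05, 0.2)),
               c("***", "**", "*", "ns", "ns"))
})

test_that("pooled t-test matches hand computation and edge conventions", {
  res <- ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t_statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)
  expect_equal(res$stars, "ns")

  same <- ttest_unpaired(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")

  expect_error(ttest_unpaired(1, c(1, 2)), class = "ihcquant_bad_input")
})

test_that("t-test is symmetric under group swap", {
  withr::with_seed(11, {
    a <- rnorm(6); b <- rnorm(6, 1)
    r1 <- ttest_unpaired(a, b); r2 <- ttest_unpaired(b, a)
    expect_equal(r1$t_statistic, -r2$t_statistic)
    expect_equal(r1$p_value, r2$p_value)
  })
})

test_that("pooled t-test agrees with the exact permutation oracle on n = 5 vs 5", {
  withr::with_seed(21, {
    for (i in 1:5) {
      a <- rnorm(5); b <- rnorm(5, 1.2)
      p_t <- ttest_unpaired(a, b)$p_value
      p_perm <- permutation_p(a, b)
      expect_lt(abs(p_t - p_perm), 0.05)
    }
  })
})

test_that("group summaries compute textbook mean/SD/SEM", {
  d <- tibble::tibble(g = rep(c("control", "treated"), each = 2),
                      y = c(0.2, 0.3, 0.1, 0.2))
  s <- summarize_groups(d, y, g)
  ctrl <- s[s$group == "control", ]
  expect_equal(ctrl$mean, 0.25)
  expect_equal(ctrl$sd, 0.07071068, tolerance = 1e-6)
  expect_equal(ctrl$sem, 0.05)
})

test_that("growth curve summary handles spheres, single timepoints and bad tables", {
  sphere <- tidyr::expand_grid(group = c("control", "treated"),
                               mouse = 1:2, day = c(0, 7)) |>
    dplyr::mutate(R1_mm = 1.8, R2_mm = 1.8)
  g <- growth_curve_summary(sphere)
  expect_equal(unique(g$series$mean_volume_mm3), 4 / 3 * pi * 1.8^3)
  expect_equal(unique(g$series$sem), 0)
  expect_equal(g$endpoint$percent_inhibition, 0)
  expect_equal(g$endpoint$p_value, 1)

  single <- dplyr::filter(sphere, day == 0)
  g1 <- growth_curve_summary(single)
  expect_equal(nrow(g1$series), 2)  # one day per group
  expect_equal(g1$endpoint$day, 0)

  expect_error(growth_curve_summary(dplyr::filter(sphere, group == "treated")),
               class = "ihcquant_bad_input")
  expect_error(growth_curve_summary(sphere[, -1]), class = "ihcquant_bad_input")
})

test_that("growth summary methods and plots work end to end", {
  tab <- generate_tumor_series("tumor-fig3a", n_mice_per_group = 5,
                               n_timepoints = 4, seed = 2)
  g <- growth_curve_summary(tab)
  expect_named(glance(g), c("control", "treated", "n_control", "n_treated",
                            "control_mean", "treated_mean", "percent_change",
                            "percent_inhibition", "t_statistic", "df",
                            "p_value", "stars", "day"))
  expect_s3_class(tidy(g), "tbl_df")
  expect_s3_class(autoplot(g), "ggplot")
})
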