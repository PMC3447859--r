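test_that("flat-field correction is identity for a constant field and inverts shading", {
  scene <- generate_ihc_field(synth_ihc_config(width = 64, height = 64,
                                               target_fraction = 0.1, seed = 1,
                                               illum_gradient = 1))$field
  flat <- flat_color_field(c(0.5, 0.5, 0.5))
  out <- flatfield_correct(scene, flat)
  expect_equal(out$pixels, scene$pixels, tolerance = 1e-12)

  # scene proportional to the flat-field collapses to a constant per channel
  ff <- generate_flatfield(64, 64, 1.8, seed = 2)
  k <- 0.6
  scaled <- rgb_field(k * ff$pixels)
  corr <- flatfield_correct(scaled, ff)
  for (ch in 1:3) {
    plane <- corr$pixels[, , ch]
    expect_lt(diff(range(plane)), 1e-9)
    expect_equal(mean(plane), k * mean(ff$pixels[, , ch]), tolerance = 1e-9)
  }

  # per-channel spatial mean preserved within 1% when nothing clips
  shaded <- rgb_field(scene$pixels * as.vector(ff$pixels[, , 1]) * 0.9)
  corr2 <- flatfield_correct(shaded, ff)
  for (ch in 1:3) {
    expect_lt(abs(mean(corr2$pixels[, , ch]) - mean(shaded$pixels[, , ch])) /
                mean(shaded$pixels[, , ch]), 0.01)
  }

  small <- flat_color_field(c(0.5, 0.5, 0.5), h = 32, w = 32)
  expect_error(flatfield_correct(scene, small), class = "ihcquant_bad_input")
  zero <- flat_color_field(c(0, 0.5, 0.5))
  expect_error(flatfield_correct(scene, zero), class = "ihcquant_bad_input")
})

test_that("hue-sector suppression desaturates only off-sector color", {
  cfg <- segmentation_config()
  dab <- flat_color_field(c(0.42, 0.28, 0.14))
  hema <- flat_color_field(c(0.35, 0.35, 0.65))
  gray <- flat_color_field(c(0.7, 0.7, 0.7))
  green <- flat_color_field(c(0.2, 0.8, 0.3))

  expect_equal(suppress_nonspecific(dab, cfg)$pixels, dab$pixels, tolerance = 1e-12)
  expect_equal(suppress_nonspecific(hema, cfg)$pixels, hema$pixels, tolerance = 1e-12)
  expect_equal(suppress_nonspecific(gray, cfg)$pixels, gray$pixels, tolerance = 1e-12)

  # off-sector saturated pixel, scale 0: replaced by its brightness (HSV V)
  out <- suppress_nonspecific(green, cfg)
  expect_equal(as.vector(out$pixels[1, 1, ]), c(0.8, 0.8, 0.8), tolerance = 1e-12)

  # scale 1 is the identity for any hue
  cfg1 <- segmentation_config(offsector_saturation_scale = 1)
  expect_equal(suppress_nonspecific(green, cfg1)$pixels, green$pixels)

  # idempotence at scale 0
  noisy <- generate_ihc_field(synth_ihc_config(width = 64, height = 64,
                                               target_fraction = 0.15, seed = 3))$field
  once <- suppress_nonspecific(noisy, cfg)
  twice <- suppress_nonspecific(once, cfg)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-12)

  expect_error(segmentation_config(hue_sectors = list(a = c(10, 50), b = c(40, 90))),
               "overlap")
  expect_error(segmentation_config(hue_sectors = list(a = c(50, 10), b = c(200, 260))),
               class = "ihcquant_bad_input")
})

test_that("stain contrast is the alpha-weighted red/blue difference", {
  f <- flat_color_field(c(0.6, 0.3, 0.2))
  expect_equal(stain_contrast(f, 1), f$pixels[, , 1])
  expect_equal(stain_contrast(f, 0), -f$pixels[, , 3])
  expect_equal(stain_contrast(f, 0.5)[1, 1], 0.2)
  expect_error(stain_contrast(f, 1.2), class = "ihcquant_bad_input")
})

test_that("band-pass removes DC and matches the Gaussian transfer oracle", {
  expect_equal(max(abs(bandpass(matrix(0.7, 256, 256), 2, 80))), 0)

  measure_gain <- function(period) {
    w <- max(256, 2 * period)
    x <- matrix(sin(2 * pi * (1:w) / period), nrow = 256, ncol = w, byrow = TRUE)
    (max(bandpass(x, 2, 80)) - min(bandpass(x, 2, 80))) / 2
  }
  # pass-band period retains >= 70% amplitude; check against the DoG transfer
  g32 <- measure_gain(32)
  expect_gte(g32, 0.7)
  expect_lt(abs(g32 - dog_gain(32, 2, 80)), 0.03)
  # very long period (4x the large structure size) is strongly attenuated
  g320 <- measure_gain(320)
  expect_lt(abs(g320 - dog_gain(320, 2, 80)), 0.03)
  expect_lt(g320, 0.3)

  expect_error(bandpass(matrix(0, 64, 64), 2, 2), class = "ihcquant_bad_input")
  expect_error(bandpass(matrix(0, 64, 64), 5, 2), class = "ihcquant_bad_input")
})

test_that("isodata threshold matches hand-iterated spike histograms", {
  expect_equal(isodata_threshold(c(rep(50, 100), rep(200, 100))), 125L)
  expect_equal(isodata_threshold(c(rep(0, 100), rep(255, 100))), 127L)
  expect_error(isodata_threshold(rep(3, 10)), class = "ihcquant_degenerate_field")
})

test_that("isodata threshold equals the exhaustive fixed-point oracle", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n_levels <- sample(2:40, 1)
      levels <- sample(0:255, n_levels)
      counts <- integer(256)
      counts[levels + 1] <- rpois(n_levels, 50) + 1
      x <- rep(0:255, counts)
      t_iter <- isodata_threshold(x)
      fp <- isodata_fixed_points(counts)
      expect_true(t_iter %in% fp)
      expect_true(any(x <= t_iter) && any(x > t_iter))
    }
  })
})

test_that("adaptive alpha favors the red axis when only red carries signal", {
  px <- array(0, dim = c(128, 128, 3))
  px[, , 1] <- 0.3; px[, , 2] <- 0.4; px[, , 3] <- 0.3
  r <- px[, , 1]; r[40:70, 50:90] <- 0.8; px[, , 1] <- r
  p <- suppressWarnings(optimize_alpha(rgb_field(px)))
  expect_gte(p$alpha, 0.8)
})

test_that("adaptive alpha rejects fields without red/blue contrast", {
  withr::with_seed(6, {
    px <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
    px[, , 3] <- px[, , 1]
  })
  expect_error(optimize_alpha(rgb_field(px)), class = "ihcquant_degenerate_field")
})

test_that("the selected alpha scores at least 95% of the best raw grid metric", {
  for (seed in c(1, 4, 9)) {
    f <- generate_ihc_field(synth_ihc_config(width = 256, height = 256,
                                             target_fraction = 0.2, seed = seed))
    supp <- suppress_nonspecific(f$field)
    p <- suppressWarnings(optimize_alpha(supp))
    m_star <- p$metric_curve$metric[p$metric_curve$alpha == p$alpha]
    expect_gte(m_star, 0.95 * max(p$metric_curve$metric))
  }
})

test_that("artifact rejection keeps DAB-like objects and drops the rest", {
  f <- flat_color_field(c(0.92, 0.90, 0.90), h = 64, w = 64)
  f <- with_patch(f, c(0.42, 0.28, 0.14), 5:20, 5:20)      # DAB: ratio 3
  f <- with_patch(f, c(0.35, 0.35, 0.65), 30:45, 30:45)    # hematoxylin: 0.54
  f <- with_patch(f, c(0.46, 0.4, 0.4), 50:62, 5:30)       # near-boundary
  mask <- matrix(FALSE, 64, 64)
  mask[5:20, 5:20] <- TRUE; mask[30:45, 30:45] <- TRUE; mask[50:62, 5:30] <- TRUE
  labels <- ihcquant:::label_mask(mask)
  # probe pass to obtain the exact ratio the filter computes for object 3,
  # then set the cutoff to that value: mean_R = tau * mean_B exactly
  probe <- remove_artifacts(mask, labels, f, segmentation_config())
  ratios <- probe$object_stats$red_blue_ratio
  tau <- ratios[which.min(abs(ratios - 1.15))]
  cfg <- segmentation_config(artifact_ratio_cutoff = tau)
  res <- remove_artifacts(mask, labels, f, cfg)
  expect_equal(res$object_count, 2L)          # DAB + boundary-exact kept
  expect_equal(res$rejected_object_count, 1L) # hematoxylin dropped
  kept <- res$object_stats[res$object_stats$kept, ]
  expect_true(all(kept$red_blue_ratio >= tau))
  expect_true(any(abs(kept$red_blue_ratio - tau) < 1e-9))  # boundary inclusive

  # tiny objects fall to the area cutoff
  small_mask <- matrix(FALSE, 64, 64); small_mask[1:3, 1:3] <- TRUE
  res2 <- remove_artifacts(small_mask, ihcquant:::label_mask(small_mask), f, cfg)
  expect_equal(res2$object_count, 0L)

  # empty mask allowed
  res3 <- remove_artifacts(matrix(FALSE, 64, 64),
                           matrix(0L, 64, 64), f, cfg)
  expect_equal(res3$object_count, 0L)
  expect_equal(res3$rejected_object_count, 0L)
})

test_that("raising tau never increases kept objects or positive area", {
  f <- generate_ihc_field(synth_ihc_config(width = 256, height = 256,
                                           target_fraction = 0.2, seed = 2))
  base <- quiet_segment(f$field)
  labels0 <- ihcquant:::label_mask(base$mask)
  prev_count <- Inf; prev_area <- Inf
  for (tau in c(0.5, 1, 1.15, 1.5, 3)) {
    cfg <- segmentation_config(artifact_ratio_cutoff = tau)
    res <- remove_artifacts(base$mask, labels0, f$field, cfg)
    expect_lte(res$object_count, prev_count)
    expect_lte(sum(res$mask), prev_area)
    prev_count <- res$object_count; prev_area <- sum(res$mask)
  }
})

test_that("labeling is 8-connected", {
  m <- matrix(FALSE, 34, 34)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal touch: one object
  m[10, 10] <- TRUE; m[12, 12] <- TRUE  # gap: two objects
  lab <- ihcquant:::label_mask(m)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(max(lab), 3L)
})

test_that("segmentation recovers the ground truth on the default synthetic preset", {
  f <- generate_ihc_field(synth_ihc_config(width = 256, height = 256,
                                           target_fraction = 0.25, seed = 1))
  seg <- quiet_segment(f$field)
  expect_gte(dice_coefficient(seg$mask, f$truth$mask), 0.8)
  expect_equal(seg$positive_area_px, sum(seg$mask))
  expect_equal(seg$area_fraction, sum(seg$mask) / (256 * 256))
  expect_equal(seg$positive_area_um2, seg$positive_area_px * f$field$pixel_size^2)
})

test_that("median Dice >= 0.8 and median area error <= 20% over 10 seeds", {
  fractions <- seq(0.05, 0.4, length.out = 10)
  dice <- rel_err <- numeric(10)
  for (i in 1:10) {
    f <- generate_ihc_field(synth_ihc_config(width = 256, height = 256,
                                             target_fraction = fractions[i],
                                             seed = 100 + i))
    seg <- quiet_segment(f$field)
    dice[i] <- dice_coefficient(seg$mask, f$truth$mask)
    rel_err[i] <- abs(seg$area_fraction - f$truth$realized_fraction) /
      f$truth$realized_fraction
  }
  expect_gte(median(dice), 0.8)
  expect_lte(median(rel_err), 0.2)
})

test_that("a blank field is degenerate or measures zero area", {
  blank <- generate_ihc_field(synth_ihc_config(width = 64, height = 64,
                                               target_fraction = 0, n_blobs = 0,
                                               n_nuclei = 0, noise_sd = 0,
                                               illum_gradient = 1))
  res <- tryCatch(quiet_segment(blank$field), error = function(e) e)
  if (inherits(res, "error")) {
    expect_s3_class(res, "ihcquant_degenerate_field")
  } else {
    expect_equal(res$area_fraction, 0)
  }
})

test_that("segmenting a shaded scene with its flat-field matches the unshaded scene", {
  scene <- generate_ihc_field(synth_ihc_config(width = 256, height = 256,
                                               target_fraction = 0.2, seed = 5,
                                               noise_sd = 0, illum_gradient = 1))
  ff <- generate_flatfield(256, 256, 1.5, seed = 9)
  shaded <- rgb_field(pmin(pmax(scene$field$pixels * as.vector(ff$pixels[, , 1]), 0), 1),
                      pixel_size = scene$field$pixel_size)
  s1 <- quiet_segment(scene$field)
  s2 <- quiet_segment(shaded, flatfield = ff)
  expect_lte(mean(s1$mask != s2$mask), 0.02)
})

test_that("section summaries aggregate fields with textbook statistics", {
  d <- tibble::tibble(
    group = rep(c("control", "treated"), each = 2),
    area_um2 = c(200, 300, 100, 200),
    fraction = c(0.2, 0.3, 0.1, 0.2),
    objects = c(10, 12, 6, 8)
  )
  s <- quantify_section(d, group, control = "control")
  g <- glance(s)
  ctrl_frac <- g[g$measure == "area_fraction" & g$group == "control", ]
  expect_equal(ctrl_frac$mean, 0.25)
  expect_equal(ctrl_frac$sd, 0.07071068, tolerance = 1e-6)
  expect_equal(ctrl_frac$sem, 0.05)
  cmp <- tidy(s)
  expect_equal(cmp$percent_inhibition[cmp$measure == "area_fraction"], 40)

  expect_error(quantify_section(d[c(1, 3, 4), ], group), class = "ihcquant_bad_input")
  expect_error(quantify_section(d[, -2], group), class = "ihcquant_bad_input")
  one_group <- dplyr::mutate(d, group = "control")
  expect_error(quantify_section(one_group, group), class = "ihcquant_bad_input")
})
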