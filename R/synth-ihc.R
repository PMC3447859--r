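#' Configuration for a synthetic immunostained field
#'
#' Parameter bundle for [generate_ihc_field()]: a DAB-brown positive signal
#' over a hematoxylin-blue nuclear counterstain on a bright background, with
#' smooth multiplicative uneven illumination and Gaussian intensity noise.
#' Defaults emulate a brightfield camera field at 0.5 um/px; stain colors are
#' typical rendered hues for DAB and hematoxylin and are configurable because
#' acquisition color balance varies between setups.
#'
#' @param width,height field size in pixels (>= 32).
#' @param pixel_size physical pixel size, um/px.
#' @param target_fraction requested DAB-positive area fraction in `[0, 0.9]`.
#' @param n_blobs nominal number of stained blobs; the generator adds or
#'   shrinks blobs until the realized fraction is within 10% (relative) of
#'   `target_fraction`.
#' @param blob_radius_mean,blob_radius_sd ellipse semi-axis distribution, px.
#' @param n_nuclei number of counterstained nuclei; default scales with area.
#' @param nucleus_radius nucleus radius, px.
#' @param dab_rgb,hematoxylin_rgb,background_rgb RGB triplets in `[0, 1]`.
#' @param illum_gradient peak-to-trough ratio of the illumination field, >= 1.
#' @param noise_sd SD of zero-mean Gaussian intensity noise.
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @return A `synth_ihc_config` object.
#' @export
synth_ihc_config <- function(width = 256, height = 256, pixel_size = 0.5,
                             target_fraction = 0.25,
                             n_blobs = NULL,
                             blob_radius_mean = 12, blob_radius_sd = 3,
                             n_nuclei = NULL, nucleus_radius = 5,
                             dab_rgb = c(0.42, 0.28, 0.14),
                             hematoxylin_rgb = c(0.35, 0.35, 0.65),
                             background_rgb = c(0.92, 0.90, 0.90),
                             illum_gradient = 1.3, noise_sd = 0.02,
                             seed = 1) {
  if (width < 32 || height < 32) stop_ihc("field must be at least 32 x 32 px", "ihcquant_bad_input")
  if (target_fraction < 0 || target_fraction > 0.9) {
    stop_ihc("`target_fraction` must lie in [0, 0.9]", "ihcquant_bad_input")
  }
  for (col in list(dab_rgb, hematoxylin_rgb, background_rgb)) {
    if (length(col) != 3 || any(col < 0) || any(col > 1)) {
      stop_ihc("stain colors must be RGB triplets in [0, 1]", "ihcquant_bad_input")
    }
  }
  if (noise_sd < 0) stop_ihc("`noise_sd` must be >= 0", "ihcquant_bad_input")
  if (illum_gradient < 1) stop_ihc("`illum_gradient` must be >= 1", "ihcquant_bad_input")
  if (blob_radius_mean < 2) stop_ihc("`blob_radius_mean` must be >= 2 px", "ihcquant_bad_input")
  n_nuclei <- n_nuclei %||% round(width * height * 0.0023)
  n_blobs <- n_blobs %||%
    max(10, round(target_fraction * width * height / (pi * blob_radius_mean^2)))
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      pixel_size = pixel_size, target_fraction = target_fraction,
      n_blobs = as.integer(n_blobs),
      blob_radius_mean = blob_radius_mean, blob_radius_sd = blob_radius_sd,
      n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
      dab_rgb = dab_rgb, hematoxylin_rgb = hematoxylin_rgb,
      background_rgb = background_rgb,
      illum_gradient = illum_gradient, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synth_ihc_config"
  )
}

#' Ground truth of a synthetic field
#'
#' Boolean mask of true DAB-positive pixels, realized area fraction (recomputed
#' exactly from the mask) and 8-connected object count.
#'
#' @param mask logical H x W matrix.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(mask) {
  if (!is.matrix(mask)) stop_ihc("`mask` must be a logical matrix", "ihcquant_bad_input")
  mask <- mask & TRUE
  structure(
    list(
      mask = mask,
      realized_fraction = sum(mask) / length(mask),
      object_count = max(label_mask(mask))
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d x %d, fraction %.4f, %d object(s)\n",
              nrow(x$mask), ncol(x$mask), x$realized_fraction, x$object_count))
  invisible(x)
}

# rasterize one ellipse into a logical matrix (in place on `mask`)
paint_ellipse <- function(mask, cx, cy, a, b, theta) {
  H <- nrow(mask); W <- ncol(mask)
  r <- ceiling(max(a, b))
  rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  dy <- rows - cy
  dx <- cols - cx
  DX <- matrix(dx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  DY <- matrix(dy, nrow = length(rows), ncol = length(cols))
  u <- (DX * cos(theta) + DY * sin(theta)) / a
  v <- (-DX * sin(theta) + DY * cos(theta)) / b
  mask[rows, cols] <- mask[rows, cols] | (u^2 + v^2 <= 1)
  mask
}

# smooth linear illumination ramp with exact peak-to-trough ratio `gradient`
make_illum <- function(height, width, gradient, theta) {
  if (gradient == 1) return(matrix(1, height, width))
  xn <- matrix(seq(0, 1, length.out = width), height, width, byrow = TRUE)
  yn <- matrix(seq(0, 1, length.out = height), height, width)
  p <- cos(theta) * xn + sin(theta) * yn
  u <- (p - min(p)) / (max(p) - min(p))
  1 / gradient + (1 - 1 / gradient) * u
}

#' Generate one synthetic immunostained field with ground truth
#'
#' Composes a brightfield image from a background, circular hematoxylin nuclei
#' and elliptical DAB blobs (painted last, so the ground truth equals exactly
#' the visible DAB area; nuclei are never counted as positive), multiplies by a
#' smooth illumination ramp with the configured peak-to-trough ratio, adds
#' zero-mean Gaussian noise and clips to `[0, 1]`. Blobs are placed one at a
#' time, the final one shrunk as needed, until the realized positive fraction
#' is within 10% (relative) of `target_fraction`.
#'
#' @param config a [synth_ihc_config()].
#' @return A list with elements `field` (an [rgb_field()]) and `truth`
#'   (a [ground_truth()]).
#' @examples
#' f <- generate_ihc_field(synth_ihc_config(width = 64, height = 64,
#'                                          target_fraction = 0.1, seed = 3))
#' f$truth$realized_fraction
#' @export
generate_ihc_field <- function(config) {
  if (!inherits(config, "synth_ihc_config")) {
    stop_ihc("`config` must be a synth_ihc_config", "ihcquant_bad_input")
  }
  H <- config$height; W <- config$width
  withr::with_seed(config$seed, {
    # ground-truth DAB mask ---------------------------------------------------
    gt <- matrix(FALSE, H, W)
    target_px <- round(config$target_fraction * H * W)
    if (target_px > 0) {
      if (config$n_blobs < 1) {
        stop_ihc(
          "target_fraction > 0 is unreachable with n_blobs = 0",
          "ihcquant_bad_input"
        )
      }
      tol_px <- 0.1 * target_px
      max_blobs <- max(500L, config$n_blobs * 50L)
      placed <- 0L
      while (sum(gt) < target_px - tol_px / 2) {
        if (placed >= max_blobs) {
          stop_ihc(sprintf(
            "target_fraction %.3g unreachable: %d blobs of mean radius %.3g px placed without reaching it",
            config$target_fraction, placed, config$blob_radius_mean
          ), "ihcquant_bad_input")
        }
        a <- max(2, rnorm(1, config$blob_radius_mean, config$blob_radius_sd))
        b <- max(2, rnorm(1, config$blob_radius_mean, config$blob_radius_sd))
        remaining <- target_px - sum(gt)
        if (pi * a * b > 1.2 * remaining) {
          # shrink the closing blob so the band is not overshot
          s <- sqrt(remaining / (pi * a * b))
          a <- max(1.5, a * s); b <- max(1.5, b * s)
        }
        m <- ceiling(max(a, b))
        if (2 * m + 2 >= min(H, W)) {
          stop_ihc("blob radius too large for the field size", "ihcquant_bad_input")
        }
        cx <- runif(1, m + 1, W - m)
        cy <- runif(1, m + 1, H - m)
        theta <- runif(1, 0, pi)
        gt <- paint_ellipse(gt, cx, cy, a, b, theta)
        placed <- placed + 1L
      }
      if (abs(sum(gt) - target_px) > tol_px) {
        stop_ihc(sprintf(
          "realized fraction %.4f misses target %.4f by more than 10%% (blob_radius_mean %.3g px too coarse)",
          sum(gt) / (H * W), config$target_fraction, config$blob_radius_mean
        ), "ihcquant_bad_input")
      }
    }

    # nuclei (painted under the DAB layer) ------------------------------------
    nuc <- matrix(FALSE, H, W)
    if (config$n_nuclei > 0) {
      r0 <- config$nucleus_radius
      for (i in seq_len(config$n_nuclei)) {
        r <- max(1.5, r0 * runif(1, 0.8, 1.2))
        nuc <- paint_ellipse(nuc, runif(1, 1, W), runif(1, 1, H), r, r, 0)
      }
    }
    nuc <- nuc & !gt

    # compose ------------------------------------------------------------------
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(config$background_rgb[ch], H, W)
      plane[nuc] <- config$hematoxylin_rgb[ch]
      plane[gt] <- config$dab_rgb[ch]
      img[, , ch] <- plane
    }
    if (config$illum_gradient > 1) {
      illum <- make_illum(H, W, config$illum_gradient, runif(1, 0, 2 * pi))
      img <- img * as.vector(illum)
    }
    if (config$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, config$noise_sd)
    }
    img <- clip01(img)

    list(
      field = rgb_field(img, pixel_size = config$pixel_size,
                        field_id = sprintf("synth-seed%d", config$seed)),
      truth = ground_truth(gt)
    )
  })
}

#' Generate a flat-field (light-field) illumination image
#'
#' Smooth multiplicative illumination image whose max/min pixel ratio equals
#' `illum_gradient` exactly (a constant image for `illum_gradient = 1`), as a
#' companion to an empty-optical-path acquisition used for flat-field
#' correction. The ramp direction is drawn from `seed`.
#'
#' @param width,height image size in pixels.
#' @param illum_gradient peak-to-trough ratio, >= 1.
#' @param seed integer seed.
#' @return An [rgb_field()] with three identical channels.
#' @export
generate_flatfield <- function(width, height, illum_gradient, seed = 1) {
  if (width < 32 || height < 32) {
    stop_ihc("flatfield must be at least 32 x 32 px", "ihcquant_bad_input")
  }
  if (illum_gradient < 1) {
    stop_ihc("`illum_gradient` must be >= 1", "ihcquant_bad_input")
  }
  withr::with_seed(as.integer(seed), {
    illum <- make_illum(height, width, illum_gradient, runif(1, 0, 2 * pi))
    rgb_field(array(rep(illum, 3), dim = c(height, width, 3)),
              field_id = "flatfield")
  })
}

#' Generate a two-group synthetic immunostained study
#'
#' Draws `n_fields_per_group` control and treated fields whose ground-truth
#' positive fractions encode a preset's effect size (e.g. the proliferation or
#' vessel marker presets). Per-field seeds and mild per-field biological
#' variability (lognormal, CV `field_jitter_cv`) are derived deterministically
#' from the master seed; the default of six fields per group mirrors the
#' random selection of six microscopic fields per stained section.
#'
#' @param preset a preset name or [synth_preset()] of type `"ihc"`.
#' @param n_fields_per_group fields per group (>= 1; default 6).
#' @param seed master seed.
#' @param width,height field size in pixels (default 512).
#' @param field_jitter_cv CV of per-field lognormal variation of the target
#'   fraction (mean-one; default 0.05).
#' @param ... further arguments passed to [synth_ihc_config()].
#' @return A tibble with one row per field: `group`, `field_id`, `seed`,
#'   `target_fraction`, `realized_fraction`, and list-columns `field`
#'   ([rgb_field()]) and `truth` ([ground_truth()]).
#' @examples
#' study <- generate_ihc_study("ki67-fig3c", n_fields_per_group = 2, seed = 1,
#'                             width = 96, height = 96)
#' dplyr::count(study, group)
#' @export
generate_ihc_study <- function(preset, n_fields_per_group = 6, seed = 1,
                               width = 512, height = 512,
                               field_jitter_cv = 0.05, ...) {
  preset <- synth_preset(preset)
  if (!identical(preset$type, "ihc")) {
    stop_ihc(sprintf("preset '%s' is not an IHC preset", preset$name),
             "ihcquant_bad_input")
  }
  n <- n_fields_per_group
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop_ihc("`n_fields_per_group` must be a positive integer", "ihcquant_bad_input")
  }
  withr::with_seed(as.integer(seed), {
    field_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n)
    sig <- sqrt(log(1 + field_jitter_cv^2))
    jitter <- exp(rnorm(2 * n, -sig^2 / 2, sig))
  })
  fractions <- rep(c(preset$control_fraction, preset$treated_fraction), each = n)
  groups <- rep(c("control", "treated"), each = n)
  rows <- purrr::map(seq_len(2 * n), function(i) {
    cfg <- synth_ihc_config(
      width = width, height = height,
      target_fraction = min(0.9, fractions[i] * jitter[i]),
      seed = field_seeds[i], ...
    )
    out <- generate_ihc_field(cfg)
    out$field$field_id <- sprintf("%s-%02d", groups[i], ((i - 1) %% n) + 1)
    tibble::tibble(
      group = groups[i],
      field_id = out$field$field_id,
      seed = field_seeds[i],
      target_fraction = cfg$target_fraction,
      realized_fraction = out$truth$realized_fraction,
      field = list(out$field),
      truth = list(out$truth)
    )
  })
  dplyr::bind_rows(rows)
}
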