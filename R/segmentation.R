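#' Segmentation configuration
#'
#' Tunables of the stained-area quantification pipeline. Defaults: alpha grid
#' step 0.05; band-pass structure sizes 2 px (small) and 80 px (large); DAB
#' hue sector 10-50 degrees and hematoxylin sector 200-260 degrees with
#' off-sector saturation scaled to 0 (full suppression of non-specific color);
#' artifact red/blue ratio cutoff tau = 1.15 (boundary inclusive); minimum
#' object area 20 px; 8-connectivity.
#'
#' @param alpha_grid_step grid step for the contrast weight alpha in `(0, 1]`.
#' @param bandpass_small,bandpass_large structure sizes in px, small < large.
#' @param hue_sectors list of two numeric `c(low, high)` hue intervals in
#'   degrees: `dab` and `hematoxylin`; must not overlap.
#' @param offsector_saturation_scale multiplier in `[0, 1]` applied to the
#'   saturation of pixels whose hue lies outside both sectors.
#' @param artifact_ratio_cutoff object mean-red / mean-blue cutoff tau (> 0).
#' @param min_object_area minimum object area in px.
#' @param connectivity pixel connectivity for object labeling (8).
#' @return A `segmentation_config` object.
#' @export
segmentation_config <- function(alpha_grid_step = 0.05,
                                bandpass_small = 2, bandpass_large = 80,
                                hue_sectors = list(dab = c(10, 50),
                                                   hematoxylin = c(200, 260)),
                                offsector_saturation_scale = 0,
                                artifact_ratio_cutoff = 1.15,
                                min_object_area = 20,
                                connectivity = 8) {
  if (alpha_grid_step <= 0 || alpha_grid_step > 1) {
    stop_ihc("`alpha_grid_step` must lie in (0, 1]", "ihcquant_bad_input")
  }
  if (!(bandpass_small > 0 && bandpass_small < bandpass_large)) {
    stop_ihc("band-pass sizes require 0 < small < large", "ihcquant_bad_input")
  }
  if (!is.list(hue_sectors) || length(hue_sectors) != 2) {
    stop_ihc("`hue_sectors` must be a list of two c(low, high) intervals",
             "ihcquant_bad_input")
  }
  for (sec in hue_sectors) {
    if (length(sec) != 2 || sec[1] < 0 || sec[2] > 360 || sec[1] >= sec[2]) {
      stop_ihc("each hue sector must satisfy 0 <= low < high <= 360",
               "ihcquant_bad_input")
    }
  }
  s1 <- hue_sectors[[1]]; s2 <- hue_sectors[[2]]
  if (max(s1[1], s2[1]) < min(s1[2], s2[2])) {
    stop_ihc("hue sectors must not overlap", "ihcquant_bad_input")
  }
  if (offsector_saturation_scale < 0 || offsector_saturation_scale > 1) {
    stop_ihc("`offsector_saturation_scale` must lie in [0, 1]", "ihcquant_bad_input")
  }
  if (artifact_ratio_cutoff <= 0) stop_ihc("tau must be > 0", "ihcquant_bad_input")
  if (connectivity != 8) stop_ihc("only 8-connectivity is supported", "ihcquant_bad_input")
  structure(
    list(
      alpha_grid_step = alpha_grid_step,
      bandpass_small = bandpass_small, bandpass_large = bandpass_large,
      hue_sectors = hue_sectors,
      offsector_saturation_scale = offsector_saturation_scale,
      artifact_ratio_cutoff = artifact_ratio_cutoff,
      min_object_area = min_object_area,
      connectivity = connectivity
    ),
    class = "segmentation_config"
  )
}

# color-space helpers ----------------------------------------------------------

# matrices in, list(h deg [0,360), s, v) out; hue of gray pixels is 0
rgb_to_hsv_mats <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  v <- mx
  s <- ifelse(mx > 0, d / mx, 0)
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  ir <- nz & mx == r
  ig <- nz & mx == g & !ir
  ib <- nz & !ir & !ig
  h[ir] <- ((g[ir] - b[ir]) / d[ir]) %% 6
  h[ig] <- (b[ig] - r[ig]) / d[ig] + 2
  h[ib] <- (r[ib] - g[ib]) / d[ib] + 4
  list(h = h * 60, s = s, v = v)
}

hsv_to_rgb_mats <- function(h, s, v) {
  h6 <- (h / 60) %% 6
  c0 <- v * s
  x <- c0 * (1 - abs(h6 %% 2 - 1))
  m <- v - c0
  k <- floor(h6)
  r <- c0 * (k == 0 | k == 5) + x * (k == 1 | k == 4)
  g <- c0 * (k == 1 | k == 2) + x * (k == 0 | k == 3)
  b <- c0 * (k == 3 | k == 4) + x * (k == 2 | k == 5)
  list(r = r + m, g = g + m, b = b + m)
}

# pipeline operations ----------------------------------------------------------

#' Flat-field (light-field) illumination correction
#'
#' Divides each channel by the flat-field image (floored at `eps`) and rescales
#' by that channel's flat-field mean, so the per-channel spatial mean of the
#' scene is preserved when no clipping occurs; output is clipped to `[0, 1]`.
#'
#' @param image scene [rgb_field()].
#' @param flatfield acquisition of the empty optical path, same dimensions.
#' @param eps positive floor applied to the flat-field before division.
#' @return The corrected [rgb_field()].
#' @export
flatfield_correct <- function(image, flatfield, eps = 1e-3) {
  assert_rgb_field(image); assert_rgb_field(flatfield, "flatfield")
  if (!identical(dim(image$pixels), dim(flatfield$pixels))) {
    stop_ihc("image and flatfield dimensions differ", "ihcquant_bad_input")
  }
  out <- image$pixels
  for (ch in 1:3) {
    ff <- flatfield$pixels[, , ch]
    if (all(ff <= 0)) {
      stop_ihc(sprintf("flat-field channel %d is all zero", ch), "ihcquant_bad_input")
    }
    ff <- pmax(ff, eps)
    out[, , ch] <- image$pixels[, , ch] / ff * mean(ff)
  }
  with_pixels(image, clip01(out))
}

#' Suppress non-specific color outside the stain hue sectors
#'
#' Converts the image to hue/saturation/brightness, multiplies the saturation
#' of every pixel whose hue falls outside both configured stain sectors
#' (DAB-brown, hematoxylin-blue) by `offsector_saturation_scale`, and converts
#' back. In-sector pixels and achromatic pixels (saturation 0) are unchanged;
#' with scale 0 the operation is idempotent.
#'
#' @param image an [rgb_field()].
#' @param config a [segmentation_config()] providing the sectors and scale.
#' @return The suppressed [rgb_field()].
#' @export
suppress_nonspecific <- function(image, config = segmentation_config()) {
  assert_rgb_field(image)
  scale <- config$offsector_saturation_scale
  if (scale == 1) return(image)
  r <- channel(image, 1); g <- channel(image, 2); b <- channel(image, 3)
  hsv <- rgb_to_hsv_mats(r, g, b)
  in_sector <- Reduce(`|`, lapply(config$hue_sectors, function(sec) {
    hsv$h >= sec[1] & hsv$h <= sec[2]
  }))
  hsv$s[!in_sector] <- hsv$s[!in_sector] * scale
  rgb <- hsv_to_rgb_mats(hsv$h, hsv$s, hsv$v)
  px <- array(c(rgb$r, rgb$g, rgb$b), dim = dim(image$pixels))
  with_pixels(image, clip01(px))
}

#' Red-blue stain contrast image
#'
#' The weighted channel difference `C = alpha * R - (1 - alpha) * B` that the
#' adaptive color sorting optimizes: high alpha weights the red (DAB) axis,
#' low alpha the (negated) blue (hematoxylin) axis. Returned unscaled;
#' conversion to 8-bit happens at thresholding.
#'
#' @param image an [rgb_field()].
#' @param alpha mixing weight in `[0, 1]`.
#' @return A numeric H x W matrix.
#' @export
stain_contrast <- function(image, alpha) {
  assert_rgb_field(image)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    stop_ihc("`alpha` must lie in [0, 1]", "ihcquant_bad_input")
  }
  alpha * channel(image, 1) - (1 - alpha) * channel(image, 3)
}

#' Band-pass background removal
#'
#' Difference of two Gaussian blurs with `sigma = size / 2` for the small and
#' large structure sizes: structures between the two scales pass, smooth
#' background (and the DC level) and pixel noise are suppressed. The output
#' has spatial mean zero.
#'
#' @param contrast numeric matrix (e.g. from [stain_contrast()]).
#' @param small,large structure sizes in px, `0 < small < large`.
#' @return A numeric matrix of the same size with mean 0.
#' @export
bandpass <- function(contrast, small = 2, large = 80) {
  if (!is.matrix(contrast)) stop_ihc("`contrast` must be a matrix", "ihcquant_bad_input")
  if (!(small > 0 && small < large)) {
    stop_ihc("band-pass sizes require 0 < small < large", "ihcquant_bad_input")
  }
  lo <- EBImage::gblur(contrast, sigma = small / 2)
  hi <- EBImage::gblur(contrast, sigma = large / 2)
  out <- lo - hi
  out - mean(out)
}

# min-max rescale to integer 0..255; NULL if the input is constant
rescale_8bit <- function(x) {
  mn <- min(x); mx <- max(x)
  if (!is.finite(mn) || !is.finite(mx) || mx - mn < 1e-12) return(NULL)
  r <- round((x - mn) / (mx - mn) * 255)
  storage.mode(r) <- "integer"
  r
}

#' Isodata (intermeans) automatic threshold
#'
#' Iterative intermeans thresholding on the 8-bit histogram: starting from the
#' truncated overall mean, the threshold is repeatedly replaced by the integer
#' part of the average of the mean level at-or-below and the mean level above
#' it, until it is a fixed point. Integer-valued input already on the 0..255
#' scale is used as-is; other input is min-max rescaled to `[0, 255]` first.
#' Pixels strictly above the returned threshold are the positive class.
#'
#' @param x numeric vector or matrix of intensities.
#' @return The integer threshold T in `0..254`.
#' @examples
#' isodata_threshold(c(rep(50, 100), rep(200, 100)))  # 125
#' @export
isodata_threshold <- function(x) {
  x <- as.vector(x)
  if (!length(x) || anyNA(x)) stop_ihc("invalid threshold input", "ihcquant_bad_input")
  already_8bit <- all(x == round(x)) && min(x) >= 0 && max(x) <= 255
  if (already_8bit) {
    x8 <- as.integer(x)
  } else {
    x8 <- rescale_8bit(x)
    if (is.null(x8)) {
      stop_ihc("constant image: threshold undefined (degenerate field)",
               "ihcquant_degenerate_field")
    }
  }
  counts <- tabulate(x8 + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) {
    stop_ihc("histogram has a single populated level (degenerate field)",
             "ihcquant_degenerate_field")
  }
  lev <- 0:255
  csum_n <- cumsum(counts)
  csum_w <- cumsum(counts * lev)
  n_tot <- csum_n[256]; w_tot <- csum_w[256]
  t_cur <- floor(w_tot / n_tot)
  for (i in 1:256) {
    n_lo <- csum_n[t_cur + 1]
    if (n_lo == 0 || n_lo == n_tot) break
    m_lo <- csum_w[t_cur + 1] / n_lo
    m_hi <- (w_tot - csum_w[t_cur + 1]) / (n_tot - n_lo)
    t_new <- floor((m_lo + m_hi) / 2)
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  as.integer(t_cur)
}

#' Adaptive red-blue contrast optimization
#'
#' The adaptive pixel color sorting step: for each alpha on the grid
#' `{0, step, ..., 1}` the contrast image [stain_contrast()] is rescaled to
#' 8-bit and auto-thresholded ([isodata_threshold()]); the separability metric
#' is the between-class variance at that threshold normalized by the total
#' variance. A grid point is admissible only if its above-threshold class
#' passes the same red/blue color test the artifact filter applies (mean red
#' over mean blue at least `tau`) -- the positive class must be the DAB-like
#' side the later red/blue sorting assumes; inadmissible or degenerate points
#' score 0. A four-parameter logistic is
#' then fitted to metric vs alpha (the shared [fit_4pl()] machinery) and
#' `alpha*` is the grid point maximizing the fitted curve; grid points tying
#' on the fitted curve's flat plateau are resolved by the raw metric, and any
#' remaining ties toward larger alpha (favoring the red/DAB axis). If the 4PL
#' fit fails, the raw grid argmax is used with a warning.
#'
#' @param image an [rgb_field()] (normally after [suppress_nonspecific()]).
#' @param config a [segmentation_config()].
#' @return A `contrast_params` object: `alpha`, `metric_curve` (tibble of
#'   alpha/metric), `fit` (the 4PL fit or NULL) and `fallback`.
#' @export
optimize_alpha <- function(image, config = segmentation_config()) {
  assert_rgb_field(image)
  r <- channel(image, 1); b <- channel(image, 3)
  if (isTRUE(all.equal(r, b, tolerance = 1e-12))) {
    stop_ihc("red and blue channels are identical (degenerate field)",
             "ihcquant_degenerate_field")
  }
  grid <- unique(c(seq(0, 1, by = config$alpha_grid_step), 1))
  metric <- vapply(grid, function(a) {
    cimg <- a * r - (1 - a) * b
    x8 <- rescale_8bit(cimg)
    if (is.null(x8)) return(0)
    t_a <- tryCatch(isodata_threshold(x8), error = function(e) NULL)
    if (is.null(t_a)) return(0)
    above <- x8 > t_a
    n2 <- sum(above)
    if (n2 == 0 || n2 == length(x8)) return(0)
    # the positive class must be DAB-like: same red/blue color test as the
    # artifact filter (tau, boundary inclusive)
    if (mean(r[above]) / (mean(b[above]) + 1e-6) < config$artifact_ratio_cutoff) {
      return(0)
    }
    w2 <- n2 / length(x8); w1 <- 1 - w2
    m1 <- mean(x8[!above]); m2 <- mean(x8[above])
    tv <- mean((x8 - mean(x8))^2)
    if (tv <= 0) return(0)
    w1 * w2 * (m2 - m1)^2 / tv
  }, numeric(1))

  curve <- tibble::tibble(alpha = grid, metric = metric)
  if (diff(range(metric)) < 1e-6) {
    stop_ihc("separability metric is flat across alpha (degenerate field)",
             "ihcquant_degenerate_field")
  }
  # argmax over the grid; near-ties (the fitted sigmoid is flat on its
  # plateau) are resolved by the raw metric, then toward larger alpha
  pick_max <- function(values) {
    tol <- max(1e-12, 1e-6 * diff(range(values)))
    cand <- which(values >= max(values) - tol)
    best <- cand[metric[cand] >= max(metric[cand]) - 1e-12]
    grid[max(best)]
  }
  fit <- tryCatch(
    suppressWarnings(fit_4pl(curve, alpha, metric)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    rlang::warn("4PL fit of the separability curve failed; using the raw grid argmax",
                class = "ihcquant_alpha_fallback")
    alpha_star <- pick_max(metric)
  } else {
    alpha_star <- pick_max(predict(fit, grid))
  }
  structure(
    list(alpha = alpha_star, metric_curve = curve, fit = fit,
         fallback = is.null(fit)),
    class = "contrast_params"
  )
}

#' @export
print.contrast_params <- function(x, ...) {
  cat(sprintf("<contrast_params> alpha* = %.2f (metric %.3f%s)\n",
              x$alpha,
              x$metric_curve$metric[x$metric_curve$alpha == x$alpha],
              if (x$fallback) ", raw-grid fallback" else ""))
  invisible(x)
}

# connected components ---------------------------------------------------------

# 8-connected labeling: EBImage::bwlabel (4-connected) plus a diagonal
# union-find merge.
label_mask <- function(mask) {
  if (!is.matrix(mask)) stop_ihc("`mask` must be a matrix", "ihcquant_bad_input")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  a1 <- lab[-H, -W]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -W]; b2 <- lab[-H, -1]    # up-right diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Color-based artifact rejection
#'
#' Final color sorting of the labeled objects: an object is kept iff its mean
#' red over mean blue ratio (computed on the flat-field-corrected image, with
#' a 1e-6 guard in the denominator) is at least `tau` (boundary inclusive) and
#' its area is at least `min_object_area`. Everything else -- hematoxylin
#' nuclei, gray debris -- is rejected and counted.
#'
#' @param mask logical positive mask.
#' @param labels integer label matrix consistent with `mask` (8-connected).
#' @param image the flat-field-corrected [rgb_field()] supplying the colors.
#' @param config a [segmentation_config()].
#' @return A list: filtered `mask` and `labels` (relabeled `1..K`),
#'   `object_count`, `rejected_object_count`, and a per-object tibble
#'   `object_stats` (`label`, `area_px`, `mean_red`, `mean_blue`, `red_blue_ratio`,
#'   `kept`).
#' @export
remove_artifacts <- function(mask, labels, image, config = segmentation_config()) {
  assert_rgb_field(image)
  if (!identical(dim(mask), dim(labels))) {
    stop_ihc("mask and labels dimensions differ", "ihcquant_bad_input")
  }
  n <- max(labels)
  empty_stats <- tibble::tibble(
    label = integer(), area_px = integer(), mean_red = numeric(),
    mean_blue = numeric(), red_blue_ratio = numeric(), kept = logical()
  )
  if (n == 0) {
    return(list(mask = mask & FALSE, labels = labels * 0L,
                object_count = 0L, rejected_object_count = 0L,
                object_stats = empty_stats))
  }
  rmat <- channel(image, 1); bmat <- channel(image, 3)
  idx <- which(labels > 0)
  lab <- labels[idx]
  area <- tabulate(lab, nbins = n)
  mean_r <- as.vector(rowsum(rmat[idx], lab)) / area
  mean_b <- as.vector(rowsum(bmat[idx], lab)) / area
  ratio <- mean_r / (mean_b + 1e-6)
  kept <- ratio >= config$artifact_ratio_cutoff & area >= config$min_object_area
  new_id <- cumsum(kept)
  out_labels <- matrix(0L, nrow(labels), ncol(labels))
  keep_px <- kept[lab]
  out_labels[idx[keep_px]] <- new_id[lab[keep_px]]
  list(
    mask = out_labels > 0,
    labels = out_labels,
    object_count = sum(kept),
    rejected_object_count = sum(!kept),
    object_stats = tibble::tibble(
      label = seq_len(n), area_px = area, mean_red = mean_r,
      mean_blue = mean_b, red_blue_ratio = ratio, kept = kept
    )
  )
}

#' Segment one stained field end to end
#'
#' Runs the full quantification chain: flat-field correction (skipped without
#' a flat-field), non-specific color suppression, adaptive alpha optimization,
#' stain contrast at `alpha*`, band-pass background removal, isodata
#' thresholding (positive = strictly above T), 8-connected component labeling,
#' and color-based artifact rejection. Degenerate fields (blank, or without
#' red/blue contrast) raise an error of class `ihcquant_degenerate_field`;
#' callers such as [run_pipeline()] exclude them from summaries with a logged
#' reason.
#'
#' @param image an [rgb_field()].
#' @param flatfield optional flat-field [rgb_field()].
#' @param config a [segmentation_config()].
#' @return An `ihc_segmentation` object holding the final `mask`, `labels`,
#'   8-bit `threshold`, the `contrast_params`, positive area in px and um^2,
#'   area fraction, and kept/rejected object counts. [tidy()] returns the
#'   one-row per-field summary.
#' @examples
#' f <- generate_ihc_field(synth_ihc_config(width = 96, height = 96,
#'                                          target_fraction = 0.2, seed = 2))
#' seg <- segment_field(f$field)
#' tidy(seg)
#' @export
segment_field <- function(image, flatfield = NULL,
                          config = segmentation_config()) {
  assert_rgb_field(image)
  corrected <- if (!is.null(flatfield)) {
    flatfield_correct(image, flatfield)
  } else {
    image
  }
  suppressed <- suppress_nonspecific(corrected, config)
  params <- optimize_alpha(suppressed, config)
  cimg <- stain_contrast(suppressed, params$alpha)
  bp <- bandpass(cimg, config$bandpass_small, config$bandpass_large)
  x8 <- rescale_8bit(bp)
  if (is.null(x8)) {
    stop_ihc("band-passed contrast is constant (degenerate field)",
             "ihcquant_degenerate_field")
  }
  thr <- isodata_threshold(x8)
  mask0 <- x8 > thr
  labels0 <- label_mask(mask0)
  art <- remove_artifacts(mask0, labels0, corrected, config)
  hw <- prod(dim(image$pixels)[1:2])
  area_px <- sum(art$mask)
  structure(
    list(
      field_id = image$field_id,
      pixel_size = image$pixel_size,
      mask = art$mask,
      labels = art$labels,
      threshold = thr,
      params = params,
      positive_area_px = area_px,
      positive_area_um2 = area_px * image$pixel_size^2,
      area_fraction = area_px / hw,
      object_count = art$object_count,
      rejected_object_count = art$rejected_object_count,
      object_stats = art$object_stats,
      config = config
    ),
    class = "ihc_segmentation"
  )
}

#' @export
print.ihc_segmentation <- function(x, ...) {
  cat(sprintf(
    "<ihc_segmentation '%s'> alpha* %.2f, T %d, positive %.2f%% (%d px, %.1f um2), %d object(s), %d rejected\n",
    x$field_id, x$params$alpha, x$threshold, 100 * x$area_fraction,
    x$positive_area_px, x$positive_area_um2, x$object_count,
    x$rejected_object_count
  ))
  invisible(x)
}

#' @export
tidy.ihc_segmentation <- function(x, ...) {
  tibble::tibble(
    field_id = x$field_id,
    alpha = x$params$alpha,
    threshold = x$threshold,
    area_px = x$positive_area_px,
    area_um2 = x$positive_area_um2,
    fraction = x$area_fraction,
    objects = x$object_count,
    rejected = x$rejected_object_count
  )
}

#' Summarize segmented fields per group
#'
#' Aggregates per-field segmentation results into the per-group report: mean,
#' SD and SEM of the positive area (um^2 and fraction) and of the object
#' count, plus the control-vs-treated comparison (percent change, percent
#' inhibition, unpaired two-tailed t-test with stars) for each measure.
#'
#' @param data a data frame with a grouping column and the per-field columns
#'   `area_um2`, `fraction` and `objects` (e.g. `tidy()` rows of
#'   [segment_field()] results bound with a `group` column).
#' @param group unquoted grouping column (two groups required).
#' @param control control group label (defaults as in [compare_groups()]).
#' @param welch passed to [ttest_unpaired()].
#' @return A `section_summary` object: `groups` (long per-group tibble) and
#'   `comparison` (one row per measure). [tidy()] returns the comparison.
#' @export
quantify_section <- function(data, group = group, control = NULL, welch = FALSE) {
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  need <- c("area_um2", "fraction", "objects")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_ihc(paste0("missing per-field column(s): ", paste(miss, collapse = ", ")),
             "ihcquant_bad_input")
  }
  if (length(unique(g)) != 2) {
    stop_ihc("exactly two groups (control, treated) are required", "ihcquant_bad_input")
  }
  if (any(table(g) < 2)) {
    stop_ihc("each group needs at least 2 non-degenerate fields", "ihcquant_bad_input")
  }
  d <- tibble::as_tibble(data)
  d$group <- g
  long <- tidyr::pivot_longer(
    d[, c("group", need)],
    cols = dplyr::all_of(need),
    names_to = "measure", values_to = "value"
  )
  measure_labels <- c(area_um2 = "area_um2", fraction = "area_fraction",
                      objects = "object_count")
  long$measure <- unname(measure_labels[long$measure])
  groups <- long |>
    dplyr::group_by(.data$measure, .data$group) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  comparison <- long |>
    dplyr::group_by(.data$measure) |>
    dplyr::group_modify(~ compare_groups(.x, value, group,
                                         control = control, welch = welch)) |>
    dplyr::ungroup()
  structure(list(groups = groups, comparison = comparison),
            class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat("<section_summary>\n")
  for (i in seq_len(nrow(x$comparison))) {
    cmp <- x$comparison[i, ]
    cat(sprintf(
      "  %-14s %s %.4g vs %s %.4g: change %+.1f%% (p = %.3g %s)\n",
      cmp$measure, cmp$control, cmp$control_mean, cmp$treated,
      cmp$treated_mean, cmp$percent_change, cmp$p_value, cmp$stars
    ))
  }
  invisible(x)
}

#' @export
tidy.section_summary <- function(x, ...) x$comparison

#' @export
glance.section_summary <- function(x, ...) x$groups
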