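# shared fixtures: everything is generated in code, no stored binaries

# a uniform-color field (H x W) for color-arithmetic tests
flat_color_field <- function(rgb, h = 64, w = 64, pixel_size = 1) {
  px <- array(rep(rgb, each = h * w), dim = c(h, w, 3))
  rgb_field(px, pixel_size = pixel_size)
}

# paint a centered rectangle of a given color onto a field
with_patch <- function(field, rgb, rows, cols) {
  px <- field$pixels
  for (ch in 1:3) px[rows, cols, ch] <- rgb[ch]
  with_pixels_test(field, px)
}

with_pixels_test <- function(field, px) {
  rgb_field(px, pixel_size = field$pixel_size, field_id = field$field_id)
}

# segment while silencing the documented raw-grid fallback warning
quiet_segment <- function(...) {
  withCallingHandlers(
    segment_field(...),
    ihcquant_alpha_fallback = function(w) invokeRestart("muffleWarning")
  )
}

# analytic DoG transfer (the independent oracle for the band-pass filter)
dog_gain <- function(period, small, large) {
  exp(-2 * pi^2 * (small / 2)^2 / period^2) -
    exp(-2 * pi^2 * (large / 2)^2 / period^2)
}

# exhaustive fixed-point search oracle for the intermeans threshold
isodata_fixed_points <- function(counts) {
  lev <- 0:255
  fp <- integer(0)
  for (t in 0:254) {
    lo <- lev <= t
    n_lo <- sum(counts[lo]); n_hi <- sum(counts[!lo])
    if (n_lo == 0 || n_hi == 0) next
    m_lo <- sum(counts[lo] * lev[lo]) / n_lo
    m_hi <- sum(counts[!lo] * lev[!lo]) / n_hi
    if (floor((m_lo + m_hi) / 2) == t) fp <- c(fp, t)
  }
  fp
}

# exact permutation p-value of the pooled-t statistic (oracle for the t-test)
permutation_p <- function(a, b) {
  x <- c(a, b); n <- length(a)
  idx <- utils::combn(length(x), n)
  tstat <- function(g1, g2) {
    sp <- sqrt(((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
                 (length(g1) + length(g2) - 2))
    (mean(g1) - mean(g2)) / (sp * sqrt(1 / length(g1) + 1 / length(g2)))
  }
  t_obs <- abs(tstat(a, b))
  t_perm <- apply(idx, 2, function(i) abs(tstat(x[i], x[-i])))
  mean(t_perm >= t_obs - 1e-12)
}
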