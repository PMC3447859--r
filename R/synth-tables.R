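#' Generate synthetic proliferation dose-response counts
#'
#' Draws replicate cell counts from a 4PL curve with multiplicative Gaussian
#' noise: `count = y(dose) * (1 + N(0, cv))`, floored at 0. The dose-0 rows
#' define the untreated control. With `cv = 0` the counts equal the curve
#' exactly.
#'
#' @param params a [fourpl()] parameter bundle or a fitted `fourpl_fit`.
#' @param doses numeric vector of doses in uM (non-negative, non-empty).
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param n_reps replicates per dose.
#' @param seed integer seed.
#' @param cell_line label written to the `cell_line` column.
#' @return A tibble with columns `cell_line`, `dose_uM`, `replicate`, `count`.
#' @examples
#' generate_dose_response(fourpl(0, 1000, 1.24, -1.5),
#'                        doses = c(0, 1, 3, 10), cv = 0, n_reps = 1)
#' @export
generate_dose_response <- function(params, doses, cv = 0.1, n_reps = 3,
                                   seed = 1, cell_line = "synthetic") {
  if (!inherits(params, c("fourpl_params", "fourpl_fit"))) {
    stop_ihc("`params` must be a fourpl() bundle or fourpl_fit", "ihcquant_bad_input")
  }
  if (length(doses) == 0) stop_ihc("`doses` must be non-empty", "ihcquant_bad_input")
  if (any(doses < 0)) stop_ihc("doses must be non-negative", "ihcquant_bad_input")
  if (cv < 0) stop_ihc("`cv` must be >= 0", "ihcquant_bad_input")
  if (n_reps < 1) stop_ihc("`n_reps` must be >= 1", "ihcquant_bad_input")
  mu <- fourpl_response(rep(doses, each = n_reps),
                        params$bottom, params$top, params$ec50, params$hill)
  counts <- withr::with_seed(as.integer(seed), {
    pmax(0, mu * (1 + rnorm(length(mu), 0, cv)))
  })
  tibble::tibble(
    cell_line = cell_line,
    dose_uM = rep(doses, each = n_reps),
    replicate = rep(seq_len(n_reps), times = length(doses)),
    count = counts
  )
}

# released/total fraction of an LDH preset at given times (step profile:
# the last breakpoint at or before t applies)
ldh_fraction <- function(preset, condition, time_h) {
  prof <- preset$profile[preset$profile$condition == condition, ]
  vapply(time_h, function(t) {
    rows <- prof[prof$from_h <= t, ]
    rows$fraction[which.max(rows$from_h)]
  }, numeric(1))
}

#' Generate a synthetic LDH release plate
#'
#' One row per condition and timepoint with the released and total LDH
#' signals; released/total follows the preset's per-condition step profile
#' (e.g. control leakage 2%, 15% at 1 uM and 80% at 7.5 uM from 3 h onward for
#' the shipped time-course preset). Optional multiplicative noise on the
#' released signal.
#'
#' @param preset a preset name or [synth_preset()] of type `"ldh"`.
#' @param timepoints hours after treatment (positive; default
#'   `c(0.5, 3, 24, 48)`).
#' @param seed integer seed (used only when `noise_cv > 0`).
#' @param noise_cv CV of multiplicative noise on the released signal.
#' @return A tibble with columns `condition`, `time_h`, `released`, `total`.
#' @examples
#' plate <- generate_ldh_plate("ldh-fig4a", timepoints = 3)
#' ldh_cytotoxicity(plate)
#' @export
generate_ldh_plate <- function(preset, timepoints = c(0.5, 3, 24, 48),
                               seed = 1, noise_cv = 0) {
  preset <- synth_preset(preset)
  if (!identical(preset$type, "ldh")) {
    stop_ihc(sprintf("preset '%s' is not an LDH preset", preset$name),
             "ihcquant_bad_input")
  }
  if (length(timepoints) == 0 || any(timepoints <= 0)) {
    stop_ihc("`timepoints` must be positive hours", "ihcquant_bad_input")
  }
  if (is.null(preset$total_signal) || preset$total_signal <= 0) {
    stop_ihc("preset total LDH signal must be positive", "ihcquant_bad_input")
  }
  if (any(preset$profile$fraction < 0 | preset$profile$fraction > 1)) {
    stop_ihc("preset released fraction outside [0, 1]", "ihcquant_bad_input")
  }
  conditions <- unique(preset$profile$condition)
  tab <- tidyr::expand_grid(condition = conditions, time_h = sort(timepoints))
  frac <- unname(mapply(function(cond, t) ldh_fraction(preset, cond, t),
                        tab$condition, tab$time_h))
  released <- frac * preset$total_signal
  if (noise_cv > 0) {
    released <- withr::with_seed(as.integer(seed), {
      pmax(0, released * (1 + rnorm(length(released), 0, noise_cv)))
    })
  }
  tibble::tibble(
    condition = tab$condition,
    time_h = tab$time_h,
    released = released,
    total = preset$total_signal
  )
}

#' Generate a synthetic tumor-growth caliper table
#'
#' Per-mouse exponential growth from the enrollment volume, with lognormal
#' heterogeneity of the endpoint volume (mean-one, CV = the preset's
#' dispersion) so that the treated endpoint mean equals `endpoint_ratio`
#' times the control endpoint mean in expectation. Volumes are converted to
#' caliper radii assuming the preset's fixed axis aspect ratio, so `R1 <= R2`
#' always holds in the emitted table.
#'
#' @param preset a preset name or [synth_preset()] of type `"tumor"`.
#' @param n_mice_per_group mice per group (>= 2; SEM undefined otherwise).
#' @param n_timepoints number of measurement days spread over the treatment
#'   course.
#' @param seed integer seed.
#' @return A tibble with columns `group`, `mouse`, `day`, `R1_mm`, `R2_mm`.
#' @examples
#' generate_tumor_series("tumor-fig3a", n_mice_per_group = 2,
#'                       n_timepoints = 3, seed = 1)
#' @export
generate_tumor_series <- function(preset, n_mice_per_group = 8,
                                  n_timepoints = 14, seed = 1) {
  preset <- synth_preset(preset)
  if (!identical(preset$type, "tumor")) {
    stop_ihc(sprintf("preset '%s' is not a tumor preset", preset$name),
             "ihcquant_bad_input")
  }
  if (preset$endpoint_ratio <= 0) {
    stop_ihc("preset endpoint ratio must be > 0", "ihcquant_bad_input")
  }
  n <- n_mice_per_group
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    stop_ihc("`n_mice_per_group` must be an integer >= 2 (SEM undefined for n = 1)",
             "ihcquant_bad_input")
  }
  if (n_timepoints < 1) stop_ihc("`n_timepoints` must be >= 1", "ihcquant_bad_input")
  days <- unique(round(seq(0, preset$duration_days, length.out = n_timepoints)))
  endpoint_means <- c(control = preset$control_endpoint_mm3,
                      treated = preset$control_endpoint_mm3 * preset$endpoint_ratio)
  sig <- sqrt(log(1 + preset$dispersion_cv^2))
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map(c("control", "treated"), function(grp) {
      v_end <- endpoint_means[[grp]] * exp(rnorm(n, -sig^2 / 2, sig))
      rate <- log(v_end / preset$v0_mm3) / preset$duration_days
      tidyr::expand_grid(mouse = seq_len(n), day = days) |>
        dplyr::mutate(
          group = grp,
          volume = preset$v0_mm3 * exp(rate[.data$mouse] * .data$day),
          R1_mm = (3 * .data$volume / (4 * pi * preset$aspect_ratio))^(1 / 3),
          R2_mm = preset$aspect_ratio * .data$R1_mm
        )
    })
    dplyr::bind_rows(rows) |>
      dplyr::select("group", "mouse", "day", "R1_mm", "R2_mm")
  })
}

#' Generate synthetic soft-agar colony counts
#'
#' Poisson-distributed colonies per well with the preset's per-dose means
#' (e.g. untreated mean 30 colonies/well, 0.25x control at 0.1 uM, complete
#' inhibition at and above 2.5 uM).
#'
#' @param preset a preset name or [synth_preset()] of type `"colony"`.
#' @param doses doses in uM; defaults to the preset's dose ladder. Doses not
#'   in the preset take the mean of the closest preset dose at or above them
#'   (0 beyond the ladder).
#' @param n_wells wells per dose (>= 1).
#' @param seed integer seed.
#' @return A tibble with columns `dose_uM`, `well`, `count`.
#' @examples
#' generate_colony_counts("colony-fig1b", n_wells = 3, seed = 1)
#' @export
generate_colony_counts <- function(preset, doses = NULL, n_wells = 3, seed = 1) {
  preset <- synth_preset(preset)
  if (!identical(preset$type, "colony")) {
    stop_ihc(sprintf("preset '%s' is not a colony preset", preset$name),
             "ihcquant_bad_input")
  }
  if (n_wells < 1) stop_ihc("`n_wells` must be >= 1", "ihcquant_bad_input")
  doses <- doses %||% preset$doses_uM
  if (any(doses < 0)) stop_ihc("doses must be non-negative", "ihcquant_bad_input")
  mean_at <- function(d) {
    i <- match(d, preset$doses_uM)
    if (!is.na(i)) return(preset$means[i])
    at_or_above <- which(preset$doses_uM >= d)
    if (!length(at_or_above)) return(0)
    preset$means[min(at_or_above)]
  }
  mu <- vapply(doses, mean_at, numeric(1))
  if (any(mu < 0)) stop_ihc("colony mean must be non-negative", "ihcquant_bad_input")
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      dose_uM = rep(doses, each = n_wells),
      well = rep(seq_len(n_wells), times = length(doses)),
      count = rpois(n_wells * length(doses), rep(mu, each = n_wells))
    )
  })
}
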