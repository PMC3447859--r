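#' LDH-release percent cytotoxicity
#'
#' Membrane-integrity readout of the LDH release assay: the lactate
#' dehydrogenase activity released into the culture medium expressed as a
#' percentage of the total LDH measured in a full cell lysate,
#' `100 * released / total`. Vectorized.
#'
#' @param released LDH signal in the medium (absorbance units), >= 0.
#' @param total total-lysate LDH signal, > 0.
#' @return Percent cytotoxicity (numeric vector).
#' @examples
#' percent_cytotoxicity(0.27, 1.8)  # 15%
#' @export
percent_cytotoxicity <- function(released, total) {
  if (any(!is.finite(total)) || any(total <= 0)) {
    stop_ihc("`total` LDH signal must be positive", "ihcquant_bad_input")
  }
  if (any(released < 0)) {
    stop_ihc("`released` LDH signal must be non-negative", "ihcquant_bad_input")
  }
  100 * released / total
}

#' Percent cytotoxicity for an LDH plate table
#'
#' Data-frame interface over [percent_cytotoxicity()] for the `ldh.csv` schema
#' written by [generate_ldh_plate()].
#'
#' @param data a data frame with `released` and `total` columns.
#' @return The input tibble with a `percent_cytotoxicity` column appended.
#' @export
ldh_cytotoxicity <- function(data) {
  for (col in c("released", "total")) {
    if (!col %in% names(data)) {
      stop_ihc(sprintf("column `%s` is required", col), "ihcquant_bad_input")
    }
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    percent_cytotoxicity = percent_cytotoxicity(.data$released, .data$total)
  )
}

#' Tumor volume from two caliper radii
#'
#' Ellipsoid-style caliper formula `V = 4/3 * pi * R1^2 * R2` with the radii
#' canonicalized so that `R1 <= R2` (the smaller radius is squared). Inputs
#' given in the wrong order are sorted, with a warning, rather than rejected:
#' caliper readings do not guarantee axis order. Vectorized; returns mm^3 for
#' radii in mm.
#'
#' @param R1,R2 caliper radii in mm, both positive.
#' @return Tumor volume(s) in mm^3.
#' @examples
#' tumor_volume(1, 2)  # 8*pi/3
#' @export
tumor_volume <- function(R1, R2) {
  if (any(!is.finite(R1)) || any(!is.finite(R2)) || any(R1 <= 0) || any(R2 <= 0)) {
    stop_ihc("caliper radii must be positive", "ihcquant_bad_input")
  }
  swapped <- R1 > R2
  if (any(swapped)) {
    rlang::warn(sprintf(
      "%d caliper pair(s) had R1 > R2; radii canonicalized by sorting", sum(swapped)
    ), class = "ihcquant_canonicalized")
    r1 <- pmin(R1, R2); r2 <- pmax(R1, R2)
  } else {
    r1 <- R1; r2 <- R2
  }
  4 / 3 * pi * r1^2 * r2
}

#' Percent growth inhibition relative to control
#'
#' `100 * (1 - treated / control)`. Negative values indicate stimulation
#' (growth above control, as seen at sub-GI50 doses in some cell types).
#'
#' @param treated_mean,control_mean group means in the same units; control > 0.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(16, 25)  # 36%
#' @export
percent_inhibition <- function(treated_mean, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop_ihc("`control_mean` must be positive", "ihcquant_bad_input")
  }
  100 * (1 - treated_mean / control_mean)
}

#' Percent of untreated control
#'
#' `100 * value / control`, the normalization used for enzymatic activities
#' reported relative to untreated cells.
#'
#' @param value measured quantity (same units as `control`).
#' @param control untreated-control quantity, > 0.
#' @return Percent of control.
#' @examples
#' percent_of_control(2.1, 1)  # 210%
#' @export
percent_of_control <- function(value, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop_ihc("`control` must be positive", "ihcquant_bad_input")
  }
  100 * value / control
}

#' Significance stars for a p-value
#'
#' The conventional mapping: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `ns`.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Unpaired two-tailed t-test with significance stars
#'
#' Student's two-sample t-test with pooled variance (the default reading of an
#' "unpaired two-tailed t-test"; set `welch = TRUE` for the unequal-variance
#' variant). Two groups with zero pooled variance and equal means return
#' `t = 0, p = 1`. Returns a one-row tibble in broom style.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param welch use the Welch (unequal variance) t-test instead of pooled.
#' @return A tibble with columns `t_statistic`, `df`, `p_value`, `stars`.
#' @examples
#' ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
#' @export
ttest_unpaired <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_ihc("each group needs at least 2 observations", "ihcquant_bad_input")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop_ihc("missing values in t-test input", "ihcquant_bad_input")
  }
  df <- if (welch) NA_real_ else length(group_a) + length(group_b) - 2
  res <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # essentially-constant data: zero pooled variance
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      t <- 0; p <- 1
    } else {
      t <- sign(mean(group_a) - mean(group_b)) * Inf; p <- 0
    }
  } else {
    t <- unname(res$statistic)
    p <- res$p.value
    df <- unname(res$parameter)
  }
  tibble::tibble(
    t_statistic = t, df = df, p_value = p, stars = significance_stars(p)
  )
}

#' Per-group mean, SD and SEM
#'
#' Summarizes a measurement column by group: n, mean, SD and the standard
#' error of the mean (SD / sqrt(n)). Both SD and SEM are always computed;
#' report layers pick whichever a figure convention calls for.
#'
#' @param data a data frame.
#' @param value unquoted measurement column.
#' @param group unquoted grouping column.
#' @return A tibble with one row per group: `group`, `n`, `mean`, `sd`, `sem`.
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
#' summarize_groups(d, y, g)
#' @export
summarize_groups <- function(data, value, group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = stats::sd({{ value }}),
      sem = stats::sd({{ value }}) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Two-group comparison with percent change and t-test
#'
#' Compares a treated group against a control group on one measurement:
#' group means, percent change (signed) and percent inhibition
#' (`100 * (1 - treated/control)`), plus the unpaired two-tailed t-test and
#' its significance stars.
#'
#' @inheritParams summarize_groups
#' @param control value of `group` identifying the control; defaults to
#'   `"control"` when present, otherwise the first group level.
#' @param welch passed to [ttest_unpaired()].
#' @return A one-row tibble.
#' @export
compare_groups <- function(data, value, group, control = NULL, welch = FALSE) {
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  lev <- unique(as.character(g))
  if (length(lev) != 2) {
    stop_ihc("`compare_groups()` needs exactly two groups", "ihcquant_bad_input")
  }
  control <- control %||% if ("control" %in% lev) "control" else lev[1]
  if (!control %in% lev) {
    stop_ihc(sprintf("control group '%s' not found", control), "ihcquant_bad_input")
  }
  treated <- setdiff(lev, control)
  yc <- y[g == control]; yt <- y[g == treated]
  if (length(yc) < 2 || length(yt) < 2) {
    stop_ihc("each group needs at least 2 observations", "ihcquant_bad_input")
  }
  tt <- ttest_unpaired(yt, yc, welch = welch)
  tibble::tibble(
    control = control,
    treated = treated,
    n_control = length(yc),
    n_treated = length(yt),
    control_mean = mean(yc),
    treated_mean = mean(yt),
    percent_change = 100 * (mean(yt) - mean(yc)) / mean(yc),
    percent_inhibition = percent_inhibition(mean(yt), mean(yc)),
    t_statistic = tt$t_statistic,
    df = tt$df,
    p_value = tt$p_value,
    stars = tt$stars
  )
}

#' Tumor growth-curve summary from a caliper table
#'
#' Converts per-mouse caliper pairs to volumes with [tumor_volume()], then
#' summarizes mean +/- SD/SEM volume per group and day, and compares the
#' endpoint (last day) means: percent inhibition of the treated group and the
#' unpaired two-tailed t-test.
#'
#' @param data a caliper table with columns `group`, `mouse`, `day`, `R1_mm`,
#'   `R2_mm` (the schema of [generate_tumor_series()]).
#' @param control control group label, defaults as in [compare_groups()].
#' @param welch passed to [ttest_unpaired()].
#' @return An object of class `growth_summary`: a list with `series` (per
#'   group/day tibble) and `endpoint` (one-row comparison tibble);
#'   [tidy()] returns the series, [glance()] the endpoint comparison.
#' @examples
#' tab <- generate_tumor_series(synth_preset("tumor-fig3a"),
#'                              n_mice_per_group = 4, n_timepoints = 3, seed = 1)
#' growth_curve_summary(tab)
#' @export
growth_curve_summary <- function(data, control = NULL, welch = FALSE) {
  req <- c("group", "mouse", "day", "R1_mm", "R2_mm")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop_ihc(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "ihcquant_bad_input")
  }
  d <- tibble::as_tibble(data)
  d$volume_mm3 <- tumor_volume(d$R1_mm, d$R2_mm)
  lev <- unique(as.character(d$group))
  if (length(lev) != 2) {
    stop_ihc("caliper table must contain exactly two groups (control and treated)",
             "ihcquant_bad_input")
  }
  series <- d |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_volume_mm3 = mean(.data$volume_mm3),
      sd = stats::sd(.data$volume_mm3),
      sem = stats::sd(.data$volume_mm3) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  end_day <- max(d$day)
  endpoint_data <- dplyr::filter(d, .data$day == end_day)
  if (length(unique(endpoint_data$group)) != 2) {
    stop_ihc("a group is missing at the endpoint day", "ihcquant_bad_input")
  }
  if (any(table(endpoint_data$group) < 2)) {
    stop_ihc("each group needs >= 2 mice at the endpoint (SEM undefined otherwise)",
             "ihcquant_bad_input")
  }
  endpoint <- compare_groups(endpoint_data, volume_mm3, group,
                             control = control, welch = welch)
  endpoint$day <- end_day
  structure(list(series = series, endpoint = endpoint), class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  e <- x$endpoint
  cat(sprintf(
    "<growth_summary> day %g endpoint: %s mean %.1f mm3 vs %s mean %.1f mm3; inhibition %.1f%%, p = %.3g (%s)\n",
    e$day, e$treated, e$treated_mean, e$control, e$control_mean,
    e$percent_inhibition, e$p_value, e$stars
  ))
  print(x$series)
  invisible(x)
}

#' @export
tidy.growth_summary <- function(x, ...) x$series

#' @export
glance.growth_summary <- function(x, ...) x$endpoint
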