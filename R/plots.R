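#' Plot a fitted dose-response curve
#'
#' Observed counts and the fitted 4PL curve on a log dose axis; the untreated
#' control (dose 0) is drawn at the left edge as a horizontal reference.
#'
#' @param object a `fourpl_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fourpl_fit <- function(object, ...) {
  d <- object$data
  pos <- d$dose[d$dose > 0]
  xmin <- min(pos) / 3
  curve_x <- exp(seq(log(xmin), log(max(pos) * 1.5), length.out = 200))
  curve <- tibble::tibble(dose = curve_x, response = predict(object, curve_x))
  pts <- dplyr::mutate(d, dose = ifelse(.data$dose == 0, xmin, .data$dose))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_hline(yintercept = mean(d$response[d$dose == 0]),
                        linetype = "dotted", color = "grey50") +
    ggplot2::geom_line(data = curve, color = "#2166ac") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM, log scale; control at left edge)",
                  y = "response",
                  title = sprintf("4PL fit: EC50 %.3g uM, hill %.2f",
                                  object$ec50, object$hill)) +
    ggplot2::theme_minimal()
}

#' Plot a segmentation result
#'
#' Positive mask as a raster; with a ground truth, false positives and false
#' negatives are shown in their own colors.
#'
#' @param object an `ihc_segmentation`.
#' @param truth optional [ground_truth()] for an agreement overlay.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ihc_segmentation <- function(object, truth = NULL, ...) {
  m <- object$mask
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  if (is.null(truth)) {
    d$class <- ifelse(as.vector(m[cbind(d$row, d$col)]), "positive", "background")
    pal <- c(background = "grey92", positive = "#8c510a")
  } else {
    s <- m[cbind(d$row, d$col)]; g <- truth$mask[cbind(d$row, d$col)]
    d$class <- dplyr::case_when(
      s & g ~ "true positive", s & !g ~ "false positive",
      !s & g ~ "false negative", TRUE ~ "background"
    )
    pal <- c(background = "grey92", `true positive` = "#8c510a",
             `false positive` = "#d73027", `false negative` = "#4575b4")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("'%s': %.1f%% positive (alpha* %.2f, T %d)",
                                  object$field_id, 100 * object$area_fraction,
                                  object$params$alpha, object$threshold),
                  x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot tumor growth curves
#'
#' Per-group mean volume with SEM error bars over treatment days.
#'
#' @param object a `growth_summary` from [growth_curve_summary()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.growth_summary <- function(object, ...) {
  e <- object$endpoint
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$day, y = .data$mean_volume_mm3,
                               color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_volume_mm3 - .data$sem,
      ymax = .data$mean_volume_mm3 + .data$sem
    ), width = 0.8) +
    ggplot2::labs(x = "day of treatment", y = "tumor volume (mm3, mean +/- SEM)",
                  title = sprintf("Endpoint inhibition %.1f%% (p = %.3g %s)",
                                  e$percent_inhibition, e$p_value, e$stars)) +
    ggplot2::theme_minimal()
}

#' Plot an LDH cytotoxicity time course
#'
#' Percent cytotoxicity (released/total LDH) versus time per condition.
#'
#' @param data an LDH table with `condition`, `time_h`, `released`, `total`.
#' @return A ggplot object.
#' @export
plot_ldh_timecourse <- function(data) {
  d <- ldh_cytotoxicity(data)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h,
                                  y = .data$percent_cytotoxicity,
                                  color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time after treatment (h)", y = "cytotoxicity (% of total LDH)") +
    ggplot2::theme_minimal()
}
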