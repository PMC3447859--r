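#' Four-parameter logistic (4PL) dose-response model
#'
#' The package models dose-response curves as
#' \deqn{y(x) = bottom + \frac{top - bottom}{1 + (x/ec50)^{-hill}}}
#' following the dose-response sign convention: a negative Hill slope gives a
#' descending (growth-inhibition) curve with `y(0) = top` exactly, a positive
#' slope an ascending one with `y(0) = bottom`. `ec50` is the dose at the
#' half-way response between the asymptotes.
#'
#' @param bottom,top response asymptotes (response units).
#' @param ec50 dose of half-maximal effect, must be positive (uM).
#' @param hill Hill slope; sign encodes direction (negative = inhibition).
#' @return `fourpl()` returns a parameter bundle of class `fourpl_params`.
#' @examples
#' p <- fourpl(bottom = 0, top = 1000, ec50 = 1.24, hill = -1.5)
#' fourpl_response(c(0, 1.24, 100), p$bottom, p$top, p$ec50, p$hill)
#' @export
fourpl <- function(bottom, top, ec50, hill) {
  if (!is.numeric(ec50) || length(ec50) != 1 || !is.finite(ec50) || ec50 <= 0) {
    stop_ihc("`ec50` must be a positive number", "ihcquant_bad_input")
  }
  for (v in list(bottom, top, hill)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop_ihc("4PL parameters must be finite scalars", "ihcquant_bad_input")
    }
  }
  structure(
    list(bottom = bottom, top = top, ec50 = ec50, hill = hill),
    class = "fourpl_params"
  )
}

#' @rdname fourpl
#' @param dose numeric vector of non-negative doses (uM).
#' @export
fourpl_response <- function(dose, bottom, top, ec50, hill) {
  if (any(dose < 0)) stop_ihc("doses must be non-negative", "ihcquant_bad_input")
  if (ec50 <= 0) stop_ihc("`ec50` must be positive", "ihcquant_bad_input")
  # exponent -hill: dose 0 maps to `top` for hill < 0 and `bottom` for hill > 0
  u <- (dose / ec50)^(-hill)
  bottom + (top - bottom) / (1 + u)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model (see [fourpl()]) to a tidy table of doses
#' and responses. The design must contain at least four distinct doses
#' including the untreated control (dose 0), which anchors the `top` asymptote
#' of an inhibition curve. Initialization: `top` = mean response at dose 0,
#' `bottom` = mean response at the largest dose, `ec50` = geometric mid-dose,
#' `hill` = -1; the optimizer runs until the relative change in the residual
#' sum of squares falls below 1e-10 or 500 iterations. Parameters are
#' canonicalized so that `top >= bottom` (swapping flips the sign of `hill`,
#' which leaves the curve unchanged).
#'
#' @param data a data frame with dose and response columns.
#' @param dose,response unquoted column names (doses in uM, responses >= 0).
#' @return An object of class `fourpl_fit` with elements `bottom`, `top`,
#'   `ec50`, `hill`, `residual_sse`, `converged` and the fitted data; supports
#'   [tidy()], [glance()], [predict()] and [autoplot()].
#' @seealso [gi50()] for the closed-form inversion at half the control response.
#' @examples
#' d <- generate_dose_response(fourpl(0, 1000, 1.24, -1.5),
#'                             doses = c(0, 0.1, 0.3, 1, 3, 10, 15), cv = 0)
#' fit <- fit_4pl(d, dose_uM, count)
#' tidy(fit)
#' @export
fit_4pl <- function(data, dose, response) {
  d <- rlang::eval_tidy(rlang::enquo(dose), data)
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  if (!is.numeric(d) || !is.numeric(y) || length(d) != length(y) || length(d) == 0) {
    stop_ihc("dose and response must be numeric columns of equal length",
             "ihcquant_bad_input")
  }
  if (anyNA(d) || anyNA(y)) stop_ihc("missing values in dose/response", "ihcquant_bad_input")
  if (any(d < 0)) stop_ihc("doses must be non-negative", "ihcquant_bad_input")
  if (any(y < 0)) stop_ihc("responses must be non-negative", "ihcquant_bad_input")
  if (length(unique(d)) < 4) {
    stop_ihc("at least 4 distinct doses are required", "ihcquant_fit_error")
  }
  if (!any(d == 0)) {
    stop_ihc("the design must include the untreated control (dose 0)",
             "ihcquant_fit_error")
  }
  yscale <- max(abs(y), 1)
  if (diff(range(y)) < 1e-12 * yscale) {
    stop_ihc("responses are flat: ec50 is unidentifiable", "ihcquant_fit_error")
  }

  pos <- d[d > 0]
  start <- list(
    bottom = mean(y[d == max(d)]),
    top = mean(y[d == 0]),
    log_ec50 = log(sqrt(min(pos) * max(pos))),
    hill = -1
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fourpl_response(d, bottom, top, exp(log_ec50), hill),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    ),
    error = function(e) {
      stop_ihc(paste0("4PL fit did not converge: ", conditionMessage(e)),
               "ihcquant_fit_error")
    }
  )
  co <- coef(fit)
  est <- list(bottom = unname(co["bottom"]), top = unname(co["top"]),
              ec50 = exp(unname(co["log_ec50"])), hill = unname(co["hill"]))
  se <- tryCatch({
    s <- summary(fit)$coefficients[, "Std. Error"]
    c(bottom = unname(s["bottom"]), top = unname(s["top"]),
      ec50 = est$ec50 * unname(s["log_ec50"]), hill = unname(s["hill"]))
  }, error = function(e) rep(NA_real_, 4))

  # canonical orientation: top >= bottom, curve unchanged under the swap
  if (est$top < est$bottom) {
    tmp <- est$bottom; est$bottom <- est$top; est$top <- tmp
    est$hill <- -est$hill
    se <- se[c(2, 1, 3, 4)]
  }
  boundary <- abs(est$hill) >= 50
  if (boundary) {
    rlang::warn(sprintf(
      "4PL fit hit a boundary (|hill| = %.1f): step-like data, parameters unreliable",
      abs(est$hill)
    ), class = "ihcquant_boundary_fit")
  }
  structure(
    list(
      bottom = est$bottom, top = est$top, ec50 = est$ec50, hill = est$hill,
      std_error = se,
      residual_sse = sum(stats::resid(fit)^2),
      n = length(y),
      converged = !boundary,
      data = tibble::tibble(dose = d, response = y),
      dose_range = c(min(pos), max(d))
    ),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> bottom %.4g, top %.4g, ec50 %.4g uM, hill %.3g (SSE %.4g, n %d%s)\n",
    x$bottom, x$top, x$ec50, x$hill, x$residual_sse, x$n,
    if (x$converged) "" else ", boundary"
  ))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    newdata[[1]]
  } else {
    newdata
  }
  fourpl_response(d, object$bottom, object$top, object$ec50, object$hill)
}

#' @export
predict.fourpl_params <- function(object, newdata = NULL, ...) {
  d <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  fourpl_response(d, object$bottom, object$top, object$ec50, object$hill)
}

#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    term = c("bottom", "top", "ec50", "hill"),
    estimate = c(x$bottom, x$top, x$ec50, x$hill),
    std.error = unname(x$std_error)
  )
}

#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    residual_sse = x$residual_sse,
    sigma = sqrt(x$residual_sse / max(x$n - 4, 1)),
    converged = x$converged
  )
}

#' Growth-inhibitory concentration GI50
#'
#' Inverts a fitted (or given) 4PL curve at half the untreated-control response:
#' the returned dose `x` satisfies `predict(fit, x) == control_mean / 2`
#' (closed form, no root search). Fails with a "GI50 not reached" error when
#' the curve never crosses that level, or when the crossing lies outside the
#' observed dose range extended tenfold -- mirroring assay reports where no
#' GI50 is attained at the maximal tested concentration.
#'
#' @param fit a `fourpl_fit` or `fourpl_params` object.
#' @param control_mean mean response of the untreated (dose 0) control.
#' @return The GI50 in uM (scalar).
#' @examples
#' p <- fourpl(bottom = 0, top = 400, ec50 = 2, hill = -1)
#' gi50(p, control_mean = 400)  # equals ec50 when bottom = 0, top = control
#' @export
gi50 <- function(fit, control_mean) {
  if (!inherits(fit, c("fourpl_fit", "fourpl_params"))) {
    stop_ihc("`fit` must be a fourpl_fit or fourpl_params object", "ihcquant_bad_input")
  }
  if (!is.numeric(control_mean) || length(control_mean) != 1 || control_mean <= 0) {
    stop_ihc("`control_mean` must be a positive scalar", "ihcquant_bad_input")
  }
  target <- control_mean / 2
  if (fit$hill == 0) {
    stop_ihc("GI50 not reached: flat curve (hill = 0)", "ihcquant_gi50_error")
  }
  lo <- min(fit$bottom, fit$top); hi <- max(fit$bottom, fit$top)
  if (target <= lo || target >= hi) {
    stop_ihc(sprintf(
      "GI50 not reached: half the control response (%.4g) lies outside the curve range [%.4g, %.4g]",
      target, lo, hi
    ), "ihcquant_gi50_error")
  }
  ratio <- (fit$top - target) / (target - fit$bottom)
  x <- fit$ec50 * ratio^(-1 / fit$hill)
  rng <- fit$dose_range
  if (!is.null(rng)) {
    if (x > 10 * rng[2] || x < rng[1] / 10) {
      stop_ihc(sprintf(
        "GI50 not reached within the observed dose range extended 10x (crossing at %.4g uM)", x
      ), "ihcquant_gi50_error")
    }
  }
  x
}
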