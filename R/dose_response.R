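# Dose-response analysis of a locomotor endpoint.
#
# The model is the classic log-inhibitor vs normalized-response curve:
#   Y(x) = 100 / (1 + 10^((x - logEC50) * s)),  x = log10(concentration)
# where Y is the endpoint expressed as percent of the untreated control and
# s is the (Hill) slope, fixed at 1 by default. The EC50 — the concentration
# halving the endpoint — is estimated on the log10 scale with a t-based
# asymptotic 95% CI, then back-transformed to concentration units.

#' Normalise an endpoint to percent of control
#'
#' @param values Numeric endpoint values for treated cells.
#' @param control_values Endpoint values of the zero-dose control set.
#' @param center `"mean"` (default) or `"median"`: the control central value
#'   defining 100%.
#' @return `100 * values / center(control_values)`.
#' @export
normalize_to_control <- function(values, control_values, center = c("mean", "median")) {
  center <- match.arg(center)
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0) abort("Control set is empty.")
  c0 <- if (center == "mean") mean(control_values) else median(control_values)
  if (!is.finite(c0) || c0 <= 0) {
    abort("Control central value must be positive to define 100%.")
  }
  100 * values / c0
}

dr_model <- function(x, log_ec50, s) 100 / (1 + 10^((x - log_ec50) * s))

#' Fit the log-inhibitor vs normalized-response model
#'
#' Least-squares fit of the percent-of-control response against log10
#' concentration. Zero-concentration rows (the control used for the
#' normalisation) have no finite log concentration and are excluded from the
#' fit. By default each row — typically one cell — is weighted equally; pass
#' group means if aggregation per concentration is wanted.
#'
#' @param data Data frame with a concentration column and a percent-response
#'   column.
#' @param conc Column with concentrations (uM); tidy-eval.
#' @param response Column with normalised responses (percent); tidy-eval.
#' @param slope_mode `"standard"` fixes the slope at 1 (the named normalized-
#'   response model); `"variable"` also fits the slope.
#' @param ci_method `"robust"` (default) uses a heteroscedasticity-consistent
#'   sandwich standard error for logEC50 — per-cell responses have variance
#'   that grows with the response level, since cell-to-cell variability is
#'   multiplicative — while `"classical"` uses the ordinary least-squares
#'   asymptotic standard error.
#' @return A `dose_response_fit` object with fields `log_ec50`, `ec50`,
#'   `ci95_low`, `ci95_high` (uM), `hill_slope`, `residual_ss`, `converged`,
#'   `identifiable`, and `curve` (the fitted curve sampled on a log grid).
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' conc <- c(0.5, 5, 50, 500, 5000)
#' resp <- 100 / (1 + 10^(log10(conc) - log10(50)))
#' fit <- fit_dose_response(data.frame(conc = conc, resp = resp), conc, resp)
#' fit$ec50
#' @export
fit_dose_response <- function(data, conc, response, slope_mode = c("standard", "variable"),
                              ci_method = c("robust", "classical")) {
  slope_mode <- match.arg(slope_mode)
  ci_method <- match.arg(ci_method)
  conc_v <- unname(dplyr::pull(data, {{ conc }}))
  resp_v <- unname(dplyr::pull(data, {{ response }}))
  keep <- is.finite(conc_v) & conc_v > 0 & is.finite(resp_v)
  x <- log10(conc_v[keep])
  y <- resp_v[keep]
  n_distinct <- length(unique(x))
  if (n_distinct < 3) {
    abort("Need at least 3 distinct nonzero concentrations to fit a dose-response curve.")
  }

  # start where the observed response crosses 50%
  start_log <- unname(x[which.min(abs(y - 50))])
  df_fit <- data.frame(x = x, y = y)
  fml <- if (slope_mode == "standard") {
    y ~ 100 / (1 + 10^(x - log_ec50))
  } else {
    y ~ 100 / (1 + 10^((x - log_ec50) * s))
  }
  start <- if (slope_mode == "standard") list(log_ec50 = start_log) else list(log_ec50 = start_log, s = 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df_fit, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    out <- list(
      log_ec50 = NA_real_, ec50 = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
      hill_slope = if (slope_mode == "standard") 1 else NA_real_,
      residual_ss = NA_real_, converged = FALSE, identifiable = FALSE,
      slope_mode = slope_mode, n = length(y), curve = NULL, fit = NULL
    )
    return(structure(out, class = "dose_response_fit"))
  }

  est <- coef(fit)
  se <- tryCatch({
    if (ci_method == "classical") {
      sqrt(diag(vcov(fit))[["log_ec50"]])
    } else {
      # HC sandwich on the nls gradient: bread (J'J)^-1, meat J' diag(e^2) J
      grad <- fit$m$gradient()
      e2 <- resid(fit)^2
      bread <- solve(crossprod(grad))
      vc <- bread %*% crossprod(grad * sqrt(e2)) %*% bread
      sqrt(diag(vc))[[which(names(est) == "log_ec50")]]
    }
  }, error = function(e) NA_real_)
  dof <- length(y) - length(est)
  half <- qt(0.975, dof) * se
  log_ec50 <- est[["log_ec50"]]
  ci_log <- c(log_ec50 - half, log_ec50 + half)
  # identifiable only if the estimate interpolates the tested concentrations
  # and the CI does not span the whole tested range
  tested <- range(x)
  identifiable <- is.finite(se) &&
    log_ec50 >= tested[1] && log_ec50 <= tested[2] &&
    diff(ci_log) < diff(tested)

  grid <- seq(tested[1] - 0.5, tested[2] + 0.5, length.out = 200)
  s_hat <- if (slope_mode == "standard") 1 else est[["s"]]
  curve <- tibble(
    log10_conc = grid,
    conc_uM = 10^grid,
    response_pct = dr_model(grid, log_ec50, s_hat)
  )

  structure(
    list(
      log_ec50 = log_ec50,
      ec50 = 10^log_ec50,
      ci95_low = 10^ci_log[1],
      ci95_high = 10^ci_log[2],
      hill_slope = s_hat,
      residual_ss = sum(resid(fit)^2),
      converged = isTRUE(fit$convInfo$isConv),
      identifiable = identifiable,
      slope_mode = slope_mode,
      n = length(y),
      curve = curve,
      fit = fit
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<dose_response_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<dose_response_fit> EC50 = %.4g uM (95%% CI %.4g-%.4g), slope = %.3g, n = %d%s\n",
    x$ec50, x$ci95_low, x$ci95_high, x$hill_slope, x$n,
    if (x$identifiable) "" else " [poorly identified]"
  ))
  invisible(x)
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(
    term = "ec50_uM",
    estimate = x$ec50,
    conf.low = x$ci95_low,
    conf.high = x$ci95_high,
    log_estimate = x$log_ec50
  )
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(
    ec50_uM = x$ec50, ci95_low = x$ci95_low, ci95_high = x$ci95_high,
    hill_slope = x$hill_slope, residual_ss = x$residual_ss,
    n = x$n, converged = x$converged, identifiable = x$identifiable
  )
}

#' @export
autoplot.dose_response_fit <- function(object, ...) {
  if (is.null(object$curve)) abort("No fitted curve to plot (fit did not converge).")
  obs <- tibble(
    x = object$fit$m$getEnv()$x,
    y = object$fit$m$getEnv()$y
  )
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$log10_conc, y = .data$response_pct)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = obs, ggplot2::aes(x = .data$x, y = .data$y), alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$log_ec50, linetype = "dashed") +
    ggplot2::labs(
      x = "log10 concentration (uM)", y = "response (% of control)",
      title = sprintf("EC50 = %.3g uM", object$ec50)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname fit_dose_response
#' @param x A `dose_response_fit`.
#' @param path Output path for the fit JSON / curve CSV.
#' @export
write_dose_response_json <- function(x, path) {
  jsonlite::write_json(
    list(
      log_ec50 = x$log_ec50, ec50_uM = x$ec50,
      ci95_low_uM = x$ci95_low, ci95_high_uM = x$ci95_high,
      hill_slope = x$hill_slope, residual_ss = x$residual_ss,
      n = x$n, converged = x$converged, identifiable = x$identifiable,
      slope_mode = x$slope_mode
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
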