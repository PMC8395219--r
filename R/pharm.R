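#' Hill-equation dose-response fit
#'
#' Nonlinear least squares of
#' `f(x) = bottom + (top - bottom) / (1 + (EC50 / x)^n)`
#' fitted in log-EC50 space with the span `top - bottom` constrained
#' non-negative (so `top >= bottom` by parameterization) and the Hill
#' coefficient in (0, 10]. Initial guesses come from the data quartiles:
#' bottom and top from the response extremes, EC50 from the concentration
#' nearest the half response.
#'
#' @param concentrations Positive concentrations (>= 4 distinct values).
#' @param responses Responses, same length.
#' @return Object of class `hill_fit`: `bottom`, `top`, `EC50`, `n`,
#'   `vcov` (internal parameterization: bottom, span, log EC50, n),
#'   `converged`, and the underlying `nls` object.
#' @export
hill_fit <- function(concentrations, responses) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses differ in length", call. = FALSE)
  ok <- is.finite(concentrations) & is.finite(responses)
  x <- concentrations[ok]; y <- responses[ok]
  if (any(x <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(unique(x)) < 4)
    stop("need >= 4 distinct concentrations", call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("responses are constant; returning a degenerate flat fit")
    return(structure(list(bottom = y[1], top = y[1], EC50 = NA_real_,
                          n = NA_real_, vcov = NULL, converged = FALSE,
                          degenerate = TRUE, fit = NULL,
                          data = data.frame(concentration = x, response = y)),
                     class = "hill_fit"))
  }
  mg <- tapply(y, x, mean)
  xs <- as.numeric(names(mg))
  bot0 <- min(mg); top0 <- max(mg)
  half <- (bot0 + top0) / 2
  ec0 <- xs[which.min(abs(mg - half))]
  d <- data.frame(x = x, y = y)
  fit <- try(minpack.lm::nlsLM(
    y ~ bottom + span / (1 + (exp(lec50) / x)^n),
    data = d,
    start = list(bottom = bot0, span = max(top0 - bot0, 1e-8),
                 lec50 = log(ec0), n = 1),
    lower = c(-Inf, 0, log(min(x)) - 10, 1e-3),
    upper = c(Inf, Inf, log(max(x)) + 10, 10),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Hill fit did not converge (starts: bottom=", signif(bot0, 3),
         ", top=", signif(top0, 3), ", EC50=", signif(ec0, 3), ")", call. = FALSE)
  cf <- stats::coef(fit)
  structure(list(bottom = unname(cf["bottom"]),
                 top = unname(cf["bottom"] + cf["span"]),
                 EC50 = unname(exp(cf["lec50"])),
                 n = unname(cf["n"]),
                 vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
                 converged = TRUE, degenerate = FALSE, fit = fit,
                 data = data.frame(concentration = x, response = y)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<hill_fit> degenerate (constant responses), level =", x$bottom, "\n")
    return(invisible(x))
  }
  cat("<hill_fit> EC50 = ", signif(x$EC50, 4), ", n = ", signif(x$n, 3),
      ", bottom = ", signif(x$bottom, 4), ", top = ", signif(x$top, 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(bottom = object$bottom, top = object$top, EC50 = object$EC50, n = object$n)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$concentration
       else if (is.data.frame(newdata)) newdata$concentration
       else newdata
  object$bottom + (object$top - object$bottom) / (1 + (object$EC50 / x)^object$n)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration, d$response, log = "x",
                 xlab = "concentration", ylab = "response", ...)
  xx <- exp(seq(log(min(d$concentration)), log(max(d$concentration)),
                length.out = 200))
  graphics::lines(xx, predict(x, xx))
  invisible(x)
}

#' Normalized peak response of a fluorescence trace
#'
#' `max(trace after stimulation) / mean(trace in the baseline window)` —
#' the per-well readout of plate-reader calcium mobilization assays, fed
#' into [hill_fit()] across a concentration series.
#'
#' @param trace Numeric fluorescence time series.
#' @param baseline_window Indices of the pre-stimulation baseline.
#' @param stim_index First index after stimulation (defaults to the sample
#'   after the baseline window).
#' @return Normalized peak (dimensionless).
#' @export
peak_response <- function(trace, baseline_window, stim_index = max(baseline_window) + 1L) {
  if (max(baseline_window) >= stim_index)
    stop("baseline window must precede the stimulation index", call. = FALSE)
  base <- mean(trace[baseline_window])
  if (!is.finite(base) || base == 0) stop("zero or invalid baseline", call. = FALSE)
  max(trace[stim_index:length(trace)]) / base
}

#' Specific binding from total and nonspecific curves
#'
#' Pointwise difference between total and nonspecific binding measured on
#' matched concentration grids (negative differences floored at zero with
#' a warning), followed by a Hill fit of the specific component.
#'
#' @param concentrations Shared concentration grid.
#' @param total,nonspecific Binding signals on that grid.
#' @return List with `specific` (data frame) and `fit` (a [hill_fit()]).
#' @export
specific_binding <- function(concentrations, total, nonspecific) {
  if (length(total) != length(concentrations) ||
      length(nonspecific) != length(concentrations))
    stop("concentration grids do not match", call. = FALSE)
  spec <- total - nonspecific
  if (any(spec < 0)) {
    warning("negative specific binding floored at 0")
    spec[spec < 0] <- 0
  }
  fit <- hill_fit(concentrations, spec)
  list(specific = data.frame(concentration = concentrations, specific = spec),
       fit = fit)
}
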