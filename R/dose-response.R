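#' Four-parameter logistic dose-response fit
#'
#' Least-squares 4PL fit on log10 dose:
#' `y = bottom + (top - bottom) / (1 + 10^(hill * (log10(IC50) - log10(x))))`.
#' The fit is multi-start (a grid of IC50 and Hill-slope initial values via
#' Levenberg-Marquardt) and the best sum of squared errors wins. The
#' reported IC50 is the relative (inflection-point) IC50. A flat response
#' (variance below tolerance) or a degenerate solution (span collapsed to
#' ~0) is returned with `converged = FALSE` and an undefined IC50.
#'
#' @param dose Concentrations (same units as the IC50 you want back,
#'   e.g. nM); at least 4 distinct positive values.
#' @param response Percent killing at each dose.
#' @return An object of class `dose_response_fit` with elements `bottom`,
#'   `top`, `ic50`, `hill`, `sse`, `converged`, `data`.
#' @export
fit_dose_response <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]
  response <- response[keep]
  if (any(dose <= 0)) abort("Doses must be positive.")
  if (length(unique(dose)) < 4) abort("Need >= 4 distinct positive doses.")
  dat <- tibble(dose = dose, response = response)

  flat_tol <- 1e-8
  span <- diff(range(response))
  if (var(response) < flat_tol) {
    return(new_dose_response_fit(mean(response), mean(response), NA_real_,
                                 NA_real_, 0, FALSE, dat))
  }

  lx <- log10(dose)
  # starting grids: IC50 across the observed dose range, both hill signs
  start_li <- unique(stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE))
  start_hill <- c(0.5, 1, 2, -1)
  best <- NULL
  for (li in start_li) {
    for (h in start_hill) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          response ~ bottom + (top - bottom) /
            (1 + 10^(hill * (li50 - log10(dose)))),
          data = dat,
          start = list(bottom = min(response), top = max(response),
                       li50 = li, hill = h),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      sse <- sum(resid(fit)^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(fit = fit, sse = sse)
      }
    }
  }
  if (is.null(best)) {
    return(new_dose_response_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                                 NA_real_, FALSE, dat))
  }
  p <- coef(best$fit)
  bottom <- unname(p["bottom"]); top <- unname(p["top"])
  hill <- unname(p["hill"]); ic50 <- 10^unname(p["li50"])
  # normalize so bottom <= top (flip is a reparameterisation of the 4PL)
  if (bottom > top) {
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  degenerate <- (top - bottom) < 1e-6 * max(1, span)
  new_dose_response_fit(bottom, top, if (degenerate) NA_real_ else ic50,
                        hill, best$sse, !degenerate, dat,
                        fit = best$fit)
}

new_dose_response_fit <- function(bottom, top, ic50, hill, sse, converged,
                                  data, fit = NULL) {
  structure(
    list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
         sse = sse, converged = converged, data = data, fit = fit),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit\n")
  if (x$converged) {
    cat(sprintf("  IC50: %.4g  hill: %.3g  bottom: %.3g  top: %.3g  SSE: %.4g\n",
                x$ic50, x$hill, x$bottom, x$top, x$sse))
  } else {
    cat("  not converged (flat or degenerate response)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble(
    term = c("bottom", "top", "ic50", "hill"),
    estimate = c(x$bottom, x$top, x$ic50, x$hill)
  )
}

#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, bottom = x$bottom, top = x$top,
         sse = x$sse, converged = x$converged, n = nrow(x$data))
}
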