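## Confirmation-stage percent-inhibition filtering and least-squares
## four-parameter logistic (4PL) IC50 estimation.

#' Four-parameter logistic response
#'
#' `R(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`; at `c = ic50`
#' the response is the midpoint of the plateaus.
#'
#' @param conc Concentrations (uM).
#' @param bottom,top Plateaus (% of control).
#' @param hill Hill coefficient (> 0 for a decreasing curve).
#' @param ic50 Half-maximal inhibitory concentration (uM).
#' @export
four_pl <- function(conc, bottom, top, hill, ic50) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Percent inhibition and the re-screen filter
#'
#' Inhibition is `100 - response` on the percent-of-control scale; compounds
#' with inhibition strictly greater than 25% pass the confirmation filter.
#'
#' @param response_pct Response as percent of the vehicle control.
#' @return Tibble: `inhibition_pct`, `passes_filter`.
#' @export
percent_inhibition <- function(response_pct) {
  inhibition <- 100 - response_pct
  tibble::tibble(inhibition_pct = inhibition, passes_filter = inhibition > 25)
}

#' Least-squares 4PL fit of a dose-response series
#'
#' Minimizes the residual sum of squares of the four-parameter logistic with
#' IC50 parameterized on the log10 scale, multi-start initialization over an
#' IC50 grid spanning the observed concentration range, and box constraints
#' (hill in `[0.2, 10]`, bottom in `[-10, 50]`%, top in `[50, 150]`%). The
#' fit is reported as non-converged when the optimizer fails, when the IC50
#' runs out of `[min conc / 100, max conc * 100]`, or when the data carry no
#' downward trend.
#'
#' @param series Tibble with `concentration_um` and `response_pct` (>= 4
#'   distinct positive concentrations).
#' @param init Optional named starting values
#'   (`bottom`, `top`, `hill`, `ic50_um`), added to the multi-start set.
#' @return A `four_pl_fit` list: `bottom_pct`, `top_pct`, `hill`, `ic50_um`,
#'   `rss`, `converged`, `reason`, `n_points`.
#' @export
fit_4pl <- function(series, init = NULL) {
  conc <- series$concentration_um
  resp <- series$response_pct
  if (any(!is.finite(conc)) || any(!is.finite(resp))) {
    cs_abort("concentrations and responses must be finite", "parameter_error")
  }
  if (any(conc <= 0)) cs_abort("concentrations must be positive", "parameter_error")
  if (length(unique(conc)) < 4) {
    cs_abort("at least 4 distinct concentrations are required", "parameter_error")
  }

  fail <- function(reason) {
    structure(list(bottom_pct = NA_real_, top_pct = NA_real_, hill = NA_real_,
                   ic50_um = NA_real_, rss = NA_real_, converged = FALSE,
                   reason = reason, n_points = length(conc)),
              class = "four_pl_fit")
  }
  if (diff(range(resp)) < 1e-8 * max(1, abs(mean(resp)))) {
    return(fail("flat response"))
  }
  means <- tapply(resp, conc, mean)
  means <- means[order(as.numeric(names(means)))]
  if (all(diff(means) >= 0) && tail(means, 1) > head(means, 1)) {
    return(fail("no downward trend"))
  }

  lower <- c(bottom = -10, top = 50, hill = 0.2,
             lic50 = log10(min(conc)) - 2)
  upper <- c(bottom = 50, top = 150, hill = 10,
             lic50 = log10(max(conc)) + 2)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

  rss_fn <- function(par) {
    r <- resp - four_pl(conc, par[1], par[2], par[3], 10^par[4])
    sum(r * r)
  }

  starts <- list()
  b0 <- clamp(min(resp), lower[1], upper[1])
  t0 <- clamp(max(resp), lower[2], upper[2])
  for (lic in seq(log10(min(conc)), log10(max(conc)), length.out = 5)) {
    for (h in c(0.5, 1, 2)) {
      starts[[length(starts) + 1L]] <- c(b0, t0, h, lic)
    }
  }
  if (!is.null(init)) {
    starts[[length(starts) + 1L]] <- c(
      clamp(init[["bottom"]], lower[1], upper[1]),
      clamp(init[["top"]], lower[2], upper[2]),
      clamp(init[["hill"]], lower[3], upper[3]),
      clamp(log10(init[["ic50_um"]]), lower[4], upper[4]))
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(fail("optimizer failed"))
  # polish from the best start; an occasional abnormal line-search exit on
  # one restart must not mark an otherwise clean optimum as failed
  polish <- tryCatch(
    optim(best$par, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 1000)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) {
    polish$convergence <- min(polish$convergence, best$convergence)
    best <- polish
  } else if (!is.null(polish) && polish$convergence == 0 &&
             polish$value <= best$value * (1 + 1e-8)) {
    best$convergence <- 0L
  }

  ic50 <- 10^best$par[4]
  out_of_range <- ic50 < min(conc) / 100 || ic50 > max(conc) * 100
  structure(list(bottom_pct = unname(best$par[1]), top_pct = unname(best$par[2]),
                 hill = unname(best$par[3]), ic50_um = unname(ic50),
                 rss = best$value,
                 converged = best$convergence == 0 && !out_of_range,
                 reason = if (out_of_range) "IC50 outside supported range" else "ok",
                 n_points = length(conc)),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<four_pl_fit> IC50 = %.3g uM (hill %.2f, bottom %.1f%%, top %.1f%%, RSS %.3g)\n",
                x$ic50_um, x$hill, x$bottom_pct, x$top_pct, x$rss))
  } else {
    cat(sprintf("<four_pl_fit> not converged: %s\n", x$reason))
  }
  invisible(x)
}

#' Predict from a 4PL fit
#' @param object A `four_pl_fit`.
#' @param conc Concentrations (uM).
#' @param ... Unused.
#' @export
predict.four_pl_fit <- function(object, conc, ...) {
  four_pl(conc, object$bottom_pct, object$top_pct, object$hill, object$ic50_um)
}
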