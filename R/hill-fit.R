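#' Fit configuration for Hill models
#'
#' @param fix_r0,fix_rmax fix the baseline / maximum at the given value
#'   (`NULL` = free). Normalized data are conveniently fitted with
#'   `fix_rmax = 1`.
#' @param n_bounds bounds for the Hill coefficient.
#' @param ec50_upper_factor upper EC50 bound as a multiple of the highest
#'   concentration.
#' @param n_init starting Hill coefficient.
#' @param maxiter maximum Levenberg-Marquardt iterations.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(fix_r0 = NULL, fix_rmax = NULL, n_bounds = c(0.3, 10),
                       ec50_upper_factor = 10, n_init = 2, maxiter = 200) {
  structure(list(fix_r0 = fix_r0, fix_rmax = fix_rmax, n_bounds = n_bounds,
                 ec50_upper_factor = ec50_upper_factor, n_init = n_init,
                 maxiter = maxiter),
            class = "fit_config")
}

#' Normalize a dose-response to its maximal mean response
#'
#' Divides every replicate response by the mean response at the
#' concentration whose mean is highest, so the normalized maximal mean is
#' exactly 1 -- the normalization applied to population concentration-
#' response curves before Hill fitting. EC50 and Hill coefficient are
#' invariant under this rescaling.
#'
#' @param dr a [dose_response()].
#' @return The normalized `dose_response`.
#' @export
normalize_to_max <- function(dr) {
  .assert(inherits(dr, "dose_response"), "dr must be a dose_response")
  means <- tapply(dr$data$response, dr$data$conc_mM, mean)
  top <- max(means)
  .assert(is.finite(top) && top > 0, "no positive responses to normalize to")
  dr$data$response <- dr$data$response / top
  dr
}

#' IP1 percent inhibition
#'
#' The competition-assay transform: percent inhibition of IP1-HRP binding =
#' `(1 - stimulated / unstimulated) * 100`. More accumulated IP1 displaces
#' more tracer, so higher inhibition means stronger receptor activation.
#'
#' @param stimulated IP1-HRP binding in stimulated cells (vector).
#' @param unstimulated IP1-HRP binding in unstimulated cells (> 0 scalar or
#'   vector).
#' @return Percent inhibition values.
#' @examples
#' ip1_percent_inhibition(50, 100)  # 50
#' @export
ip1_percent_inhibition <- function(stimulated, unstimulated) {
  .assert(all(unstimulated > 0), "unstimulated binding must be > 0")
  (1 - stimulated / unstimulated) * 100
}

#' Transform a raw IP1 assay into a percent-inhibition dose-response
#'
#' @param assay an `ip1_assay` (see [simulate_ip1_assay()] for the format).
#' @return A `dose_response` with readout `"ip1"` on the percent scale.
#' @export
ip1_to_dose_response <- function(assay) {
  .assert(inherits(assay, "ip1_assay"), "assay must be an ip1_assay")
  dose_response(assay$data$conc_mM,
                ip1_percent_inhibition(assay$data$binding,
                                       assay$unstimulated),
                replicate = assay$data$replicate,
                readout = "ip1", phe_mM = assay$phe_mM)
}

## Hill term c^n / (e^n + c^n)
.hill_term <- function(conc, ec50, n) {
  cn <- conc^n
  cn / (ec50^n + cn)
}

## Bounded Levenberg-Marquardt least squares over a list of candidate
## starts; returns the lowest-RSS solution with standard errors from the
## Gauss-Newton covariance at the optimum (NA if that matrix is singular).
.lm_least_squares <- function(model_fn, y, starts, lower, upper, maxiter) {
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = function(p) y - model_fn(p),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$deviance < best$deviance))
      best <- res
  }
  if (is.null(best)) return(NULL)
  par <- unlist(best$par)
  se <- stats::setNames(rep(NA_real_, length(par)), names(par))
  sm <- tryCatch(summary(best)$coefficients, error = function(e) NULL)
  if (!is.null(sm)) se[rownames(sm)] <- sm[, "Std. Error"]
  list(par = par, se = se, rss = best$deviance,
       converged = best$info %in% 1:4, info = best$info)
}

## initial EC50 guess: concentration where the mean curve crosses half of its
## observed span, linearly interpolated on the log-concentration axis
.ec50_init <- function(conc, y) {
  means <- tapply(y, conc, mean)
  cu <- as.numeric(names(means))
  o <- order(cu)
  cu <- cu[o]; means <- as.numeric(means)[o]
  half <- (min(means) + max(means)) / 2
  above <- which(means >= half)
  if (!length(above) || above[1] == 1) return(cu[1])
  i <- above[1]
  w <- (half - means[i - 1]) / (means[i] - means[i - 1])
  exp((1 - w) * log(cu[i - 1]) + w * log(cu[i]))
}

#' Fit the Hill equation to a dose-response
#'
#' Least-squares fit of `r(c) = r0 + (rmax - r0) * c^n / (ec50^n + c^n)` by
#' bounded Levenberg-Marquardt, with replicates fitted as individual
#' (unweighted) points. Standard errors come from the local quadratic
#' approximation at the optimum. Non-convergence or an active bound is
#' flagged on the result rather than raised.
#'
#' @param dr a [dose_response()] with at least 4 distinct concentrations.
#' @param cfg a [fit_config()].
#' @return An object of class `hill_fit`: `estimate` (named vector `ec50`,
#'   `n`, `r0`, `rmax`), `se`, `rss`, `n_obs`, `n_par`, `converged`,
#'   `fixed`, `readout`.
#' @examples
#' dr <- simulate_dose_response(hill_params(3, 3.7),
#'                              c(0.5, 1, 2, 3, 4, 5, 7.5, 10),
#'                              noise_cv = 0.05, seed = 1)
#' fit_hill(dr)
#' @export
fit_hill <- function(dr, cfg = fit_config()) {
  .assert(inherits(dr, "dose_response"), "dr must be a dose_response")
  conc <- dr$data$conc_mM
  y <- dr$data$response
  .assert(length(unique(conc)) >= 4,
          "need at least 4 distinct concentrations to fit a Hill curve")
  .assert(all(is.finite(y)), "responses must be finite")

  means_range <- range(tapply(y, conc, mean))
  start <- list(ec50 = .ec50_init(conc, y), n = cfg$n_init)
  lower <- c(ec50 = 1e-6, n = cfg$n_bounds[1])
  upper <- c(ec50 = cfg$ec50_upper_factor * max(conc), n = cfg$n_bounds[2])
  start$ec50 <- min(max(start$ec50, lower[["ec50"]] * 2), upper[["ec50"]] / 2)

  free_r0 <- is.null(cfg$fix_r0)
  free_rmax <- is.null(cfg$fix_rmax)
  if (free_r0) {
    start$r0 <- means_range[1]
    lower <- c(lower, r0 = -Inf); upper <- c(upper, r0 = Inf)
  }
  if (free_rmax) {
    start$rmax <- means_range[2]
    lower <- c(lower, rmax = -Inf); upper <- c(upper, rmax = Inf)
  }
  model_fn <- function(p) {
    r0 <- if (free_r0) p[["r0"]] else cfg$fix_r0
    rmax <- if (free_rmax) p[["rmax"]] else cfg$fix_rmax
    r0 + (rmax - r0) * .hill_term(conc, p[["ec50"]], p[["n"]])
  }
  ## perturbed fallback start for pathological landscapes
  alt <- start
  alt$ec50 <- min(start$ec50 * 1.3, upper[["ec50"]] / 2)
  alt$n <- cfg$n_init + 0.5
  if (free_r0) alt$r0 <- means_range[1] - 0.05 * diff(means_range)
  if (free_rmax) alt$rmax <- means_range[2] + 0.05 * diff(means_range)
  fit <- .lm_least_squares(model_fn, y, list(start, alt), lower, upper,
                           cfg$maxiter)

  est <- c(ec50 = NA_real_, n = NA_real_,
           r0 = cfg$fix_r0 %||% NA_real_, rmax = cfg$fix_rmax %||% NA_real_)
  se <- c(ec50 = NA_real_, n = NA_real_, r0 = NA_real_, rmax = NA_real_)
  rss <- NA_real_
  converged <- FALSE
  if (!is.null(fit)) {
    est[names(fit$par)] <- fit$par
    se[names(fit$se)] <- fit$se
    rss <- fit$rss
    ## flag active bounds on the shape parameters
    tol <- 1e-6
    at_bound <- est[["n"]] <= cfg$n_bounds[1] + tol ||
      est[["n"]] >= cfg$n_bounds[2] - tol ||
      est[["ec50"]] >= upper[["ec50"]] * (1 - 1e-9)
    converged <- fit$converged && !at_bound
  }
  structure(list(
    estimate = est, se = se, rss = rss,
    n_obs = length(y),
    n_par = 2L + free_r0 + free_rmax,
    converged = converged,
    fixed = list(r0 = cfg$fix_r0, rmax = cfg$fix_rmax),
    readout = dr$readout, phe_mM = dr$phe_mM,
    data_key = .data_key(conc, y)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit [%s%s]: EC50 = %.3g +/- %.2g mM, n = %.3g +/- %.2g%s\n",
    x$readout, if (x$phe_mM > 0) " +L-Phe" else "",
    x$estimate[["ec50"]], x$se[["ec50"]],
    x$estimate[["n"]], x$se[["n"]],
    if (!x$converged) " [NOT CONVERGED]" else ""))
  cat(sprintf("  r0 = %.3g, rmax = %.3g, RSS = %.3g on %d points\n",
              x$estimate[["r0"]], x$estimate[["rmax"]], x$rss, x$n_obs))
  invisible(x)
}

#' Predict from a Hill fit
#' @param object a `hill_fit`.
#' @param conc concentrations at which to evaluate the fitted curve.
#' @param ... unused.
#' @export
predict.hill_fit <- function(object, conc, ...) {
  e <- object$estimate
  e[["r0"]] + (e[["rmax"]] - e[["r0"]]) * .hill_term(conc, e[["ec50"]],
                                                     e[["n"]])
}

## small-sample corrected Akaike information criterion for least squares;
## k counts the error variance as a parameter
.aicc <- function(rss, n_obs, n_par) {
  k <- n_par + 1
  n_obs * log(rss / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' AICc of a fitted dose-response model
#' @param fit a `hill_fit` or `biphasic_fit`.
#' @return Small-sample corrected AIC.
#' @export
aicc <- function(fit) {
  .assert(inherits(fit, c("hill_fit", "biphasic_fit")),
          "fit must be a hill_fit or biphasic_fit")
  .aicc(fit$rss, fit$n_obs, fit$n_par)
}
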