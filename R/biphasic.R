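#' Fit a biphasic (two-component) Hill model
#'
#' Least squares for
#' `r(c) = r0 + A * [ f * h1(c) + (1 - f) * h2(c) ]`
#' where `h1`, `h2` are unit Hill terms with `ec50_1 < ec50_2` -- the shape
#' taken by concentration-response curves whose positive homotropic
#' cooperativity is disrupted so that low- and high-affinity components
#' separate. Phase order is enforced by parametrizing the second midpoint as
#' `ec50_2 = ec50_1 * rho` with `rho > 1`; the amplitude split `f` is free
#' in \[0.05, 0.95\] to avoid boundary degeneracy. Fits whose phases are not
#' separable (`rho < 1.5` at the optimum) are flagged `degenerate` rather
#' than raised.
#'
#' @param dr a [dose_response()] with at least 7 distinct concentrations
#'   spanning both phases.
#' @param cfg a [fit_config()] (`fix_r0` honoured; `fix_rmax` ignored).
#' @return An object of class `biphasic_fit`: `phase1` and `phase2`
#'   ([hill_params()] of each component with amplitudes on the response
#'   scale), `f`, `estimate`, `se`, `rss`, `n_obs`, `n_par`, `converged`,
#'   `degenerate`.
#' @export
fit_biphasic <- function(dr, cfg = fit_config()) {
  .assert(inherits(dr, "dose_response"), "dr must be a dose_response")
  conc <- dr$data$conc_mM
  y <- dr$data$response
  .assert(length(unique(conc)) >= 7,
          "need at least 7 distinct concentrations for a biphasic fit")
  .assert(all(is.finite(y)), "responses must be finite")

  means <- tapply(y, conc, mean)
  means <- as.numeric(means)[order(as.numeric(names(means)))]
  span <- max(means) - min(means)
  .assert(span > 0, "responses carry no signal to fit")
  free_r0 <- is.null(cfg$fix_r0)
  model_fn <- function(p) {
    r0 <- if (free_r0) p[["r0"]] else cfg$fix_r0
    r0 + p[["A"]] * (p[["f"]] * .hill_term(conc, p[["e1"]], p[["n1"]]) +
                       (1 - p[["f"]]) *
                         .hill_term(conc, p[["e1"]] * p[["rho"]], p[["n2"]]))
  }

  nb <- cfg$n_bounds
  lower <- c(A = 1e-12, f = 0.05, e1 = 1e-6, rho = 1.05, n1 = nb[1],
             n2 = nb[1])
  upper <- c(A = Inf, f = 0.95, e1 = cfg$ec50_upper_factor * max(conc),
             rho = 100, n1 = nb[2], n2 = nb[2])
  if (free_r0) {
    lower <- c(lower, r0 = -Inf); upper <- c(upper, r0 = Inf)
  }

  ## multi-start: quantile-based midpoint guesses crossed with a few
  ## amplitude splits and slopes; keep the lowest-RSS converged fit
  cu <- sort(unique(conc))
  e1_guess <- .ec50_of_fraction(cu, means, 0.25)
  e2_guess <- .ec50_of_fraction(cu, means, 0.75)
  rho_guess <- max(2, e2_guess / e1_guess)
  starts <- list()
  for (f0 in c(0.5, 0.3, 0.7)) for (n0 in c(2, 4)) {
    start <- list(A = span, f = f0,
                  e1 = min(max(e1_guess, 2 * lower[["e1"]]),
                           upper[["e1"]] / 2),
                  rho = min(rho_guess, 50), n1 = n0, n2 = n0)
    if (free_r0) start$r0 <- min(means)
    starts <- c(starts, list(start))
  }
  best <- .lm_least_squares(model_fn, y, starts, lower, upper, cfg$maxiter)
  n_par <- 6L + free_r0

  if (is.null(best)) {
    return(structure(list(phase1 = NULL, phase2 = NULL, f = NA_real_,
                          estimate = NULL, se = NULL, rss = NA_real_,
                          n_obs = length(y), n_par = n_par,
                          converged = FALSE, degenerate = TRUE,
                          readout = dr$readout, phe_mM = dr$phe_mM,
                          data_key = .data_key(conc, y)),
                     class = "biphasic_fit"))
  }
  cf <- best$par
  r0_val <- if (free_r0) cf[["r0"]] else cfg$fix_r0
  A <- cf[["A"]]; f <- cf[["f"]]
  e1 <- cf[["e1"]]; e2 <- cf[["e1"]] * cf[["rho"]]
  se <- best$se
  ## phases are inseparable when the midpoints nearly coincide or when the
  ## amplitude split collapses onto its boundary
  degenerate <- cf[["rho"]] < 1.5 ||
    cf[["f"]] <= 0.05 + 1e-6 || cf[["f"]] >= 0.95 - 1e-6
  structure(list(
    phase1 = hill_params(e1, cf[["n1"]], r0 = 0, rmax = A * f),
    phase2 = hill_params(e2, cf[["n2"]], r0 = 0, rmax = A * (1 - f)),
    f = f, r0 = r0_val,
    estimate = c(cf, ec50_1 = e1, ec50_2 = e2, r0 = r0_val),
    se = se, rss = best$rss, n_obs = length(y), n_par = n_par,
    converged = best$converged, degenerate = degenerate,
    readout = dr$readout, phe_mM = dr$phe_mM,
    data_key = .data_key(conc, y)
  ), class = "biphasic_fit")
}

## concentration at which the mean curve crosses `frac` of its span,
## interpolated on the log axis
.ec50_of_fraction <- function(cu, means, frac) {
  means <- as.numeric(means)
  target <- min(means) + frac * (max(means) - min(means))
  above <- which(means >= target)
  if (!length(above) || above[1] == 1) return(cu[1])
  i <- above[1]
  w <- (target - means[i - 1]) / (means[i] - means[i - 1])
  exp((1 - w) * log(cu[i - 1]) + w * log(cu[i]))
}

#' @export
print.biphasic_fit <- function(x, ...) {
  if (is.null(x$estimate)) {
    cat("biphasic fit: FAILED\n"); return(invisible(x))
  }
  cat(sprintf(
    "Biphasic Hill fit [%s]: EC50 %.3g / %.3g mM (n %.2g / %.2g), f = %.2f%s\n",
    x$readout, x$phase1$ec50, x$phase2$ec50, x$phase1$n, x$phase2$n, x$f,
    if (x$degenerate) " [DEGENERATE]" else ""))
  invisible(x)
}

#' Predict from a biphasic fit
#' @param object a `biphasic_fit`.
#' @param conc concentrations.
#' @param ... unused.
#' @export
predict.biphasic_fit <- function(object, conc, ...) {
  .assert(!is.null(object$estimate), "cannot predict from a failed fit")
  p1 <- object$phase1; p2 <- object$phase2
  object$r0 + p1$rmax * .hill_term(conc, p1$ec50, p1$n) +
    p2$rmax * .hill_term(conc, p2$ec50, p2$n)
}

#' Monophasic-versus-biphasic model selection
#'
#' Declares a concentration-response curve biphasic only when the
#' two-component fit earns it: `AICc(biphasic) < AICc(monophasic) - 2` and
#' the biphasic fit is not degenerate (separable phases). The AICc margin of
#' 2 is a package assumption, documented as such.
#'
#' @param mono a [fit_hill()] result.
#' @param bi a [fit_biphasic()] result on the same data.
#' @return `"monophasic"` or `"biphasic"`.
#' @export
select_model <- function(mono, bi) {
  .assert(inherits(mono, "hill_fit"), "mono must be a hill_fit")
  .assert(inherits(bi, "biphasic_fit"), "bi must be a biphasic_fit")
  .assert(isTRUE(all.equal(mono$data_key, bi$data_key, tolerance = 1e-8)),
          "fits were not computed on the same data")
  if (bi$degenerate || is.null(bi$estimate)) return("monophasic")
  if (aicc(bi) < aicc(mono) - 2) "biphasic" else "monophasic"
}

#' Heterotropic shift produced by an allosteric modulator
#'
#' Quantifies how a modulator (L-Phe) moves a concentration-response curve:
#' positive `delta_ec50` and `ec50_ratio < 1` indicate a left shift
#' (sensitization), a positive `delta_n` an increase in apparent
#' cooperativity.
#'
#' @param fit_without,fit_with [fit_hill()] results for the same readout
#'   without and with the modulator.
#' @return A list of class `shift_report`: `delta_ec50` (without - with,
#'   mM), `ec50_ratio` (with / without), `delta_n` (with - without), and
#'   both fits.
#' @export
heterotropic_shift <- function(fit_without, fit_with) {
  .assert(inherits(fit_without, "hill_fit") && inherits(fit_with, "hill_fit"),
          "both arguments must be hill_fit objects")
  .assert(identical(fit_without$readout, fit_with$readout),
          "fits are for different readouts (%s vs %s)",
          fit_without$readout, fit_with$readout)
  e0 <- fit_without$estimate; e1 <- fit_with$estimate
  structure(list(
    readout = fit_without$readout,
    delta_ec50 = e0[["ec50"]] - e1[["ec50"]],
    ec50_ratio = e1[["ec50"]] / e0[["ec50"]],
    delta_n = e1[["n"]] - e0[["n"]],
    without = fit_without, with = fit_with
  ), class = "shift_report")
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf(
    "Heterotropic shift [%s]: EC50 %.3g -> %.3g mM (delta %.3g, ratio %.2f); n %.3g -> %.3g\n",
    x$readout, x$without$estimate[["ec50"]], x$with$estimate[["ec50"]],
    x$delta_ec50, x$ec50_ratio, x$without$estimate[["n"]],
    x$with$estimate[["n"]]))
  invisible(x)
}
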