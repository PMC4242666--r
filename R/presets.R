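#' Hill concentration-response parameters
#'
#' The four-parameter Hill model used throughout:
#' \deqn{r(c) = r_0 + (r_{max} - r_0)\frac{c^n}{EC_{50}^n + c^n}}
#' with `ec50` the half-maximal agonist concentration (mM), `n` the Hill
#' coefficient (dimensionless; > 1 indicates positive cooperativity), and
#' `r0`/`rmax` the baseline and maximal responses in readout units.
#'
#' @param ec50 half-maximal concentration, mM (> 0).
#' @param n Hill coefficient (> 0).
#' @param r0 baseline response.
#' @param rmax maximal response (> `r0`).
#' @return An object of class `hill_params`.
#' @examples
#' hp <- hill_params(3.0, 3.7)
#' hill_response(hp, c(1, 3, 10))
#' @export
hill_params <- function(ec50, n, r0 = 0, rmax = 1) {
  .assert(is.numeric(ec50) && ec50 > 0, "ec50 must be > 0")
  .assert(is.numeric(n) && n > 0, "Hill coefficient n must be > 0")
  .assert(rmax > r0, "rmax must exceed r0")
  structure(list(ec50 = ec50, n = n, r0 = r0, rmax = rmax),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: EC50 = %g mM, n = %g, r0 = %g, rmax = %g\n",
              x$ec50, x$n, x$r0, x$rmax))
  invisible(x)
}

#' Evaluate a Hill curve
#'
#' @param hp a [hill_params()] object.
#' @param conc concentrations (same units as `hp$ec50`).
#' @return Numeric responses.
#' @export
hill_response <- function(hp, conc) {
  .assert(inherits(hp, "hill_params"), "hp must be a hill_params object")
  cn <- conc^hp$n
  hp$r0 + (hp$rmax - hp$r0) * cn / (hp$ec50^hp$n + cn)
}

#' CaSR constructs with built-in presets
#'
#' Wild-type CaSR plus the four disease-associated "toggle" mutations at the
#' hinge of the extracellular Venus-flytrap domain: L173F and P221L
#' (gain-of-function, ADHH-associated) and L173P and P221Q (loss-of-function,
#' FHH-associated).
#'
#' @return Character vector of construct names.
#' @export
casr_constructs <- function() c("WT", "L173F", "P221L", "L173P", "P221Q")

## -------------------------------------------------------------------------
## Preset tables. EC50 (mM), Hill n and oscillation frequencies (peaks/min)
## are the published population values for each construct with and without
## 5 mM L-Phe; they serve as ground truth for the synthetic generator.
## IP1 / phospho-ERK Hill coefficients and all response amplitudes are not
## published and are package choices (see the methods vignette).
## -------------------------------------------------------------------------

.preset_tables <- function() {
  list(
    ## [Ca2+]i cell-population readout (normalized 0..1).
    ## L173P is biphasic: two components with equal amplitude split (f = 0.5).
    ca_i = list(
      WT    = list(none = list(ec50 = 3.0, n = 3.7),
                   phe  = list(ec50 = 1.9, n = 5.0)),
      L173F = list(none = list(ec50 = 1.9, n = 3.3),
                   phe  = list(ec50 = 1.6, n = 3.7)),
      P221L = list(none = list(ec50 = 2.0, n = 3.2),
                   phe  = list(ec50 = 1.7, n = 2.8)),
      L173P = list(none = list(phase1 = list(ec50 = 3.8,  n = 3.3),
                               phase2 = list(ec50 = 13.0, n = 3.6), f = 0.5),
                   phe  = list(phase1 = list(ec50 = 3.1,  n = 2.5),
                               phase2 = list(ec50 = 12.2, n = 5.8), f = 0.5)),
      P221Q = list(none = list(ec50 = 5.2, n = 2.4),
                   phe  = list(ec50 = 3.7, n = 4.1))
    ),
    ## IP1 accumulation (percent inhibition of IP1-HRP binding, 0..100 scale;
    ## plateau 75% chosen; n = 3.0 chosen).
    ip1 = list(
      WT    = list(none = 2.9,  phe = 2.0),
      L173F = list(none = 1.2,  phe = 1.0),
      P221L = list(none = 1.1,  phe = 0.9),
      L173P = list(none = 10.7, phe = 9.0),
      P221Q = list(none = 6.1,  phe = 4.5)
    ),
    ## phospho-ERK1/2 (normalized immunoblot signal; n = 3.0 chosen).
    perk = list(
      WT    = list(none = 3.0,  phe = 1.9),
      L173F = list(none = 2.7,  phe = 1.6),
      P221L = list(none = 2.2,  phe = 1.7),
      L173P = list(none = 14.9, phe = 13.5),
      P221Q = list(none = 11.9, phe = 9.5)
    ),
    ## L-Phe concentration-response EC50 (mM) at fixed [Ca2+]o. `low_ca` is
    ## at the physiological 1.5 mM; `high_ca` (loss-of-function mutants only)
    ## at the construct's own calcium EC50 (15 mM for L173P, 5 mM for P221Q).
    phe_response = list(
      WT    = list(low_ca = 3.7),
      L173F = list(low_ca = 3.2),
      P221L = list(low_ca = 4.3),
      L173P = list(low_ca = 5.5, high_ca = 4.9),
      P221Q = list(low_ca = 4.5, high_ca = 2.5)
    ),
    ## Single-cell oscillation pattern: modal starting / ending step (mM),
    ## fraction of oscillatory cells in the modal bin where published,
    ## frequency (peaks/min) at the designated step. L173P without L-Phe does
    ## not plateau within 30 mM for ~80% of cells: explicit lognormal.
    osc = list(
      WT    = list(none = list(start = c(mode = 3.0, frac = 0.53),
                               end   = c(mode = 5.0, frac = 0.50),
                               freq_ppm = 1.3, freq_step = 3.0),
                   phe  = list(start = c(mode = 1.5, frac = 0.55),
                               end   = c(mode = 3.0, frac = 0.55),
                               freq_ppm = 2.1, freq_step = 3.0)),
      L173F = list(none = list(start = c(mode = 2.0, frac = 0.79),
                               end   = c(mode = 4.0, frac = 0.55),
                               freq_ppm = 1.7, freq_step = 2.5),
                   phe  = list(start = c(mode = 2.0, frac = 0.79),
                               end   = c(mode = 3.5, frac = 0.55),
                               freq_ppm = 1.9, freq_step = 2.5)),
      P221L = list(none = list(start = c(mode = 2.5, frac = 0.40),
                               end   = c(mode = 4.0, frac = 0.55),
                               freq_ppm = 1.6, freq_step = 2.5),
                   phe  = list(start = c(mode = 2.5, frac = 0.40),
                               end   = c(mode = 3.5, frac = 0.55),
                               freq_ppm = 1.8, freq_step = 2.5)),
      L173P = list(none = list(start = c(mode = 12.5, frac = 0.55),
                               end   = NULL,
                               end_lognormal = c(median = 34, sdlog = 0.15),
                               freq_ppm = 1.3, freq_step = 15.0),
                   phe  = list(start = c(mode = 10.0, frac = 0.55),
                               end   = c(mode = 25.0, frac = 0.55),
                               freq_ppm = 1.8, freq_step = 15.0)),
      P221Q = list(none = list(start = c(mode = 5.0, frac = 0.55),
                               end   = c(mode = 12.5, frac = 0.55),
                               freq_ppm = 1.5, freq_step = 5.0),
                   phe  = list(start = c(mode = 3.5, frac = 0.55),
                               end   = c(mode = 10.0, frac = 0.55),
                               freq_ppm = 2.2, freq_step = 5.0))
    )
  )
}

## Solve for the lognormal sdlog that puts `frac` of the distribution into the
## protocol bin (lower, mode], with the median pinned just below the modal
## step (median = 0.97 * mode). Used to translate a published modal fraction
## into a cell-to-cell threshold distribution.
.calibrate_sdlog <- function(mode, lower, frac, median_factor = 0.97) {
  m <- log(median_factor * mode)
  f <- function(s) stats::plnorm(mode, m, s) - stats::plnorm(lower, m, s) - frac
  stats::uniroot(f, c(0.012, 1.2), tol = 1e-10)$root
}

## lognormal (median, sdlog) for a threshold given its modal step on the
## canonical protocol
.threshold_lognormal <- function(mode, frac, protocol = default_protocol()) {
  steps <- protocol$steps$ca_mM
  i <- which(abs(steps - mode) < 1e-9)
  .assert(length(i) == 1 && i > 1, "modal step %g not on the protocol", mode)
  median <- 0.97 * mode
  c(median = median, sdlog = .calibrate_sdlog(mode, steps[i - 1], frac))
}

#' Full preset for one CaSR construct
#'
#' Bundles the published oscillation parameters (Table-level modal starting /
#' ending points and peaks-per-minute frequencies) and Hill concentration-
#' response parameters for the \[Ca2+\]i, IP1, phospho-ERK and L-Phe readouts
#' of one construct, with and without 5 mM L-Phe. These values are the ground
#' truth from which the synthetic generators draw, so that the analysis
#' pipeline can be validated by parameter recovery.
#'
#' @param construct one of [casr_constructs()].
#' @return A list with elements `construct`, `ca_i`, `ip1`, `perk`,
#'   `phe_response` (each holding `hill_params` or biphasic component lists,
#'   keyed by L-Phe condition) and `osc` (oscillation ground truth).
#' @examples
#' casr_preset("WT")$ca_i$none
#' @export
casr_preset <- function(construct) {
  construct <- match.arg(construct, casr_constructs())
  tb <- .preset_tables()
  mk_ca <- function(x) {
    if (!is.null(x$phase1)) {
      list(phase1 = hill_params(x$phase1$ec50, x$phase1$n),
           phase2 = hill_params(x$phase2$ec50, x$phase2$n),
           f = x$f)
    } else hill_params(x$ec50, x$n)
  }
  structure(list(
    construct = construct,
    ca_i = lapply(tb$ca_i[[construct]], mk_ca),
    ip1  = lapply(tb$ip1[[construct]], function(e)
      hill_params(e, n = 3.0, r0 = 0, rmax = 75)),
    perk = lapply(tb$perk[[construct]], function(e)
      hill_params(e, n = 3.0, r0 = 0, rmax = 1)),
    phe_response = lapply(tb$phe_response[[construct]], function(e)
      hill_params(e, n = 2.5, r0 = 0.2, rmax = 1)),
    osc = tb$osc[[construct]]
  ), class = "casr_preset")
}

#' @export
print.casr_preset <- function(x, ...) {
  cat(sprintf("CaSR preset '%s'\n", x$construct))
  fmt <- function(h) {
    if (inherits(h, "hill_params")) sprintf("EC50 %g mM, n %g", h$ec50, h$n)
    else sprintf("biphasic: EC50 %g/%g mM (f = %g)",
                 h$phase1$ec50, h$phase2$ec50, h$f)
  }
  cat("  [Ca2+]i:  ", fmt(x$ca_i$none), " | +L-Phe: ", fmt(x$ca_i$phe), "\n")
  cat("  IP1:      ", fmt(x$ip1$none),  " | +L-Phe: ", fmt(x$ip1$phe), "\n")
  cat("  p-ERK:    ", fmt(x$perk$none), " | +L-Phe: ", fmt(x$perk$phe), "\n")
  o <- x$osc$none
  cat(sprintf("  oscillation: start mode %s mM, freq %g peaks/min at %g mM\n",
              format(o$start[["mode"]]), o$freq_ppm, o$freq_step))
  invisible(x)
}

#' Population parameters for a preset construct
#'
#' Builds [population_params()] for one construct and L-Phe condition. The
#' per-cell oscillation onset and plateau thresholds are lognormal, calibrated
#' so that the modal protocol step carries the published fraction of
#' oscillatory cells (e.g. ~53% of oscillatory WT cells start at 3.0 mM).
#'
#' @param construct one of [casr_constructs()].
#' @param phe logical; presence of 5 mM L-Phe.
#' @param n_cells number of cells to simulate.
#' @param fraction_nonresponding fraction of cells with no CaSR response
#'   (flat baseline), e.g. untransfected cells.
#' @param protocol protocol against which threshold modes are calibrated.
#' @return A `population_params` object (see [population_params()]).
#' @export
preset_population <- function(construct, phe = FALSE, n_cells = 60,
                              fraction_nonresponding = 0.05,
                              protocol = default_protocol()) {
  pr <- casr_preset(construct)
  o <- if (phe) pr$osc$phe else pr$osc$none
  on <- .threshold_lognormal(o$start[["mode"]], o$start[["frac"]], protocol)
  pl <- if (!is.null(o$end)) {
    .threshold_lognormal(o$end[["mode"]], o$end[["frac"]], protocol)
  } else o$end_lognormal
  f_none <- pr$osc$none$freq_ppm
  f_phe <- pr$osc$phe$freq_ppm
  population_params(
    n_cells = n_cells,
    onset_median = on[["median"]],
    onset_cv = sqrt(exp(on[["sdlog"]]^2) - 1),
    plateau_median = pl[["median"]],
    plateau_cv = sqrt(exp(pl[["sdlog"]]^2) - 1),
    rate_fn = function(ca_mM, phe_mM) if (phe_mM > 0) f_phe else f_none,
    fraction_nonresponding = fraction_nonresponding
  )
}
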