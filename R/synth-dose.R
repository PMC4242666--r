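#' Dose-response data container
#'
#' Replicate responses at a set of agonist concentrations for one readout
#' (`ca_i`, `ip1`, `perk` or `phe_response`), optionally with a fixed
#' co-agonist level (e.g. 5 mM L-Phe present throughout, or a fixed
#' \[Ca2+\]o for L-Phe concentration-response curves).
#'
#' @param conc_mM agonist concentrations (mM, > 0), one per row.
#' @param response measured responses (same length).
#' @param replicate replicate labels (recycled).
#' @param readout one of `"ca_i"`, `"ip1"`, `"perk"`, `"phe_response"`.
#' @param phe_mM fixed L-Phe concentration (mM), if any.
#' @param ca_mM fixed \[Ca2+\]o (mM), for L-Phe response curves.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(conc_mM, response, replicate = 1L,
                          readout = c("ca_i", "ip1", "perk", "phe_response"),
                          phe_mM = 0, ca_mM = NA_real_) {
  readout <- match.arg(readout)
  .assert(is.numeric(conc_mM) && all(conc_mM > 0),
          "concentrations must be positive")
  .assert(length(conc_mM) == length(response),
          "conc_mM and response lengths differ")
  .assert(all(is.finite(response)), "responses must be finite")
  structure(list(
    data = data.frame(conc_mM = conc_mM, replicate = rep_len(replicate,
                                                             length(conc_mM)),
                      response = response),
    readout = readout, phe_mM = phe_mM, ca_mM = ca_mM
  ), class = "dose_response")
}

#' @export
as.data.frame.dose_response <- function(x, ...) x$data

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("dose_response [%s]: %d points at %d concentrations%s\n",
              x$readout, nrow(x$data), length(unique(x$data$conc_mM)),
              if (x$phe_mM > 0) sprintf(" (+%g mM L-Phe)", x$phe_mM) else ""))
  invisible(x)
}

#' Simulate a population dose-response assay
#'
#' Generates replicate responses from a Hill curve (or a two-component
#' biphasic mixture) with multiplicative, CV-style noise: each replicate is
#' the noiseless value times `(1 + eps)`, `eps ~ Normal(0, noise_cv)` --
#' the error structure of plate-reader population assays.
#'
#' @param hp [hill_params()] ground truth (first phase if `hp2` given).
#' @param concentrations agonist concentrations (mM, > 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @param hp2 optional second-phase [hill_params()] for a biphasic mixture.
#' @param f fraction of the response carried by the first phase (`hp`);
#'   `f = 1` collapses to the single-component curve.
#' @param readout,phe_mM,ca_mM metadata stored on the result, see
#'   [dose_response()].
#' @return A `dose_response` with a `ground_truth` attribute.
#' @examples
#' dr <- simulate_dose_response(hill_params(3.0, 3.7), c(1, 2, 3, 5, 10),
#'                              noise_cv = 0.05, replicates = 3, seed = 1)
#' @export
simulate_dose_response <- function(hp, concentrations, noise_cv = 0,
                                   replicates = 3L, seed = NULL, hp2 = NULL,
                                   f = 1,
                                   readout = "ca_i", phe_mM = 0,
                                   ca_mM = NA_real_) {
  .assert(inherits(hp, "hill_params"), "hp must be hill_params")
  .assert(all(concentrations > 0), "concentrations must be > 0")
  .assert(.is_count(replicates), "replicates must be >= 1")
  .assert(noise_cv >= 0, "noise_cv must be >= 0")
  .assert(f > 0 && f <= 1, "f must be in (0, 1]")
  .use_seed(seed)
  mu <- f * hill_response(hp, concentrations)
  if (!is.null(hp2)) {
    .assert(inherits(hp2, "hill_params"), "hp2 must be hill_params")
    mu <- mu + (1 - f) * hill_response(hp2, concentrations)
  } else {
    mu <- mu / f  # single-component: f has no effect
  }
  conc <- rep(concentrations, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(concentrations))
  y <- rep(mu, times = replicates)
  if (noise_cv > 0)
    y <- y * (1 + stats::rnorm(length(y), 0, noise_cv))
  out <- dose_response(conc, y, replicate = rep_id, readout = readout,
                       phe_mM = phe_mM, ca_mM = ca_mM)
  attr(out, "ground_truth") <- list(hp = hp, hp2 = hp2, f = f,
                                    noise_cv = noise_cv)
  out
}

#' Simulate a raw IP1 competition assay
#'
#' The IP-One assay measures IP1 accumulation through competition between
#' free IP1 and HRP-conjugated IP1 for an anti-IP1 antibody: the more IP1 a
#' stimulated well accumulates, the less IP1-HRP binds. The generator emits
#' raw binding values `B(c) = B0 * (1 - H(c)/100) * (1 + eps)` where `H(c)`
#' is the target percent-inhibition Hill curve and `B0` the (fixed)
#' unstimulated binding, so that [ip1_percent_inhibition()] applied to the
#' noiseless output recovers `H(c)` exactly.
#'
#' @param hp [hill_params()] for the percent-inhibition curve (0-100 scale).
#' @param concentrations \[Ca2+\]o concentrations (mM, > 0).
#' @param noise_cv multiplicative noise CV on the stimulated binding.
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @param b0 unstimulated IP1-HRP binding (arbitrary units, > 0).
#' @param phe_mM fixed L-Phe level recorded on the result.
#' @return An object of class `ip1_assay`: data frame `data` (`conc_mM`,
#'   `replicate`, `binding`), scalar `unstimulated`, and metadata.
#' @export
simulate_ip1_assay <- function(hp, concentrations, noise_cv = 0,
                               replicates = 3L, seed = NULL, b0 = 100,
                               phe_mM = 0) {
  .assert(inherits(hp, "hill_params"), "hp must be hill_params")
  .assert(hp$rmax <= 100 && hp$r0 >= 0,
          "percent-inhibition curve must stay within [0, 100]")
  .assert(b0 > 0, "unstimulated binding b0 must be > 0")
  .assert(all(concentrations > 0), "concentrations must be > 0")
  .use_seed(seed)
  H <- hill_response(hp, concentrations)
  conc <- rep(concentrations, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(concentrations))
  b <- rep(b0 * (1 - H / 100), times = replicates)
  if (noise_cv > 0)
    b <- b * (1 + stats::rnorm(length(b), 0, noise_cv))
  structure(list(
    data = data.frame(conc_mM = conc, replicate = rep_id, binding = b),
    unstimulated = b0, phe_mM = phe_mM,
    ground_truth = list(hp = hp, noise_cv = noise_cv)
  ), class = "ip1_assay")
}
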