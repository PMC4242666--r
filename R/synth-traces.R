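#' Single-cell trace parameters
#'
#' Phenomenological description of one cell's ratiometric response to a
#' stepwise \[Ca2+\]o protocol. Below `onset_mM` the cell sits at
#' `baseline_ratio`; at steps with `onset_mM <= ca < plateau_mM` it emits a
#' train of Gaussian-shaped \[Ca2+\]i spikes at `rate_fn(ca, phe)` peaks/min;
#' at `ca >= plateau_mM` the ratio holds a sustained elevation
#' (`plateau_ratio`). Every step change to `ca > 0.5` mM additionally elicits
#' one initial transient peak, reflecting the store-release transient seen on
#' each solution change; its peak level equals `baseline_ratio +
#' spike_amplitude` irrespective of the running level (ratiometric
#' saturation), so the per-cell maximum is the spike peak level.
#'
#' @param onset_mM oscillation-start threshold (mM).
#' @param plateau_mM oscillation-end threshold (mM), > `onset_mM`.
#' @param rate_fn `function(ca_mM, phe_mM)` returning the spike rate in
#'   peaks/min at that step.
#' @param baseline_ratio resting 340/380 ratio.
#' @param spike_amplitude spike height above baseline (ratio units).
#' @param spike_width_s full width at half maximum of one spike (s).
#' @param plateau_ratio sustained ratio once oscillations cease.
#' @param noise_sd additive Gaussian measurement noise (ratio units).
#' @return An object of class `cell_params`.
#' @export
cell_params <- function(onset_mM, plateau_mM, rate_fn,
                        baseline_ratio = 0.8, spike_amplitude = 0.6,
                        spike_width_s = 10, plateau_ratio = 1.3,
                        noise_sd = 0.02) {
  .assert(is.numeric(onset_mM) && onset_mM > 0, "onset_mM must be > 0")
  .assert(plateau_mM > onset_mM, "onset_mM must be below plateau_mM")
  .assert(is.function(rate_fn), "rate_fn must be a function(ca_mM, phe_mM)")
  .assert(spike_amplitude > 0 && spike_width_s > 0 && baseline_ratio > 0 &&
            plateau_ratio > 0, "amplitudes and widths must be positive")
  .assert(noise_sd >= 0, "noise_sd must be non-negative")
  structure(list(onset_mM = onset_mM, plateau_mM = plateau_mM,
                 rate_fn = rate_fn, baseline_ratio = baseline_ratio,
                 spike_amplitude = spike_amplitude,
                 spike_width_s = spike_width_s, plateau_ratio = plateau_ratio,
                 noise_sd = noise_sd),
            class = "cell_params")
}

#' Cell-population parameters
#'
#' Cell-to-cell heterogeneity of the oscillation thresholds is lognormal
#' (strictly positive, right-skewed, matching published threshold
#' histograms): `onset_mM` and `plateau_mM` are drawn per cell from
#' lognormals with the given medians and coefficients of variation. A
#' fraction of cells does not respond at all (flat baseline).
#'
#' @param n_cells number of cells (>= 1).
#' @param onset_median,onset_cv median (mM) and CV of the per-cell onset
#'   threshold.
#' @param plateau_median,plateau_cv median (mM) and CV of the per-cell
#'   plateau threshold.
#' @param rate_fn shared spike-rate function, see [cell_params()].
#' @param fraction_nonresponding fraction in `[0, 1)` of unresponsive cells.
#' @param ... further arguments passed to [cell_params()] (amplitudes, noise).
#' @return An object of class `population_params`.
#' @export
population_params <- function(n_cells, onset_median, onset_cv,
                              plateau_median, plateau_cv, rate_fn,
                              fraction_nonresponding = 0, ...) {
  .assert(.is_count(n_cells), "n_cells must be a positive integer")
  .assert(onset_median > 0 && plateau_median > 0, "medians must be > 0")
  .assert(onset_cv >= 0 && plateau_cv >= 0, "CVs must be >= 0")
  .assert(fraction_nonresponding >= 0 && fraction_nonresponding < 1,
          "fraction_nonresponding must be in [0, 1)")
  .assert(is.function(rate_fn), "rate_fn must be a function")
  structure(list(n_cells = as.integer(n_cells),
                 onset_median = onset_median, onset_cv = onset_cv,
                 plateau_median = plateau_median, plateau_cv = plateau_cv,
                 rate_fn = rate_fn,
                 fraction_nonresponding = fraction_nonresponding,
                 cell_args = list(...)),
            class = "population_params")
}

## Gaussian bump helper: adds `amp * exp(-(t-center)^2 / (2 sd^2))` to y,
## truncated below `from` so a step's response never precedes the step change
.add_bump <- function(y, times, center, amp, fwhm, from = -Inf) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  win <- abs(times - center) < 4 * sd & times >= from
  y[win] <- y[win] + amp * exp(-((times[win] - center)^2) / (2 * sd^2))
  y
}

## Spike-train event times within one dwell window [0, dwell): a regular
## train with uniform phase and +/-10% inter-spike-interval jitter, confined
## to [t0, dwell - tail_s] so events never collide with this step's initial
## transient or the next step's. The expected event count equals
## rate * dwell / 60 exactly, which makes peaks-per-dwell an unbiased
## frequency readout.
.train_times <- function(rate_ppm, dwell_s, t0 = 15, tail_s = 12) {
  n_expected <- rate_ppm * dwell_s / 60
  if (n_expected <= 0) return(numeric(0))
  window <- dwell_s - tail_s - t0
  if (window <= 0) return(numeric(0))
  period <- window / n_expected
  phase <- stats::runif(1)
  k <- 0:ceiling(n_expected + 1)
  tt <- t0 + (k + phase) * period
  tt <- tt[tt <= dwell_s - tail_s]
  tt + stats::runif(length(tt), -0.1, 0.1) * period
}

#' Simulate one single-cell ratiometric trace
#'
#' Generates a Fura-2-style ratio time series for one cell under a stepwise
#' \[Ca2+\]o protocol: baseline plus Gaussian noise below the onset
#' threshold, one initial transient at each step change (for steps with
#' ca > 0.5 mM), a jittered regular spike train at `rate_fn(ca, phe)`
#' peaks/min at oscillatory steps, and a sustained plateau at and above the
#' plateau threshold.
#'
#' @param params a [cell_params()] object.
#' @param protocol a [step_protocol()].
#' @param seed integer seed (the RNG state is restored afterwards).
#' @param cell_id identifier stored on the trace.
#' @return An object of class `casr_trace`: list with `cell_id`, `time_s`,
#'   `ratio`, `protocol`, and a `ground_truth` list holding the thresholds
#'   and emitted spike/transient times per step.
#' @examples
#' p <- default_protocol()
#' cp <- cell_params(3.0, 5.0, function(ca, phe) 1.3)
#' tr <- simulate_trace(cp, p, seed = 1)
#' @export
simulate_trace <- function(params, protocol, seed = NULL, cell_id = "cell_1") {
  .assert(inherits(params, "cell_params"), "params must be cell_params")
  .assert(inherits(protocol, "step_protocol"),
          "protocol must be a step_protocol")
  .use_seed(seed)
  dt <- protocol$sampling_dt
  total <- .protocol_duration(protocol)
  times <- seq(0, total - dt, by = dt)
  steps <- protocol$steps
  peak_level <- params$baseline_ratio + params$spike_amplitude

  ## running level per step
  level_of <- function(ca) {
    if (ca >= params$plateau_mM) params$plateau_ratio else params$baseline_ratio
  }
  step_idx <- .step_index_of(protocol, times)
  y <- vapply(steps$ca_mM[step_idx], level_of, numeric(1))

  spike_times <- vector("list", nrow(steps))
  transient_times <- rep(NA_real_, nrow(steps))
  for (i in seq_len(nrow(steps))) {
    ca <- steps$ca_mM[i]; phe <- steps$phe_mM[i]; t_start <- steps$start_s[i]
    lev <- level_of(ca)
    if (ca > 0.5) {
      tc <- t_start + 2
      transient_times[i] <- tc
      y <- .add_bump(y, times, tc, peak_level - lev, params$spike_width_s,
                     from = t_start)
    }
    if (ca >= params$onset_mM && ca < params$plateau_mM) {
      rate <- params$rate_fn(ca, phe)
      tt <- t_start + .train_times(rate, protocol$dwell_s)
      spike_times[[i]] <- tt
      for (tc in tt)
        y <- .add_bump(y, times, tc, params$spike_amplitude,
                       params$spike_width_s, from = t_start)
    } else {
      spike_times[[i]] <- numeric(0)
    }
  }
  if (params$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, params$noise_sd)

  structure(list(cell_id = cell_id, time_s = times, ratio = y,
                 protocol = protocol,
                 ground_truth = list(onset_mM = params$onset_mM,
                                     plateau_mM = params$plateau_mM,
                                     responding = TRUE,
                                     spike_times = spike_times,
                                     transient_times = transient_times)),
            class = "casr_trace")
}

#' @export
print.casr_trace <- function(x, ...) {
  cat(sprintf("casr_trace '%s': %d samples over %.0f s (%d protocol steps)\n",
              x$cell_id, length(x$time_s),
              utils::tail(x$time_s, 1) + x$protocol$sampling_dt,
              nrow(x$protocol$steps)))
  invisible(x)
}

#' Simulate a population of single-cell traces
#'
#' Draws per-cell onset/plateau thresholds from the population lognormals,
#' marks a random subset of cells as non-responding (flat baseline plus
#' noise), and simulates each cell with [simulate_trace()]. Ground-truth
#' thresholds and responder labels are attached for recovery testing.
#'
#' @param pop a [population_params()] object.
#' @param protocol a [step_protocol()].
#' @param seed integer seed.
#' @return A list of class `casr_population`: `traces` (list of `casr_trace`)
#'   and `ground_truth` (data frame with `cell_id`, `onset_mM`, `plateau_mM`,
#'   `responding`).
#' @export
simulate_population <- function(pop, protocol, seed = NULL) {
  .assert(inherits(pop, "population_params"), "pop must be population_params")
  .use_seed(seed)
  n <- pop$n_cells
  sdlog_on <- sqrt(log(1 + pop$onset_cv^2))
  sdlog_pl <- sqrt(log(1 + pop$plateau_cv^2))
  ## zero-CV populations share the median exactly (rlnorm would return
  ## exp(log(m)), which differs from m in the last ulp and can straddle a
  ## protocol step placed exactly at the median)
  onset <- if (sdlog_on == 0) rep(pop$onset_median, n)
    else stats::rlnorm(n, log(pop$onset_median), sdlog_on)
  plateau <- if (sdlog_pl == 0) rep(pop$plateau_median, n)
    else stats::rlnorm(n, log(pop$plateau_median), sdlog_pl)
  ## enforce onset < plateau per cell (rare inversions under high CV)
  bad <- plateau <= onset
  plateau[bad] <- onset[bad] * 1.3
  responding <- stats::runif(n) >= pop$fraction_nonresponding

  traces <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("cell_%03d", i)
    if (responding[i]) {
      cp <- do.call(cell_params,
                    c(list(onset_mM = onset[i], plateau_mM = plateau[i],
                           rate_fn = pop$rate_fn), pop$cell_args))
      traces[[i]] <- simulate_trace(cp, protocol, seed = NULL, cell_id = id)
    } else {
      ## unresponsive cell: baseline + noise only
      args <- pop$cell_args
      noise_sd <- args$noise_sd %||% 0.02
      baseline <- args$baseline_ratio %||% 0.8
      dt <- protocol$sampling_dt
      times <- seq(0, .protocol_duration(protocol) - dt, by = dt)
      traces[[i]] <- structure(
        list(cell_id = id, time_s = times,
             ratio = baseline + stats::rnorm(length(times), 0, noise_sd),
             protocol = protocol,
             ground_truth = list(onset_mM = NA_real_, plateau_mM = NA_real_,
                                 responding = FALSE,
                                 spike_times = rep(list(numeric(0)),
                                                   nrow(protocol$steps)),
                                 transient_times = rep(NA_real_,
                                                       nrow(protocol$steps)))),
        class = "casr_trace")
    }
  }
  structure(list(
    traces = traces,
    ground_truth = data.frame(
      cell_id = vapply(traces, `[[`, "", "cell_id"),
      onset_mM = ifelse(responding, onset, NA_real_),
      plateau_mM = ifelse(responding, plateau, NA_real_),
      responding = responding)
  ), class = "casr_population")
}
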