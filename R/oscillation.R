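#' Peak-detection and plateau configuration
#'
#' Tunable parameters of the oscillation analysis. Peaks are local maxima of
#' the moving-average-smoothed trace whose topographic prominence reaches
#' `k` times a robust noise estimate (scaled median absolute deviation of
#' the first-difference signal, insensitive to the spikes themselves), kept
#' at a minimum pairwise separation. The plateau criterion declares a step
#' "plateaued" when the mean of the last half of its dwell reaches
#' `plateau_fraction` of the per-cell trace maximum with coefficient of
#' variation at most `cv_max`.
#'
#' @param smooth_s moving-average smoothing window (s).
#' @param k prominence factor (multiples of the noise SD).
#' @param min_sep_s minimum peak separation (s).
#' @param plateau_fraction fraction of the trace maximum the late-dwell mean
#'   must reach.
#' @param cv_max maximal coefficient of variation of the late-dwell signal.
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(smooth_s = 5, k = 3, min_sep_s = 10,
                        plateau_fraction = 0.8, cv_max = 0.05) {
  .assert(smooth_s > 0 && min_sep_s >= 0 && k > 0, "invalid peak config")
  .assert(plateau_fraction > 0 && plateau_fraction <= 1 && cv_max > 0,
          "invalid plateau config")
  structure(list(smooth_s = smooth_s, k = k, min_sep_s = min_sep_s,
                 plateau_fraction = plateau_fraction, cv_max = cv_max),
            class = "peak_config")
}

## moving average with shrinking windows at the edges
.smooth_ma <- function(y, width) {
  if (width <= 1) return(y)
  n <- length(y)
  half <- width %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## topographic prominence of local maxima at indices `idx` of signal y
.prominence <- function(y, idx) {
  vapply(idx, function(i) {
    yl <- y[seq_len(i - 1)]
    yr <- y[seq(i + 1, length(y))]
    higher_l <- which(yl > y[i])
    higher_r <- which(yr > y[i])
    left_min <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)])
      else min(yl)
    right_min <- if (length(higher_r)) min(yr[seq_len(min(higher_r) - 1)])
      else min(yr)
    y[i] - max(left_min, right_min)
  }, numeric(1))
}

#' Detect \[Ca2+\]i peaks in a single-cell trace
#'
#' @param trace a `casr_trace` (see [simulate_trace()] or [read_traces()]).
#' @param cfg a [peak_config()].
#' @return A data frame with one row per peak: `time_s`, `height` (smoothed
#'   ratio at the peak), `prominence`, and `step_index` (protocol step
#'   containing the peak), sorted by time.
#' @examples
#' tr <- simulate_trace(cell_params(3, 5, function(ca, phe) 1.3),
#'                      default_protocol(), seed = 1)
#' head(detect_peaks(tr, peak_config()))
#' @export
detect_peaks <- function(trace, cfg = peak_config()) {
  .assert(inherits(trace, "casr_trace"), "trace must be a casr_trace")
  dt <- trace$protocol$sampling_dt
  width <- max(1L, round(cfg$smooth_s / dt))
  if (width %% 2 == 0) width <- width + 1L
  n <- length(trace$ratio)
  if (n <= width)
    .stopf("trace (%d samples) is shorter than the smoothing window", n)

  y <- .smooth_ma(trace$ratio, width)
  sigma <- stats::mad(diff(trace$ratio)) / sqrt(2)

  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  empty <- data.frame(time_s = numeric(0), height = numeric(0),
                      prominence = numeric(0), step_index = integer(0))
  if (length(idx) == 0) return(empty)
  prom <- .prominence(y, idx)
  ## absolute floor guards against 1e-16 ripples on noiseless traces
  keep <- prom >= cfg$k * sigma & prom > 1e-9
  idx <- idx[keep]; prom <- prom[keep]
  if (length(idx) == 0) return(empty)

  ## enforce minimum separation, keeping the taller of clashing peaks
  ord <- order(y[idx], decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(trace$time_s[idx[i]] - trace$time_s[idx[kept]]) >=
              cfg$min_sep_s))
      kept <- c(kept, i)
  }
  kept <- sort(idx[kept])
  prom <- prom[match(kept, idx)]
  data.frame(
    time_s = trace$time_s[kept],
    height = y[kept],
    prominence = prom,
    step_index = .step_index_of(trace$protocol, trace$time_s[kept])
  )
}

#' Oscillation classification of one protocol step
#'
#' A cell is oscillatory at a step if, after discarding the first peak in
#' the step's dwell window (the step-change transient), at least three
#' successive peaks remain -- the "three or more successive fluctuations
#' after the initial peak" criterion.
#'
#' @param peaks peak table from [detect_peaks()].
#' @param step_index protocol step to classify.
#' @return `TRUE`/`FALSE`.
#' @export
classify_oscillatory <- function(peaks, step_index) {
  .assert(is.data.frame(peaks) && "step_index" %in% names(peaks),
          "peaks must be a detect_peaks() table")
  n_in_step <- sum(peaks$step_index == step_index)
  n_in_step - 1L >= 3L
}

#' Oscillation starting point
#'
#' The lowest protocol \[Ca2+\]o at which the cell shows at least three
#' successive peaks after the initial transient ([classify_oscillatory()]).
#' When two adjacent steps both qualify, the lower concentration is
#' reported.
#'
#' @param trace a `casr_trace`.
#' @param cfg a [peak_config()].
#' @param peaks optional precomputed peak table.
#' @return Starting \[Ca2+\]o in mM, or `NA` if the cell never oscillates.
#' @export
find_start_point <- function(trace, cfg = peak_config(), peaks = NULL) {
  peaks <- peaks %||% detect_peaks(trace, cfg)
  steps <- trace$protocol$steps
  for (i in seq_len(nrow(steps))) {
    if (classify_oscillatory(peaks, i)) return(steps$ca_mM[i])
  }
  NA_real_
}

#' Oscillation frequency at a designated step
#'
#' Peaks per minute at the protocol step holding `at_mM`, after discarding
#' the initial step-change transient: `(n_peaks - 1) / dwell_min`. The step
#' is caller-designated because published frequencies are measured at
#' construct-specific \[Ca2+\]o levels.
#'
#' @param trace a `casr_trace`.
#' @param at_mM \[Ca2+\]o of the designated step (must be on the protocol).
#' @param cfg a [peak_config()].
#' @param peaks optional precomputed peak table.
#' @return Frequency in peaks/min (0 if at most the transient is present).
#' @export
compute_frequency <- function(trace, at_mM, cfg = peak_config(),
                              peaks = NULL) {
  i <- .step_at_ca(trace$protocol, at_mM)
  peaks <- peaks %||% detect_peaks(trace, cfg)
  n_qual <- max(0L, sum(peaks$step_index == i) - 1L)
  n_qual / (trace$protocol$dwell_s / 60)
}

## plateau test for one step window: late-dwell mean near the trace maximum
## with low variability (computed on the smoothed trace)
.is_plateau <- function(trace, step_i, cfg, y_smooth, y_max) {
  p <- trace$protocol
  t0 <- p$steps$start_s[step_i]
  sel <- trace$time_s >= t0 + p$dwell_s / 2 & trace$time_s < t0 + p$dwell_s
  seg <- y_smooth[sel]
  m <- mean(seg)
  m >= cfg$plateau_fraction * y_max && stats::sd(seg) / m <= cfg$cv_max
}

#' Oscillation ending point
#'
#' The lowest protocol \[Ca2+\]o at or above the starting point at which the
#' cell has stopped oscillating ([classify_oscillatory()] is `FALSE`) and
#' the trace has reached a sustained plateau (late-dwell mean at least
#' `plateau_fraction` of the per-cell maximum with low variability). `NA`
#' if oscillations persist through the final step.
#'
#' @inheritParams find_start_point
#' @return Ending \[Ca2+\]o in mM, or `NA`.
#' @export
find_end_point <- function(trace, cfg = peak_config(), peaks = NULL) {
  peaks <- peaks %||% detect_peaks(trace, cfg)
  steps <- trace$protocol$steps
  start <- find_start_point(trace, cfg, peaks = peaks)
  dt <- trace$protocol$sampling_dt
  width <- max(1L, round(cfg$smooth_s / dt))
  if (width %% 2 == 0) width <- width + 1L
  y <- .smooth_ma(trace$ratio, width)
  y_max <- max(y)
  from <- if (is.na(start)) 1L else .step_at_ca(trace$protocol, start)
  for (i in seq(from, nrow(steps))) {
    if (!classify_oscillatory(peaks, i) &&
        .is_plateau(trace, i, cfg, y, y_max))
      return(steps$ca_mM[i])
  }
  NA_real_
}

#' Extract the three oscillation parameters of one cell
#'
#' Runs peak detection once and derives the oscillatory classification, the
#' starting point, the ending point, and (optionally) the frequency at a
#' designated step. The frequency is reported only for cells classified
#' oscillatory at that step (`NA` otherwise), matching how frequencies of
#' oscillating cells are tabulated.
#'
#' @param trace a `casr_trace`.
#' @param cfg a [peak_config()].
#' @param freq_at optional \[Ca2+\]o (mM) of the designated frequency step.
#' @return A one-row data frame: `cell_id`, `oscillatory`, `start_mM`,
#'   `end_mM`, `freq_ppm`.
#' @export
extract_features <- function(trace, cfg = peak_config(), freq_at = NULL) {
  peaks <- detect_peaks(trace, cfg)
  start <- find_start_point(trace, cfg, peaks = peaks)
  end <- find_end_point(trace, cfg, peaks = peaks)
  freq <- NA_real_
  if (!is.null(freq_at)) {
    i <- .step_at_ca(trace$protocol, freq_at)
    if (classify_oscillatory(peaks, i))
      freq <- compute_frequency(trace, freq_at, cfg, peaks = peaks)
  }
  data.frame(cell_id = trace$cell_id, oscillatory = !is.na(start),
             start_mM = start, end_mM = end, freq_ppm = freq)
}

#' Summarize oscillation features over a cell population
#'
#' @param features data frame of per-cell features (rows from
#'   [extract_features()]).
#' @param bin_edges histogram bin edges (mM) for the starting/ending-point
#'   distributions; defaults to midpoints between protocol-style steps
#'   inferred from the observed values.
#' @return A list of class `population_summary`: `n_cells`,
#'   `fraction_oscillatory`, `start_hist` and `end_hist` (data frames of bin
#'   mids and counts over oscillatory cells), `freq_mean`, `freq_se`,
#'   `n_freq`, the modal starting and ending steps (`modal_start`,
#'   `modal_end`) with `modal_start_fraction` (share of oscillatory cells in
#'   the modal start bin), their order-statistic medians (`median_start`,
#'   `median_end`, always an observed step and statistically more stable
#'   than the mode), and `fraction_end_undefined` (oscillatory cells still
#'   oscillating at the final step).
#' @export
summarize_population <- function(features, bin_edges = NULL) {
  .assert(is.data.frame(features) && nrow(features) >= 1,
          "features must be a non-empty data frame")
  .assert(all(c("oscillatory", "start_mM", "end_mM", "freq_ppm") %in%
                names(features)), "missing feature columns")
  osc <- features[features$oscillatory, , drop = FALSE]
  hist_of <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(data.frame(mid = numeric(0), count = integer(0)))
    vals <- sort(unique(x))
    edges <- bin_edges %||%
      c(vals[1] - 0.25, (vals[-1] + vals[-length(vals)]) / 2,
        vals[length(vals)] + 0.25)
    cuts <- cut(x, edges, include.lowest = TRUE)
    data.frame(mid = (edges[-1] + edges[-length(edges)]) / 2,
               count = as.integer(table(cuts)))
  }
  start_hist <- hist_of(osc$start_mM)
  fr <- features$freq_ppm[!is.na(features$freq_ppm)]
  modal_value <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    tab <- table(x)
    as.numeric(names(tab)[which.max(tab)])
  }
  modal_start <- modal_value(osc$start_mM)
  modal_end <- modal_value(osc$end_mM)
  ## lower-order-statistic median: always an observed protocol step, and a
  ## far more stable population center than the modal bin
  median_step <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    unname(stats::quantile(x, 0.5, type = 1))
  }
  structure(list(
    n_cells = nrow(features),
    fraction_oscillatory = mean(features$oscillatory),
    start_hist = start_hist,
    end_hist = hist_of(osc$end_mM),
    freq_mean = if (length(fr)) mean(fr) else NA_real_,
    freq_se = if (length(fr) > 1) stats::sd(fr) / sqrt(length(fr))
      else NA_real_,
    n_freq = length(fr),
    modal_start = modal_start,
    modal_start_fraction = if (!is.na(modal_start))
      mean(osc$start_mM == modal_start, na.rm = TRUE) else NA_real_,
    modal_end = modal_end,
    median_start = median_step(osc$start_mM),
    median_end = median_step(osc$end_mM),
    fraction_end_undefined = if (nrow(osc)) mean(is.na(osc$end_mM))
      else NA_real_
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("population_summary: %d cells, %.0f%% oscillatory\n",
              x$n_cells, 100 * x$fraction_oscillatory))
  if (!is.na(x$modal_start))
    cat(sprintf("  modal start: %g mM (%.0f%% of oscillatory cells)\n",
                x$modal_start, 100 * x$modal_start_fraction))
  if (!is.na(x$freq_mean))
    cat(sprintf("  frequency: %.2f +/- %.2f peaks/min (n = %d)\n",
                x$freq_mean, x$freq_se, x$n_freq))
  invisible(x)
}
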