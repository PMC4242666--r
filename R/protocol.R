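#' Stepwise agonist protocol
#'
#' Describes a stepwise increase of extracellular calcium \[Ca2+\]o, as used in
#' single-cell Fura-2 imaging experiments where \[Ca2+\]o is raised every few
#' minutes while the 340/380 nm fluorescence ratio is recorded, optionally in
#' the continuous presence of an allosteric modulator (L-Phe).
#'
#' Step start times are `0, dwell_s, 2*dwell_s, ...`; each step holds
#' `ca_mM[i]` (and `phe_mM[i]`) for `dwell_s` seconds.
#'
#' @param ca_mM numeric vector of extracellular calcium concentrations (mM),
#'   non-decreasing across steps.
#' @param phe_mM L-Phe concentration per step (mM); a scalar is recycled.
#' @param dwell_s dwell time per concentration step in seconds (default 180 s).
#' @param sampling_dt sampling interval of the recording in seconds (default 1 s).
#' @return An object of class `step_protocol`: a list with a `steps` data frame
#'   (`start_s`, `ca_mM`, `phe_mM`), `dwell_s` and `sampling_dt`.
#' @examples
#' p <- step_protocol(c(0.5, 1, 2, 3, 5, 10))
#' p
#' @export
step_protocol <- function(ca_mM, phe_mM = 0, dwell_s = 180, sampling_dt = 1) {
  .assert(is.numeric(ca_mM) && length(ca_mM) >= 1 && all(is.finite(ca_mM)),
          "ca_mM must be a finite numeric vector")
  .assert(all(diff(ca_mM) >= 0), "ca_mM must be non-decreasing across steps")
  .assert(is.numeric(dwell_s) && length(dwell_s) == 1 && dwell_s > 0,
          "dwell_s must be a single positive number")
  .assert(is.numeric(sampling_dt) && sampling_dt > 0 && sampling_dt <= dwell_s,
          "sampling_dt must be positive and no longer than the dwell")
  phe_mM <- rep_len(phe_mM, length(ca_mM))
  .assert(all(phe_mM >= 0), "phe_mM must be non-negative")
  start_s <- (seq_along(ca_mM) - 1) * dwell_s
  out <- list(
    steps = data.frame(start_s = start_s, ca_mM = as.numeric(ca_mM),
                       phe_mM = as.numeric(phe_mM)),
    dwell_s = dwell_s,
    sampling_dt = sampling_dt
  )
  class(out) <- "step_protocol"
  out
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Stepwise [Ca2+]o protocol: %d steps x %.0f s (dt = %g s)\n",
              nrow(x$steps), x$dwell_s, x$sampling_dt))
  cat("  ca_mM:", paste(format(x$steps$ca_mM), collapse = " "), "\n")
  if (any(x$steps$phe_mM > 0))
    cat("  phe_mM:", paste(format(unique(x$steps$phe_mM)), collapse = " "), "\n")
  invisible(x)
}

#' Canonical stepwise protocol used throughout the package
#'
#' Sixteen steps from 0.5 to 30 mM \[Ca2+\]o spanning the working ranges of
#' wild-type CaSR and of both loss- and gain-of-function mutants, at the
#' default 180 s dwell and 1 Hz sampling. The dwell time and sampling rate are
#' package assumptions (the imaging literature does not fix them) and are
#' freely configurable through [step_protocol()].
#'
#' @param phe_mM L-Phe concentration held constant over the run (mM).
#' @param dwell_s,sampling_dt see [step_protocol()].
#' @return A `step_protocol`.
#' @export
default_protocol <- function(phe_mM = 0, dwell_s = 180, sampling_dt = 1) {
  step_protocol(
    ca_mM = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7.5, 10, 12.5, 15, 20, 25, 30),
    phe_mM = phe_mM, dwell_s = dwell_s, sampling_dt = sampling_dt
  )
}

## total recording length in seconds
.protocol_duration <- function(protocol) {
  utils::tail(protocol$steps$start_s, 1) + protocol$dwell_s
}

## index of the protocol step containing each time point
.step_index_of <- function(protocol, time_s) {
  findInterval(time_s, protocol$steps$start_s)
}

## step index whose ca_mM equals `ca` (error listing available steps if absent)
.step_at_ca <- function(protocol, ca) {
  i <- which(abs(protocol$steps$ca_mM - ca) < 1e-9)
  if (length(i) == 0)
    .stopf("no protocol step at %g mM; available steps: %s", ca,
           paste(format(protocol$steps$ca_mM), collapse = ", "))
  i[1]
}
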