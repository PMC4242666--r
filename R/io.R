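## File formats: traces and dose-response tables as CSV, protocols / site
## definitions / reports as JSON, ensembles as multi-model PDB or plain XYZ.
## Concentrations are always serialized in mM, times in seconds,
## coordinates in Angstrom.

#' Write single-cell traces to long-format CSV
#'
#' Columns `cell_id,time_s,ratio`, one row per sample.
#'
#' @param traces a `casr_population`, or a list of `casr_trace`, or one
#'   `casr_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "casr_population")) traces <- traces$traces
  if (inherits(traces, "casr_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, time_s = tr$time_s, ratio = tr$ratio)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read single-cell traces from CSV
#'
#' Reads a `cell_id,time_s,ratio` CSV, validates every row, groups samples
#' by cell and binds each trace to the protocol. Malformed rows are
#' rejected with their line numbers; a non-uniform time grid is an error.
#'
#' @param path trace CSV path.
#' @param protocol the [step_protocol()] the traces were recorded under, or
#'   a path to a protocol file (see [read_protocol()]).
#' @return A list of `casr_trace`.
#' @export
read_traces <- function(path, protocol) {
  if (is.character(protocol)) protocol <- read_protocol(protocol)
  .assert(inherits(protocol, "step_protocol"),
          "protocol must be a step_protocol or a path to one")
  .assert(file.exists(path), "no such file: %s", path)
  raw <- utils::read.csv(path, colClasses = "character")
  .assert(all(c("cell_id", "time_s", "ratio") %in% names(raw)),
          "trace CSV must have columns cell_id,time_s,ratio (got: %s)",
          paste(names(raw), collapse = ","))
  time_s <- suppressWarnings(as.numeric(raw$time_s))
  ratio <- suppressWarnings(as.numeric(raw$ratio))
  bad <- which(!is.finite(time_s) | !is.finite(ratio))
  if (length(bad))
    .stopf("malformed numeric value(s) on line(s) %s of %s",
           paste(bad + 1, collapse = ", "), path)  # +1 for the header line
  ids <- unique(raw$cell_id)
  lapply(ids, function(id) {
    sel <- raw$cell_id == id
    tt <- time_s[sel]; rr <- ratio[sel]
    o <- order(tt)
    tt <- tt[o]; rr <- rr[o]
    d <- diff(tt)
    .assert(length(tt) >= 2 && all(d > 0) &&
              max(abs(d - d[1])) < 1e-6,
            "cell '%s': time grid is not strictly increasing and uniform", id)
    structure(list(cell_id = id, time_s = tt, ratio = rr,
                   protocol = protocol, ground_truth = NULL),
              class = "casr_trace")
  })
}

#' Write / read a step protocol
#'
#' JSON (`.json`) stores steps plus dwell and sampling interval; CSV stores
#' the `start_s,ca_mM,phe_mM` step table (dwell inferred from the start
#' spacing on read).
#'
#' @param protocol a [step_protocol()].
#' @param path output path, extension `.json` or `.csv`.
#' @return `path` invisibly ([write_protocol()]); a `step_protocol`
#'   ([read_protocol()]).
#' @export
write_protocol <- function(protocol, path) {
  .assert(inherits(protocol, "step_protocol"), "not a step_protocol")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(steps = protocol$steps,
                              dwell_s = protocol$dwell_s,
                              sampling_dt = protocol$sampling_dt),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(protocol$steps, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    step_protocol(obj$steps$ca_mM, phe_mM = obj$steps$phe_mM,
                  dwell_s = obj$dwell_s, sampling_dt = obj$sampling_dt)
  } else {
    df <- utils::read.csv(path)
    .assert(all(c("start_s", "ca_mM") %in% names(df)),
            "protocol CSV needs start_s and ca_mM columns")
    dwell <- if (nrow(df) > 1) df$start_s[2] - df$start_s[1] else 180
    step_protocol(df$ca_mM, phe_mM = df$phe_mM %||% 0, dwell_s = dwell)
  }
}

#' Write / read dose-response tables
#'
#' CSV with columns `conc_mM,replicate,response,readout,phe_mM`.
#'
#' @param dr a [dose_response()].
#' @param path CSV path.
#' @return `path` invisibly; [read_dose_response()] returns a
#'   `dose_response`.
#' @export
write_dose_response <- function(dr, path) {
  .assert(inherits(dr, "dose_response"), "not a dose_response")
  df <- dr$data
  df$readout <- dr$readout
  df$phe_mM <- dr$phe_mM
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path)
  .assert(all(c("conc_mM", "response") %in% names(df)),
          "dose-response CSV needs conc_mM and response columns")
  dose_response(df$conc_mM, df$response,
                replicate = df$replicate %||% 1L,
                readout = (df$readout %||% "ca_i")[1],
                phe_mM = (df$phe_mM %||% 0)[1])
}

#' Write a correlation map as CSV
#'
#' Square matrix with residue labels as header and first column; undefined
#' (zero-variance) entries are serialized as `NaN`.
#'
#' @param map a [compute_dccm()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(map, path) {
  .assert(inherits(map, "correlation_map"), "not a correlation_map")
  m <- map$matrix
  df <- data.frame(residue = map$labels, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NaN")
  invisible(path)
}

#' Write an ensemble as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, one C-alpha `ATOM` record per
#' residue, coordinates in Angstrom.
#'
#' @param ens a [trajectory_ensemble()].
#' @param path PDB path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  .assert(inherits(ens, "trajectory_ensemble"), "not a trajectory_ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(ens$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- .frame_coords(ens, f)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(ens$n_residues), seq_len(ens$n_residues),
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an ensemble from a multi-model PDB
#'
#' @param path PDB path with `MODEL`/`ENDMDL` frames.
#' @param sites optional named list of residue index vectors to attach.
#' @return A [trajectory_ensemble()].
#' @export
read_ensemble_pdb <- function(path, sites = list()) {
  .assert(file.exists(path), "no such file: %s", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  trajectory_ensemble(unclass(xyz), sites = sites)
}

#' Write / read an ensemble as plain XYZ frames
#'
#' Whitespace-separated `x y z` rows, `n_residues` rows per frame, frames
#' concatenated.
#'
#' @param ens a [trajectory_ensemble()].
#' @param path file path.
#' @param n_residues residue count per frame (read).
#' @return `path` invisibly; [read_ensemble_xyz()] returns a
#'   `trajectory_ensemble`.
#' @export
write_ensemble_xyz <- function(ens, path) {
  .assert(inherits(ens, "trajectory_ensemble"), "not a trajectory_ensemble")
  m <- do.call(rbind, lapply(seq_len(ens$n_frames),
                             function(f) .frame_coords(ens, f)))
  utils::write.table(format(m, nsmall = 6, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_xyz
#' @export
read_ensemble_xyz <- function(path, n_residues) {
  .assert(file.exists(path), "no such file: %s", path)
  m <- as.matrix(utils::read.table(path))
  .assert(ncol(m) == 3, "XYZ file must have exactly 3 columns")
  .assert(nrow(m) %% n_residues == 0,
          "row count %d is not a multiple of n_residues = %d", nrow(m),
          n_residues)
  n_frames <- nrow(m) %/% n_residues
  xyz <- matrix(0, n_frames, 3 * n_residues)
  for (f in seq_len(n_frames)) {
    rows <- ((f - 1) * n_residues + 1):(f * n_residues)
    xyz[f, ] <- as.vector(t(m[rows, ]))
  }
  trajectory_ensemble(xyz)
}
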