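## End-to-end pipeline: simulate (or ingest) -> oscillation features ->
## Hill / biphasic fits with modulator shifts -> optional dynamics scores,
## collected into a JSON-serializable report.

## default concentration grids (mM) per readout; the IP1 grid follows the
## construct-specific assay ranges (loss-of-function mutants need higher
## [Ca2+]o to span their curves)
.ca_grid <- function() c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10, 15, 20, 30)

.ip1_grid <- function(construct) {
  switch(construct,
         L173P = c(3, 5, 7.5, 10, 15, 20, 25),
         P221Q = c(2, 3, 5, 7.5, 10, 15),
         c(0.5, 1, 2, 3, 5, 7.5))
}

.perk_grid <- function() c(0.5, 1, 2, 3, 4, 5, 7.5, 10, 15, 20, 25)

.phe_grid <- function() c(0.5, 1, 2, 3, 4, 5, 7.5, 10, 12)

#' Pipeline run configuration
#'
#' @param construct one of [casr_constructs()].
#' @param seed master seed; all stage seeds derive from it.
#' @param n_cells cells per oscillation population (per L-Phe condition).
#' @param noise_cv multiplicative noise CV of the dose-response assays.
#' @param replicates replicates per dose-response concentration.
#' @param peak_cfg a [peak_config()].
#' @param fit_cfg a [fit_config()].
#' @param protocol a [step_protocol()] (without L-Phe; the +L-Phe protocol
#'   adds 5 mM).
#' @param dynamics `NULL`, or a list with `n_frames` (and optionally
#'   `threshold`) to run the ensemble coupling comparison.
#' @param out_dir optional output directory for the report and tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(construct = "WT", seed = 1L, n_cells = 60L,
                       noise_cv = 0.05, replicates = 3L,
                       peak_cfg = peak_config(), fit_cfg = fit_config(),
                       protocol = default_protocol(), dynamics = NULL,
                       out_dir = NULL) {
  construct <- match.arg(construct, casr_constructs())
  .assert(.is_count(seed, min = 0), "seed must be a non-negative integer")
  .assert(.is_count(n_cells), "n_cells must be a positive integer")
  structure(list(construct = construct, seed = as.integer(seed),
                 n_cells = as.integer(n_cells), noise_cv = noise_cv,
                 replicates = as.integer(replicates), peak_cfg = peak_cfg,
                 fit_cfg = fit_cfg, protocol = protocol,
                 dynamics = dynamics, out_dir = out_dir),
            class = "run_config")
}

## plain-list view of a hill_fit for JSON reports
.fit_summary <- function(fit) {
  list(ec50 = unname(fit$estimate[["ec50"]]),
       ec50_se = unname(fit$se[["ec50"]]),
       n = unname(fit$estimate[["n"]]),
       n_se = unname(fit$se[["n"]]),
       r0 = unname(fit$estimate[["r0"]]),
       rmax = unname(fit$estimate[["rmax"]]),
       rss = fit$rss, n_obs = fit$n_obs, converged = fit$converged)
}

.biphasic_summary <- function(fit) {
  if (is.null(fit$estimate)) return(list(converged = FALSE, degenerate = TRUE))
  list(ec50_1 = fit$phase1$ec50, n_1 = fit$phase1$n,
       ec50_2 = fit$phase2$ec50, n_2 = fit$phase2$n,
       f = fit$f, rss = fit$rss, converged = fit$converged,
       degenerate = fit$degenerate)
}

.summary_list <- function(s) {
  list(n_cells = s$n_cells,
       fraction_oscillatory = s$fraction_oscillatory,
       modal_start = s$modal_start,
       modal_start_fraction = s$modal_start_fraction,
       modal_end = s$modal_end,
       median_start = s$median_start,
       median_end = s$median_end,
       fraction_end_undefined = s$fraction_end_undefined,
       freq_mean = s$freq_mean, freq_se = s$freq_se, n_freq = s$n_freq)
}

#' Run the full analysis pipeline for one construct
#'
#' Simulates the construct's single-cell populations (with and without 5 mM
#' L-Phe), extracts oscillation features and population summaries, simulates
#' and fits the \[Ca2+\]i, IP1 and phospho-ERK dose-response readouts with
#' monophasic/biphasic model selection and heterotropic-shift reports, and
#' (optionally) runs the ensemble coupling comparison. Any stage failure
#' aborts with the stage name. The report is deterministic for a fixed
#' configuration and seed.
#'
#' @param cfg a [run_config()].
#' @return A nested report list (also written as JSON and CSV if
#'   `cfg$out_dir` is set).
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config("WT", seed = 1, n_cells = 20))
#' rep$oscillation$none$modal_start
#' }
#' @export
run_pipeline <- function(cfg) {
  .assert(inherits(cfg, "run_config"), "cfg must be a run_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  preset <- casr_preset(cfg$construct)
  seed <- cfg$seed

  ## --- oscillation populations, +/- L-Phe -------------------------------
  osc <- stage("oscillation", {
    out <- list()
    for (cond in c("none", "phe")) {
      phe <- cond == "phe"
      prot <- if (phe) step_protocol(cfg$protocol$steps$ca_mM, phe_mM = 5,
                                     dwell_s = cfg$protocol$dwell_s,
                                     sampling_dt = cfg$protocol$sampling_dt)
        else cfg$protocol
      pop <- preset_population(cfg$construct, phe = phe,
                               n_cells = cfg$n_cells, protocol = prot)
      sim <- simulate_population(pop, prot,
                                 seed = seed + ifelse(phe, 101L, 100L))
      freq_at <- (if (phe) preset$osc$phe else preset$osc$none)$freq_step
      feats <- do.call(rbind, lapply(sim$traces, extract_features,
                                     cfg = cfg$peak_cfg, freq_at = freq_at))
      out[[cond]] <- .summary_list(summarize_population(feats))
      out[[cond]]$freq_step <- freq_at
      attr(out, paste0("features_", cond)) <- feats
    }
    out
  })

  ## --- dose-response readouts ------------------------------------------
  sim_ca <- function(cond, s) {
    hp <- preset$ca_i[[cond]]
    phe <- if (cond == "phe") 5 else 0
    if (inherits(hp, "hill_params")) {
      simulate_dose_response(hp, .ca_grid(), noise_cv = cfg$noise_cv,
                             replicates = cfg$replicates, seed = s,
                             readout = "ca_i", phe_mM = phe)
    } else {
      simulate_dose_response(hp$phase1, .ca_grid(), noise_cv = cfg$noise_cv,
                             replicates = cfg$replicates, seed = s,
                             hp2 = hp$phase2, f = hp$f,
                             readout = "ca_i", phe_mM = phe)
    }
  }
  fits <- stage("cooperativity", {
    out <- list()
    ## [Ca2+]i with model selection
    for (cond in c("none", "phe")) {
      dr <- sim_ca(cond, seed + 200L + (cond == "phe"))
      mono <- fit_hill(dr, cfg$fit_cfg)
      bi <- fit_biphasic(dr, cfg$fit_cfg)
      out$ca_i[[cond]] <- list(hill = .fit_summary(mono),
                               biphasic = .biphasic_summary(bi),
                               model = select_model(mono, bi))
      attr(out, paste0("ca_fit_", cond)) <- mono
    }
    out$ca_i$shift <- {
      sh <- heterotropic_shift(attr(out, "ca_fit_none"),
                               attr(out, "ca_fit_phe"))
      list(delta_ec50 = sh$delta_ec50, ec50_ratio = sh$ec50_ratio,
           delta_n = sh$delta_n)
    }
    ## IP1 via the raw competition assay and percent-inhibition transform
    ip1_fits <- list()
    for (cond in c("none", "phe")) {
      assay <- simulate_ip1_assay(preset$ip1[[cond]],
                                  .ip1_grid(cfg$construct),
                                  noise_cv = cfg$noise_cv,
                                  replicates = cfg$replicates,
                                  seed = seed + 300L + (cond == "phe"),
                                  phe_mM = if (cond == "phe") 5 else 0)
      ip1_fits[[cond]] <- fit_hill(ip1_to_dose_response(assay), cfg$fit_cfg)
      out$ip1[[cond]] <- .fit_summary(ip1_fits[[cond]])
    }
    sh <- heterotropic_shift(ip1_fits$none, ip1_fits$phe)
    out$ip1$shift <- list(delta_ec50 = sh$delta_ec50,
                          ec50_ratio = sh$ec50_ratio, delta_n = sh$delta_n)
    ## phospho-ERK
    perk_fits <- list()
    for (cond in c("none", "phe")) {
      dr <- simulate_dose_response(preset$perk[[cond]], .perk_grid(),
                                   noise_cv = cfg$noise_cv,
                                   replicates = cfg$replicates,
                                   seed = seed + 400L + (cond == "phe"),
                                   readout = "perk",
                                   phe_mM = if (cond == "phe") 5 else 0)
      perk_fits[[cond]] <- fit_hill(dr, cfg$fit_cfg)
      out$perk[[cond]] <- .fit_summary(perk_fits[[cond]])
    }
    sh <- heterotropic_shift(perk_fits$none, perk_fits$phe)
    out$perk$shift <- list(delta_ec50 = sh$delta_ec50,
                           ec50_ratio = sh$ec50_ratio, delta_n = sh$delta_n)
    ## L-Phe concentration-response at fixed [Ca2+]o
    for (cond in names(preset$phe_response)) {
      dr <- simulate_dose_response(preset$phe_response[[cond]], .phe_grid(),
                                   noise_cv = cfg$noise_cv,
                                   replicates = cfg$replicates,
                                   seed = seed + 500L +
                                     match(cond, names(preset$phe_response)),
                                   readout = "phe_response")
      out$phe_response[[cond]] <- .fit_summary(fit_hill(dr, cfg$fit_cfg))
    }
    out
  })

  ## --- optional dynamics comparison ------------------------------------
  dyn <- NULL
  if (!is.null(cfg$dynamics)) {
    dyn <- stage("dynamics", {
      nf <- cfg$dynamics$n_frames %||% 2000L
      thr <- cfg$dynamics$threshold %||% 0.5
      res <- list()
      for (which in c("wt_like", "lof_like")) {
        spec <- covariance_preset(which)
        ens <- simulate_ensemble(spec, n_frames = nf,
                                 seed = seed + 600L +
                                   (which == "lof_like"))
        ens <- superpose(ens)
        map <- compute_dccm(ens)
        sites <- ens$sites
        cp <- site_coupling(map, sites$site1,
                            sort(unique(unlist(sites[c("site2", "site3",
                                                       "site4")]))),
                            threshold = thr)
        pca <- trajectory_pca(ens, k = 3)
        res[[which]] <- list(mean_c = cp$mean_c, mean_abs_c = cp$mean_abs_c,
                             frac_strong = cp$frac_strong,
                             pc1_explained = pca$explained[1])
      }
      res$coupling_contrast <- res$wt_like$mean_abs_c -
        res$lof_like$mean_abs_c
      res
    })
  }

  report <- list(
    construct = cfg$construct,
    oscillation = list(none = osc$none, phe = osc$phe),
    fits = fits[c("ca_i", "ip1", "perk", "phe_response")],
    dynamics = dyn,
    provenance = list(seed = cfg$seed, n_cells = cfg$n_cells,
                      noise_cv = cfg$noise_cv,
                      replicates = cfg$replicates,
                      package_version = as.character(
                        utils::packageVersion("casrcoop")))
  )
  if (is.null(dyn)) report$dynamics <- NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(cfg$out_dir, "report.json"))
    utils::write.csv(report_table(report),
                     file.path(cfg$out_dir, "summary_table.csv"),
                     row.names = FALSE)
    for (cond in c("none", "phe")) {
      feats <- attr(osc, paste0("features_", cond))
      utils::write.csv(feats,
                       file.path(cfg$out_dir,
                                 sprintf("cell_features_%s.csv", cond)),
                       row.names = FALSE)
    }
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report a [run_pipeline()] report.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' One-row summary table of a pipeline report
#'
#' Mirrors the published table layout: EC50 / Hill coefficient / frequency
#' for each readout, with and without L-Phe.
#'
#' @param report a [run_pipeline()] report.
#' @return A one-row data frame.
#' @export
report_table <- function(report) {
  f <- report$fits
  data.frame(
    construct = report$construct,
    ec50_ca = f$ca_i$none$hill$ec50, ec50_ca_phe = f$ca_i$phe$hill$ec50,
    hill_ca = f$ca_i$none$hill$n, hill_ca_phe = f$ca_i$phe$hill$n,
    model_ca = f$ca_i$none$model,
    ec50_ip1 = f$ip1$none$ec50, ec50_ip1_phe = f$ip1$phe$ec50,
    ec50_perk = f$perk$none$ec50, ec50_perk_phe = f$perk$phe$ec50,
    freq_ppm = report$oscillation$none$freq_mean,
    freq_ppm_phe = report$oscillation$phe$freq_mean,
    modal_start = report$oscillation$none$modal_start,
    modal_start_phe = report$oscillation$phe$modal_start
  )
}
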