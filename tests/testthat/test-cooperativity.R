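test_that("normalization divides by the maximal mean response", {
  dr <- dose_response(c(1, 2, 4), c(2, 4, 8))
  nn <- normalize_to_max(dr)
  expect_equal(nn$data$response, c(0.25, 0.5, 1.0))
  expect_equal(normalize_to_max(nn)$data$response, nn$data$response)
  expect_error(normalize_to_max(dose_response(c(1, 2, 4), c(0, 0, 0))),
               "positive")
})

test_that("normalization leaves the fitted EC50 and Hill coefficient unchanged", {
  dr <- simulate_dose_response(hill_params(3.0, 3.7, r0 = 0.05, rmax = 2.4),
                               c(0.5, 1, 1.5, 2, 2.5, 3, 5, 10),
                               noise_cv = 0.05, replicates = 3, seed = 8)
  f1 <- fit_hill(dr)
  f2 <- fit_hill(normalize_to_max(dr))
  expect_equal(f1$estimate[["ec50"]], f2$estimate[["ec50"]],
               tolerance = 1e-6)
  expect_equal(f1$estimate[["n"]], f2$estimate[["n"]], tolerance = 1e-6)
})

test_that("percent inhibition transform follows its defining formula", {
  expect_equal(ip1_percent_inhibition(100, 100), 0)
  expect_equal(ip1_percent_inhibition(50, 100), 50)
  expect_equal(ip1_percent_inhibition(0, 100), 100)
  expect_error(ip1_percent_inhibition(1, 0), "unstimulated")
})

test_that("noiseless Hill data are recovered to numerical precision", {
  wt <- casr_preset("WT")$ca_i$none  # EC50 3.0, n 3.7
  dr <- simulate_dose_response(wt, c(0.5, 1, 1.5, 2, 2.5, 3, 5, 10),
                               noise_cv = 0, replicates = 1)
  fit <- fit_hill(dr)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate[["ec50"]] - 3.0) / 3.0, 1e-6)
  expect_lt(abs(fit$estimate[["n"]] - 3.7) / 3.7, 1e-6)
  ## fitted curve passes through the half-maximum at the fitted EC50
  e <- fit$estimate
  expect_equal(predict(fit, e[["ec50"]]),
               (e[["r0"]] + e[["rmax"]]) / 2, tolerance = 1e-8)
  expect_error(fit_hill(dose_response(c(1, 2, 3), c(1, 2, 3))),
               "4 distinct")
})

test_that("the optimizer reaches the brute-force grid-search optimum", {
  set.seed(17)
  for (case in 1:3) {
    true_ec50 <- stats::runif(1, 2, 8)
    true_n <- stats::runif(1, 1.5, 5)
    dr <- simulate_dose_response(hill_params(true_ec50, true_n),
                                 c(0.5, 1, 2, 3, 5, 7.5, 10, 15),
                                 noise_cv = 0.05, replicates = 3,
                                 seed = 100 + case)
    fit <- fit_hill(dr)
    oracle <- grid_hill_oracle(dr$data$conc_mM, dr$data$response)
    expect_lte(fit$rss, oracle$rss + 1e-10)
    expect_lt(abs(log(fit$estimate[["ec50"]] / oracle$ec50)),
              oracle$ec50_step)
    expect_lt(abs(fit$estimate[["n"]] - oracle$n), oracle$n_step)
  }
})

test_that("Hill fits are scale-equivariant and unit-consistent", {
  dr <- simulate_dose_response(hill_params(3.0, 3.7),
                               c(0.5, 1, 2, 3, 5, 7.5, 10, 15),
                               noise_cv = 0.05, replicates = 3, seed = 12)
  f0 <- fit_hill(dr)
  ## response scale: EC50, n invariant; r0, rmax scale
  dr_s <- dr
  dr_s$data$response <- dr$data$response * 4.2
  fs <- fit_hill(dr_s)
  expect_equal(fs$estimate[["ec50"]], f0$estimate[["ec50"]],
               tolerance = 1e-6)
  expect_equal(fs$estimate[["n"]], f0$estimate[["n"]], tolerance = 1e-6)
  expect_equal(fs$estimate[["rmax"]], 4.2 * f0$estimate[["rmax"]],
               tolerance = 1e-6)
  ## concentration units: uM in place of mM multiplies EC50 by 1000
  dr_u <- dr
  dr_u$data$conc_mM <- dr$data$conc_mM * 1000
  fu <- fit_hill(dr_u)
  expect_equal(fu$estimate[["ec50"]], 1000 * f0$estimate[["ec50"]],
               tolerance = 1e-6)
  expect_equal(fu$estimate[["n"]], f0$estimate[["n"]], tolerance = 1e-5)
})

test_that("noiseless biphasic mixtures are recovered to high precision", {
  l173p <- casr_preset("L173P")$ca_i$none  # EC50 3.8 / 13.0, f = 0.5
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10, 15, 20, 30)
  dr <- simulate_dose_response(l173p$phase1, grid, noise_cv = 0,
                               replicates = 1, hp2 = l173p$phase2, f = 0.5)
  fit <- fit_biphasic(dr)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$phase1$ec50 - 3.8) / 3.8, 1e-4)
  expect_lt(abs(fit$phase2$ec50 - 13.0) / 13.0, 1e-4)
  expect_lt(abs(fit$f - 0.5), 1e-4)
  expect_lt(fit$phase1$ec50, fit$phase2$ec50)  # ordering constraint
  expect_error(fit_biphasic(dose_response(c(1, 2, 3, 5), 1:4)), "7 distinct")
})

test_that("single-phase data collapse the biphasic fit to a flagged degenerate", {
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10, 15, 20, 30)
  dr <- simulate_dose_response(hill_params(3.0, 3.7), grid, noise_cv = 0,
                               replicates = 1)
  bi <- fit_biphasic(dr)
  mono <- fit_hill(dr)
  expect_true(bi$degenerate)
  expect_lt(abs(bi$phase1$ec50 - mono$estimate[["ec50"]]) /
              mono$estimate[["ec50"]], 0.1)
  expect_equal(select_model(mono, bi), "monophasic")
})

test_that("noisy biphasic midpoints are recovered within 10% in the median", {
  l173p <- casr_preset("L173P")$ca_i$none
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10, 15, 20, 30)
  errs <- vapply(1:20, function(s) {
    dr <- simulate_dose_response(l173p$phase1, grid, noise_cv = 0.05,
                                 replicates = 3, seed = s,
                                 hp2 = l173p$phase2, f = 0.5)
    fit <- fit_biphasic(dr)
    abs(fit$phase2$ec50 - 13.0) / 13.0
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("model selection refuses mismatched data", {
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10, 15, 20, 30)
  dr1 <- simulate_dose_response(hill_params(3, 3.7), grid, noise_cv = 0.05,
                                seed = 1)
  dr2 <- simulate_dose_response(hill_params(3, 3.7), grid, noise_cv = 0.05,
                                seed = 2)
  expect_error(select_model(fit_hill(dr1), fit_biphasic(dr2)), "same data")
})

test_that("heterotropic shift reports quantify the L-Phe left shift", {
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 5, 10)
  fit_of <- function(hp) fit_hill(
    simulate_dose_response(hp, grid, noise_cv = 0, replicates = 1))
  wt <- casr_preset("WT")
  sh <- heterotropic_shift(fit_of(wt$ca_i$none), fit_of(wt$ca_i$phe))
  expect_equal(sh$delta_ec50, 3.0 - 1.9, tolerance = 1e-4)
  expect_equal(sh$ec50_ratio, 1.9 / 3.0, tolerance = 1e-4)
  expect_equal(sh$delta_n, 5.0 - 3.7, tolerance = 1e-3)
  ## identical fits: no shift
  f <- fit_of(wt$ca_i$none)
  sh0 <- heterotropic_shift(f, f)
  expect_equal(sh0$delta_ec50, 0)
  expect_equal(sh0$ec50_ratio, 1)
  ## mismatched readouts are rejected
  dr_ip1 <- simulate_dose_response(wt$ip1$none, c(1, 2, 3, 5, 7.5),
                                   noise_cv = 0, readout = "ip1")
  expect_error(heterotropic_shift(f, fit_hill(dr_ip1)), "readout")
})
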