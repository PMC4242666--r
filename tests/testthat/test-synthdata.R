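test_that("step protocols validate their invariants", {
  expect_error(step_protocol(c(3, 2, 5)), "non-decreasing")
  expect_error(step_protocol(c(1, 2), dwell_s = 0), "dwell")
  p <- step_protocol(c(0.5, 1, 2), dwell_s = 60)
  expect_equal(p$steps$start_s, c(0, 60, 120))
})

test_that("spikes appear only between the onset and plateau thresholds", {
  prot <- default_protocol()
  cp <- cell_params(3.0, 5.0, const_rate(1.3))
  tr <- simulate_trace(cp, prot, seed = 11)
  counts <- lengths(tr$ground_truth$spike_times)
  ca <- prot$steps$ca_mM
  expect_true(all(counts[ca < 3.0] == 0))
  expect_true(all(counts[ca >= 5.0] == 0))
  expect_true(all(counts[ca >= 3.0 & ca < 5.0] >= 3))
})

test_that("noiseless zero-rate trace is piecewise constant with only step transients", {
  prot <- short_protocol(c(0.5, 1, 3), dwell = 120)
  cp <- cell_params(10, 20, const_rate(0), noise_sd = 0)
  tr <- simulate_trace(cp, prot, seed = 1)
  expect_equal(lengths(tr$ground_truth$spike_times), c(0, 0, 0))
  ## away from the transients (centered 2 s after each step change) the
  ## trace sits exactly at baseline
  late <- tr$time_s %% 120 > 40
  expect_equal(tr$ratio[late], rep(0.8, sum(late)))
  ## steps with ca > 0.5 mM carry exactly one transient reaching the peak
  expect_true(is.na(tr$ground_truth$transient_times[1]))
  expect_equal(sum(!is.na(tr$ground_truth$transient_times)), 2)
  expect_equal(max(tr$ratio), 0.8 + 0.6, tolerance = 1e-6)
})

test_that("emitted spike counts match the target rate", {
  ## 1.3 peaks/min over a 300 s dwell: expected 6.5 events per dwell
  prot <- step_protocol(4, dwell_s = 300)  # one oscillatory step
  cp <- cell_params(3.0, 5.0, const_rate(1.3))
  counts <- vapply(1:40, function(s) {
    tr <- simulate_trace(cp, prot, seed = s)
    length(tr$ground_truth$spike_times[[1]])
  }, numeric(1))
  expect_true(all(counts %in% c(6, 7)))
  rate_hat <- mean(counts) / (300 / 60)
  expect_lt(abs(rate_hat - 1.3), 0.1)
})

test_that("trace generation is deterministic under a fixed seed", {
  prot <- default_protocol()
  cp <- cell_params(3.0, 5.0, const_rate(1.3))
  expect_identical(simulate_trace(cp, prot, seed = 5),
                   simulate_trace(cp, prot, seed = 5))
  pop <- preset_population("WT", n_cells = 5)
  expect_identical(simulate_population(pop, prot, seed = 5),
                   simulate_population(pop, prot, seed = 5))
  hp <- hill_params(3, 3.7)
  expect_identical(
    simulate_dose_response(hp, c(1, 2, 3, 5), noise_cv = 0.05, seed = 5),
    simulate_dose_response(hp, c(1, 2, 3, 5), noise_cv = 0.05, seed = 5))
  spec <- covariance_spec(4, list(list(a = 1:2, b = 3:4, rho = 0.5)))
  expect_identical(simulate_ensemble(spec, 50, seed = 5),
                   simulate_ensemble(spec, 50, seed = 5))
})

test_that("population thresholds follow the stated lognormals", {
  prot <- default_protocol()
  ## zero CV: every cell shares the median thresholds
  pop0 <- population_params(50, onset_median = 3.0, onset_cv = 0,
                            plateau_median = 5.0, plateau_cv = 0,
                            rate_fn = const_rate(1.3))
  sim0 <- simulate_population(pop0, prot, seed = 2)
  expect_equal(sim0$ground_truth$onset_mM, rep(3.0, 50))
  ## CV 0.2 at n = 1000: empirical median within 5% of the target
  pop <- population_params(1000, onset_median = 3.0, onset_cv = 0.2,
                           plateau_median = 5.0, plateau_cv = 0.1,
                           rate_fn = const_rate(1.3))
  sim <- simulate_population(pop, prot, seed = 3)
  expect_lt(abs(stats::median(sim$ground_truth$onset_mM) - 3.0) / 3.0, 0.05)
  ## non-responder fraction is recovered on the ground-truth labels
  popnr <- population_params(400, onset_median = 3.0, onset_cv = 0.1,
                             plateau_median = 5.0, plateau_cv = 0.1,
                             rate_fn = const_rate(1.3),
                             fraction_nonresponding = 0.1)
  simnr <- simulate_population(popnr, prot, seed = 4)
  expect_lt(abs(mean(!simnr$ground_truth$responding) - 0.1), 0.05)
  ## non-responders emit no spikes at any step
  idx <- which(!simnr$ground_truth$responding)[1]
  expect_equal(sum(lengths(simnr$traces[[idx]]$ground_truth$spike_times)), 0)
})

test_that("dose-response generator honours the Hill curve and noise model", {
  hp <- hill_params(3.0, 3.7, r0 = 0.1, rmax = 0.9)
  ## half-max identity at c = ec50, noiseless
  dr <- simulate_dose_response(hp, c(1, 2, 3, 5), noise_cv = 0,
                               replicates = 1)
  expect_equal(dr$data$response[dr$data$conc_mM == 3], (0.1 + 0.9) / 2)
  ## saturation: the published WT curve is within 1% of rmax at 30 mM
  wt <- casr_preset("WT")$ca_i$none
  expect_lt(abs(hill_response(wt, 30) - 1), 0.01)
  ## degenerate mixture f = 1 equals the single-component output
  a <- simulate_dose_response(hp, c(1, 2, 3, 5), noise_cv = 0.05, seed = 9)
  b <- simulate_dose_response(hp, c(1, 2, 3, 5), noise_cv = 0.05, seed = 9,
                              hp2 = hill_params(10, 2), f = 1)
  ## f = 1 drops the second component entirely
  expect_equal(a$data$response,
               simulate_dose_response(hp, c(1, 2, 3, 5), noise_cv = 0.05,
                                      seed = 9, f = 1)$data$response)
  ## replicate mean converges to the noiseless value
  drm <- simulate_dose_response(hp, 3, noise_cv = 0.05, replicates = 400,
                                seed = 10)
  expect_lt(abs(mean(drm$data$response) - 0.5) / 0.5,
            3 * 0.05 / sqrt(400))
})

test_that("IP1 assay raw values invert exactly through the percent transform", {
  hp <- casr_preset("WT")$ip1$none
  conc <- c(0.5, 1, 2, 3, 5, 7.5)
  assay <- simulate_ip1_assay(hp, conc, noise_cv = 0, replicates = 1)
  H <- hill_response(hp, conc)
  expect_equal(assay$data$binding, 100 * (1 - H / 100))
  rec <- ip1_percent_inhibition(assay$data$binding, assay$unstimulated)
  expect_equal(rec, H)
})

test_that("ensemble sampling reproduces the specified covariance", {
  ## perfect correlation: displacement vectors identical across residues
  spec1 <- covariance_spec(2, list(list(a = 1, b = 2, rho = 1)))
  ens1 <- simulate_ensemble(spec1, 100, seed = 1)
  d1 <- sweep(ens1$xyz[, 1:3], 2, ens1$reference[1, ])
  d2 <- sweep(ens1$xyz[, 4:6], 2, ens1$reference[2, ])
  expect_equal(d1, d2, tolerance = 1e-6)
  ## rho = -0.8 recovered within sampling error at 5000 frames
  spec2 <- covariance_spec(2, list(list(a = 1, b = 2, rho = -0.8)))
  ens2 <- simulate_ensemble(spec2, 5000, seed = 2)
  dx1 <- ens2$xyz[, 1] - ens2$reference[1, 1]
  dx2 <- ens2$xyz[, 4] - ens2$reference[2, 1]
  expect_lt(abs(stats::cor(dx1, dx2) - (-0.8)), 0.05)
  ## independent residues: off-diagonal sample correlations near zero
  spec3 <- covariance_spec(4)
  ens3 <- simulate_ensemble(spec3, 5000, seed = 3)
  dd <- sapply(1:4, function(i) ens3$xyz[, 3 * i - 2])
  cc <- stats::cor(dd)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  ## Frobenius convergence of the sample covariance
  spec4 <- covariance_spec(8, list(list(a = 1:4, b = 1:4, rho = 0.6),
                                   list(a = 1:4, b = 5:8, rho = -0.4)),
                           variance = 0.5)
  ens4 <- simulate_ensemble(spec4, 10000, seed = 4)
  dx <- sapply(1:8, function(i) ens4$xyz[, 3 * i - 2])
  S <- stats::cov(dx)
  expect_lt(norm(S - spec4$K, "F") / norm(spec4$K, "F"), 0.05)
})

test_that("non-positive-semi-definite covariances are rejected with the offending block", {
  err <- expect_error(
    covariance_spec(8, list(list(a = 1:4, b = 5:8, rho = -0.9))),
    "not positive semi-definite")
  expect_match(conditionMessage(err), "block")
})

test_that("generator parameter validation catches bad inputs", {
  expect_error(cell_params(5, 3, const_rate(1)), "onset")
  expect_error(cell_params(3, 5, const_rate(1), noise_sd = -1), "noise_sd")
  expect_error(population_params(0, 3, 0.1, 5, 0.1, const_rate(1)),
               "n_cells")
  expect_error(population_params(10, 3, 0.1, 5, 0.1, const_rate(1),
                                 fraction_nonresponding = 1), "fraction")
  expect_error(hill_params(-1, 2), "ec50")
  expect_error(simulate_dose_response(hill_params(3, 2), c(-1, 2, 3, 5)),
               "concentrations")
})
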