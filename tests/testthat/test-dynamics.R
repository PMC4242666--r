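test_that("superposition removes exact rigid-body motion", {
  set.seed(91)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  frames <- lapply(1:8, function(i) {
    R <- random_rotation()
    sweep(base %*% R, 2, rnorm(3, sd = 10), `+`)
  })
  xyz <- do.call(rbind, lapply(frames, function(m) as.vector(t(m))))
  xyz <- rbind(as.vector(t(base)), xyz)
  ens <- trajectory_ensemble(xyz)
  sup <- superpose(ens)
  expect_true(sup$superposed)
  expect_lt(max(frame_rmsd(sup, 1)), 1e-8)
})

test_that("superposition is idempotent and never increases frame RMSD", {
  spec <- covariance_spec(10, variance = 0.5)
  ens <- simulate_ensemble(spec, 40, seed = 92)
  s1 <- superpose(ens)
  s2 <- superpose(s1)
  expect_lt(max(abs(s1$xyz - s2$xyz)), 1e-10)
  expect_true(all(frame_rmsd(s1, 1) <= frame_rmsd(ens, 1) + 1e-12))
})

test_that("collinear reference coordinates are rejected", {
  line <- cbind(1:5, 0, 0)
  xyz <- rbind(as.vector(t(line)), as.vector(t(line + 0.1)))
  ens <- trajectory_ensemble(xyz)
  expect_error(superpose(ens), "collinear")
})

test_that("superposition agrees with the reference implementation", {
  spec <- covariance_preset("wt_like")
  ens <- simulate_ensemble(spec, 30, seed = 93)
  ours <- superpose(ens)
  ## bio3d fits with the same least-squares criterion
  theirs <- suppressWarnings(
    bio3d::fit.xyz(fixed = ens$xyz[1, ], mobile = ens$xyz))
  expect_lt(max(abs(ours$xyz - unclass(theirs))), 1e-6)
})

test_that("identical and opposite motions give correlations of +1 and -1", {
  set.seed(94)
  disp <- matrix(rnorm(60), 20, 3)
  xyz <- matrix(0, 20, 9)
  xyz[, 1:3] <- disp                     # residue 1
  xyz[, 4:6] <- sweep(disp, 2, c(10, 0, 0), `+`)   # residue 2: identical
  xyz[, 7:9] <- sweep(-disp, 2, c(0, 10, 0), `+`)  # residue 3: opposite
  ens <- trajectory_ensemble(xyz, superposed = TRUE)
  C <- compute_dccm(ens)$matrix
  expect_equal(unname(C[1, 2]), 1, tolerance = 1e-12)
  expect_equal(unname(C[1, 3]), -1, tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 3))
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(C, t(C))
})

test_that("DCCM and PCA match naive double-loop implementations", {
  spec <- covariance_spec(5, list(list(a = 1:2, b = 4:5, rho = -0.5)),
                          variance = 0.8)
  ens <- simulate_ensemble(spec, 50, seed = 95)
  ens <- superpose(ens)
  C <- compute_dccm(ens)$matrix
  dimnames(C) <- NULL
  expect_equal(C, brute_dccm(ens$xyz), tolerance = 1e-10)
  pca <- trajectory_pca(ens, k = 5)
  ref <- brute_pca(ens$xyz)
  expect_equal(pca$eigenvalues[1:5], ref$values[1:5], tolerance = 1e-10)
  ## modes match up to sign
  for (m in 1:3)
    expect_equal(abs(sum(pca$modes[, m] * ref$vectors[, m])), 1,
                 tolerance = 1e-8)
})

test_that("DCCM agrees with the reference implementation on a random ensemble", {
  spec <- covariance_spec(8, list(list(a = 1:4, b = 1:4, rho = 0.7),
                                  list(a = 5:8, b = 5:8, rho = 0.7),
                                  list(a = 1:4, b = 5:8, rho = 0.4)),
                          variance = 0.5)
  ens <- superpose(simulate_ensemble(spec, 100, seed = 96))
  ours <- compute_dccm(ens)$matrix
  theirs <- bio3d::dccm.xyz(ens$xyz)
  expect_equal(unname(ours), unname(unclass(theirs)[1:8, 1:8]),
               tolerance = 1e-8)
})

test_that("the map is invariant to a global rotation applied before fitting", {
  spec <- covariance_spec(6, list(list(a = 1:3, b = 1:3, rho = 0.8),
                                  list(a = 4:6, b = 4:6, rho = 0.8),
                                  list(a = 1:3, b = 4:6, rho = -0.6)))
  ens <- simulate_ensemble(spec, 60, seed = 97)
  C1 <- compute_dccm(superpose(ens))$matrix
  set.seed(98)
  rot <- transform_ensemble(ens, random_rotation(), shift = c(3, -2, 7))
  C2 <- compute_dccm(superpose(rot))$matrix
  expect_equal(C1, C2, tolerance = 1e-8)
})

test_that("zero-variance residues are flagged and set undefined", {
  set.seed(99)
  xyz <- cbind(matrix(rnorm(120), 20, 6),
               matrix(rep(c(1, 2, 3), each = 20), 20, 3))
  ens <- trajectory_ensemble(xyz, superposed = TRUE)
  expect_warning(map <- compute_dccm(ens), "zero variance")
  expect_true(all(is.na(map$matrix[3, -3])))
  expect_equal(unname(map$matrix[3, 3]), 1)
})

test_that("site coupling summarizes block correlations", {
  set.seed(100)
  disp <- matrix(rnorm(90), 30, 3)
  xyz <- cbind(disp, sweep(disp, 2, c(5, 0, 0), `+`))
  ens <- trajectory_ensemble(xyz, superposed = TRUE)
  cp <- site_coupling(compute_dccm(ens), 1, 2)
  expect_equal(cp$mean_c, 1, tolerance = 1e-10)
  expect_equal(cp$frac_strong, 1)
  ## uncorrelated spec: mean coupling near zero
  spec0 <- covariance_spec(10)
  ens0 <- superpose(simulate_ensemble(spec0, 5000, seed = 101))
  cp0 <- site_coupling(compute_dccm(ens0), 1:3, 6:8)
  expect_lt(abs(cp0$mean_c), 0.05)
  expect_equal(cp0$frac_strong, 0)
  expect_error(site_coupling(compute_dccm(ens0), 1:3, 3:5), "disjoint")
})

test_that("PCA identifies the dominant collective motion", {
  ## displacement along a single fixed direction: one mode carries all
  ## variance
  set.seed(102)
  base <- matrix(rnorm(12, sd = 4), 4, 3)
  direction <- rnorm(12)
  direction <- direction / sqrt(sum(direction^2))
  amp <- rnorm(25, sd = 2)
  xyz <- t(vapply(amp, function(a) as.vector(t(base)) + a * direction,
                  numeric(12)))
  ens <- trajectory_ensemble(xyz, superposed = TRUE)
  pca <- trajectory_pca(ens, k = 3)
  expect_equal(pca$explained[1], 1, tolerance = 1e-10)
  expect_lt(pca$eigenvalues[2], 1e-10)
  expect_equal(abs(sum(pca$modes[, 1] * direction)), 1, tolerance = 1e-8)
  ## projections are mean-centered
  expect_lt(max(abs(colMeans(pca$projections))), 1e-10)
  ## eigenvalue sum equals total coordinate variance
  expect_equal(sum(pca$eigenvalues),
               sum(apply(xyz, 2, stats::var)), tolerance = 1e-10)
  ## modes are orthonormal
  g <- crossprod(pca$modes)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8)
})

test_that("an isotropic ensemble has nearly equal leading eigenvalues", {
  spec <- covariance_spec(5, variance = 1)
  ens <- superpose(simulate_ensemble(spec, 20000, seed = 103))
  pca <- trajectory_pca(ens, k = 3)
  ## rigid-body removal leaves 9 soft modes out of 15; the leading retained
  ## modes should be near-degenerate
  expect_lt(pca$eigenvalues[1] / pca$eigenvalues[2], 1.25)
})
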