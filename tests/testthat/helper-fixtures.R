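## Shared fixtures and independent oracle implementations used across the
## test files. Everything here is deliberately naive and independent of the
## package's own computation paths.

## short protocol for fast trace tests
short_protocol <- function(ca = c(0.5, 1, 2, 3, 4, 5, 7.5), phe = 0,
                           dwell = 180) {
  step_protocol(ca, phe_mM = phe, dwell_s = dwell)
}

const_rate <- function(ppm) function(ca_mM, phe_mM) ppm

## hand-built trace: baseline + optional Gaussian bumps at given times
make_trace <- function(ratio, protocol, cell_id = "fix") {
  structure(list(cell_id = cell_id,
                 time_s = seq(0, length(ratio) - 1) * protocol$sampling_dt,
                 ratio = ratio, protocol = protocol, ground_truth = NULL),
            class = "casr_trace")
}

add_gauss <- function(y, times, center, amp, fwhm = 10) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  y + amp * exp(-((times - center)^2) / (2 * sd^2))
}

## --- grid-search oracle for the 4-parameter Hill fit ---------------------
## exhaustive (ec50, n) grid with the analytic linear solve for (r0, rmax)
grid_hill_oracle <- function(conc, y, ec50_range = c(0.5, 20),
                             n_range = c(0.5, 8), n_grid = 200) {
  ec50s <- exp(seq(log(ec50_range[1]), log(ec50_range[2]),
                   length.out = n_grid))
  ns <- seq(n_range[1], n_range[2], length.out = n_grid)
  best <- list(rss = Inf)
  for (e in ec50s) for (n in ns) {
    h <- conc^n / (e^n + conc^n)
    fit <- stats::.lm.fit(cbind(1, h), y)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, ec50 = e, n = n,
                   r0 = fit$coefficients[1],
                   rmax = fit$coefficients[1] + fit$coefficients[2])
  }
  best$ec50_step <- log(ec50s[2] / ec50s[1])
  best$n_step <- ns[2] - ns[1]
  best
}

## --- naive double-loop DCCM and PCA --------------------------------------
brute_dccm <- function(xyz) {
  nf <- nrow(xyz)
  nr <- ncol(xyz) / 3
  arr <- array(0, c(nf, nr, 3))
  for (f in seq_len(nf))
    arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  mean_pos <- apply(arr, c(2, 3), mean)
  C <- matrix(0, nr, nr)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(nf)) {
      di <- arr[f, i, ] - mean_pos[i, ]
      dj <- arr[f, j, ] - mean_pos[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di)
      vj <- vj + sum(dj * dj)
    }
    C[i, j] <- num / sqrt(vi * vj)
  }
  C
}

brute_pca <- function(xyz) {
  X <- scale(xyz, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors)
}

## random rigid rotation matrix
random_rotation <- function() {
  qrres <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qrres)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## apply a rigid motion to every frame of an ensemble
transform_ensemble <- function(ens, R, shift = c(0, 0, 0)) {
  for (f in seq_len(ens$n_frames)) {
    P <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    ens$xyz[f, ] <- as.vector(t(sweep(P %*% R, 2, shift, `+`)))
  }
  ens
}

## per-frame RMSD to a reference frame
frame_rmsd <- function(ens, ref_frame = 1) {
  ref <- matrix(ens$xyz[ref_frame, ], ncol = 3, byrow = TRUE)
  vapply(seq_len(ens$n_frames), function(f) {
    P <- matrix(ens$xyz[f, ], ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums((P - ref)^2)))
  }, numeric(1))
}
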