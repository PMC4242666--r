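#' Least-squares superposition of an ensemble
#'
#' Removes rigid-body motion by superposing every frame onto a reference
#' frame with the optimal (SVD-based, Kabsch) least-squares rotation and
#' translation, computed over `mask` residues and applied to all residues.
#' Required before [compute_dccm()] or [trajectory_pca()], which analyze
#' internal motions only.
#'
#' @param ens a [trajectory_ensemble()].
#' @param reference_frame index of the frame used as reference (default 1).
#' @param mask residue indices used to compute the fit (default all).
#' @return The superposed `trajectory_ensemble` (`superposed = TRUE`).
#' @export
superpose <- function(ens, reference_frame = 1, mask = NULL) {
  .assert(inherits(ens, "trajectory_ensemble"),
          "ens must be a trajectory_ensemble")
  .assert(.is_count(reference_frame) && reference_frame <= ens$n_frames,
          "reference_frame out of range")
  mask <- mask %||% seq_len(ens$n_residues)
  .assert(all(mask %in% seq_len(ens$n_residues)), "mask indices out of range")
  .assert(length(mask) >= 3, "superposition needs at least 3 residues")

  ref <- .frame_coords(ens, reference_frame)[mask, , drop = FALSE]
  ref_cent <- colMeans(ref)
  refc <- sweep(ref, 2, ref_cent)
  if (qr(refc)$rank < 2)
    .stopf("degenerate (collinear) reference coordinates; cannot superpose")

  out <- ens$xyz
  for (f in seq_len(ens$n_frames)) {
    P <- .frame_coords(ens, f)
    cent <- colMeans(P[mask, , drop = FALSE])
    Pc_fit <- sweep(P[mask, , drop = FALSE], 2, cent)
    H <- crossprod(Pc_fit, refc)            # 3 x 3
    sv <- svd(H)
    s <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
    aligned <- sweep(P, 2, cent) %*% R
    aligned <- sweep(aligned, 2, ref_cent, `+`)
    out[f, ] <- as.vector(t(aligned))
  }
  ens$xyz <- out
  ens$superposed <- TRUE
  ens
}

#' Dynamic cross-correlation map
#'
#' Computes the residue-residue dynamic cross-correlation matrix
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}}}
#' where \eqn{\Delta r_i} is the deviation of residue `i`'s position from
#' its ensemble average. Values lie in \[-1, 1\] by construction (no
#' post-hoc clipping): +1 means a pair moves identically, -1 exactly
#' oppositely. Residues with zero positional variance yield undefined
#' correlations; their rows/columns are set to `NA` with a warning and the
#' diagonal is kept at 1.
#'
#' @param ens a superposed [trajectory_ensemble()] with >= 10 frames.
#' @return An object of class `correlation_map`: symmetric `matrix`
#'   (`n_residues x n_residues`, unit diagonal) plus residue `labels`.
#' @export
compute_dccm <- function(ens) {
  .assert(inherits(ens, "trajectory_ensemble"),
          "ens must be a trajectory_ensemble")
  .assert(ens$superposed,
          "ensemble must be superposed first (see superpose())")
  .assert(ens$n_frames >= 10, "need at least 10 frames for a correlation map")
  n <- ens$n_residues
  D <- scale(ens$xyz, center = TRUE, scale = FALSE)
  S <- matrix(0, n, n)
  for (axis in 1:3) {
    Da <- D[, seq(axis, 3 * n, by = 3), drop = FALSE]
    S <- S + crossprod(Da)
  }
  v <- diag(S)
  zero <- v <= .Machine$double.eps * max(v)
  denom <- sqrt(outer(pmax(v, .Machine$double.xmin),
                      pmax(v, .Machine$double.xmin)))
  C <- S / denom
  if (any(zero)) {
    warning(sprintf("%d residue(s) with zero variance; correlations set to NA",
                    sum(zero)))
    C[zero, ] <- NA_real_
    C[, zero] <- NA_real_
  }
  diag(C) <- 1
  dimnames(C) <- list(ens$labels, ens$labels)
  structure(list(matrix = C, labels = ens$labels, n_frames = ens$n_frames),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat(sprintf(
    "correlation_map: %d residues (%d frames); off-diagonal range [%.2f, %.2f]\n",
    nrow(x$matrix), x$n_frames, min(off, na.rm = TRUE),
    max(off, na.rm = TRUE)))
  invisible(x)
}

#' Inter-site coupling score
#'
#' Summarizes the correlated motion between two disjoint residue sets (e.g.
#' two ligand-binding sites) from a correlation map: the mean signed
#' correlation over all cross pairs, the mean absolute correlation, and the
#' fraction of pairs whose absolute correlation reaches `threshold`. This
#' score is the package's operationalization of visual map comparison; it is
#' reported as such.
#'
#' @param map a [compute_dccm()] result.
#' @param set_a,set_b disjoint, non-empty residue index vectors.
#' @param threshold absolute-correlation threshold for the pair fraction.
#' @return A list of class `site_coupling`: `mean_c`, `mean_abs_c`,
#'   `frac_strong`, `n_pairs`.
#' @export
site_coupling <- function(map, set_a, set_b, threshold = 0.5) {
  .assert(inherits(map, "correlation_map"), "map must be a correlation_map")
  n <- nrow(map$matrix)
  .assert(length(set_a) > 0 && length(set_b) > 0, "sets must be non-empty")
  .assert(all(c(set_a, set_b) %in% seq_len(n)), "set indices out of range")
  .assert(length(intersect(set_a, set_b)) == 0, "residue sets must be disjoint")
  sub <- map$matrix[set_a, set_b, drop = FALSE]
  structure(list(
    mean_c = mean(sub, na.rm = TRUE),
    mean_abs_c = mean(abs(sub), na.rm = TRUE),
    frac_strong = mean(abs(sub) >= threshold, na.rm = TRUE),
    n_pairs = length(sub), threshold = threshold
  ), class = "site_coupling")
}

#' @export
print.site_coupling <- function(x, ...) {
  cat(sprintf(
    "site_coupling over %d pairs: mean C = %.3f, mean |C| = %.3f, |C| >= %g in %.0f%%\n",
    x$n_pairs, x$mean_c, x$mean_abs_c, x$threshold, 100 * x$frac_strong))
  invisible(x)
}

#' Principal component analysis of a trajectory
#'
#' Essential-dynamics PCA: eigendecomposition of the covariance matrix of
#' the mean-centered, flattened residue coordinates of a superposed
#' ensemble. Modes are ranked by eigenvalue (A^2); frame projections onto
#' the first `k` modes describe the dominant collective motions.
#'
#' @param ens a superposed [trajectory_ensemble()] with >= 2 frames.
#' @param k number of modes to report projections for (default 3).
#' @return An object of class `traj_pca`: `eigenvalues` (all, descending,
#'   A^2), `modes` (orthonormal columns, `3*n_residues x k`), `projections`
#'   (`n_frames x k`), `explained` (variance fractions of the reported
#'   modes), `total_variance`.
#' @export
trajectory_pca <- function(ens, k = 3) {
  .assert(inherits(ens, "trajectory_ensemble"),
          "ens must be a trajectory_ensemble")
  .assert(ens$superposed,
          "ensemble must be superposed first (see superpose())")
  .assert(ens$n_frames >= 2, "need at least 2 frames")
  .assert(.is_count(k) && k <= 3 * ens$n_residues,
          "k must be between 1 and 3 * n_residues")
  X <- scale(ens$xyz, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = 0)
  lambda <- sv$d^2 / (ens$n_frames - 1)
  k_eff <- min(k, ncol(sv$v))
  modes <- sv$v[, seq_len(k_eff), drop = FALSE]
  proj <- X %*% modes
  structure(list(
    eigenvalues = lambda,
    modes = modes,
    projections = proj,
    explained = lambda[seq_len(k_eff)] / sum(lambda),
    total_variance = sum(lambda),
    k = k_eff
  ), class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  cat(sprintf("trajectory PCA: %d modes reported, total variance %.3g A^2\n",
              x$k, x$total_variance))
  cat(sprintf("  explained: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}
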