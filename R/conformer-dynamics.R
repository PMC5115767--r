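#' Sample conformers from the GNM covariance
#'
#' A desk-scale surrogate for a molecular-dynamics trajectory: frames are
#' drawn as `reference + displacement`, with displacements sampled from a
#' zero-mean Gaussian whose residue-residue covariance is
#' `amplitude * pseudo-inverse(Kirchhoff)`, applied independently and
#' identically to each Cartesian axis (the isotropic GNM convention).
#' Output is bit-reproducible given `(seed, n_frames)`.
#'
#' @param structure Reference [new_structure()].
#' @param modes [gnm_modes()] of the same structure.
#' @param n_frames Number of frames to draw (>= 1).
#' @param amplitude Scalar kBT/gamma prefactor of the covariance (> 0,
#'   default 1; per-axis variance is one third of the isotropic
#'   mean-square fluctuation).
#' @param seed RNG seed.
#' @return A [new_ensemble()] with `n_frames` frames.
#' @export
sample_conformers_gnm <- function(structure, modes, n_frames, amplitude = 1,
                                  seed = 1L) {
  assert_scalar_number(amplitude, "amplitude", positive = TRUE)
  if (n_frames < 1L) abort("n_frames must be >= 1")
  nz <- nonzero_mode_indices(modes)
  if (length(nz) == 0L) abort("no non-zero modes available")
  u <- modes$eigenvectors[, nz, drop = FALSE]
  lam <- modes$eigenvalues[nz]
  n <- nrow(u)
  if (n != nrow(structure$residues)) abort("modes and structure disagree on N")
  # C = amplitude * U diag(1/lambda) U^T  =>  L = U diag(1/sqrt(lambda))
  l_fac <- sqrt(amplitude) * sweep(u, 2, sqrt(lam), "/")
  m <- length(lam)
  frames <- array(NA_real_, dim = c(n_frames, n, 3L))
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      z <- matrix(stats::rnorm(m * 3L), m, 3L)
      frames[k, , ] <- structure$ca + l_fac %*% z
    }
  })
  new_ensemble(structure, frames,
               frame_labels = sprintf("gnm%06d", seq_len(n_frames)))
}

#' Generalized correlation coefficients from a conformer ensemble
#'
#' Mutual-information-based correlation of residue displacement
#' fluctuations in [0, 1]. Under the Gaussian estimator the MI of a
#' residue pair is `I = 0.5 log(det C_i det C_j / det C_ij)` from the
#' 3x3/6x6 displacement covariance blocks, and
#' `r_MI = sqrt(1 - exp(-2 I / 3))`. Unlike a Pearson coefficient, r_MI
#' captures correlated motion regardless of relative direction.
#'
#' @param ensemble A superposed [new_ensemble()] with >= 10 frames.
#' @param estimator `"gaussian"` (the only implemented estimator).
#' @return An object of class `corr_matrix` with `r_mi` (N x N, unit
#'   diagonal).
#' @export
generalized_correlation <- function(ensemble, estimator = "gaussian") {
  estimator <- match.arg(estimator, "gaussian")
  f <- n_frames(ensemble)
  if (f < 10L) abort("generalized correlation needs at least 10 frames")
  x <- flatten_frames(ensemble)
  n <- dim(ensemble$frames)[2]
  cc <- cov(x) * (f - 1) / f
  r <- matrix(0, n, n)
  diag(r) <- 1
  ldet <- function(m) {
    d <- determinant(m, logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }
  block <- function(i) 3L * (i - 1L) + 1:3
  ldet_i <- vapply(seq_len(n), function(i) ldet(cc[block(i), block(i)]), numeric(1))
  singular <- !is.finite(ldet_i)
  if (any(singular)) {
    warn(sprintf("%d residue(s) have singular displacement covariance; their r_MI set to 0",
                 sum(singular)))
  }
  for (i in seq_len(n - 1)) {
    if (singular[i]) next
    for (j in (i + 1):n) {
      if (singular[j]) next
      bb <- c(block(i), block(j))
      ld_ij <- ldet(cc[bb, bb])
      mi <- 0.5 * (ldet_i[i] + ldet_i[j] - ld_ij)
      mi <- max(mi, 0)
      r[i, j] <- r[j, i] <- clamp(sqrt(1 - exp(-2 * mi / 3)), 0, 1)
    }
  }
  structure(
    list(r_mi = r, estimator = "gaussian", source = "ensemble"),
    class = "corr_matrix"
  )
}

#' Analytic GNM generalized correlations
#'
#' Deterministic alternative to [generalized_correlation()]: the
#' normalised GNM covariance
#' `c_ij = pinv(Gamma)_ij / sqrt(pinv(Gamma)_ii pinv(Gamma)_jj)` applied
#' identically to all three axes has Gaussian mutual information
#' `I = -(3/2) log(1 - c^2)`, so `r_MI = |c_ij|` exactly. Agrees with the
#' sampled estimator in the large-F limit on GNM ensembles.
#'
#' @param modes A [gnm_modes()] object.
#' @return An object of class `corr_matrix`.
#' @export
analytic_gnm_correlation <- function(modes) {
  nz <- nonzero_mode_indices(modes)
  if (length(nz) == 0L) abort("no non-zero modes available")
  u <- modes$eigenvectors[, nz, drop = FALSE]
  lam <- modes$eigenvalues[nz]
  pinv <- u %*% (t(u) / lam)
  dvar <- diag(pinv)
  r <- abs(pinv / sqrt(outer(dvar, dvar)))
  r <- clamp((r + t(r)) / 2, 0, 1)
  diag(r) <- 1
  structure(
    list(r_mi = r, estimator = "gaussian", source = "gnm_analytic"),
    class = "corr_matrix"
  )
}

#' @export
print.corr_matrix <- function(x, ...) {
  off <- x$r_mi[upper.tri(x$r_mi)]
  cat(sprintf("<corr_matrix> %d residues (%s/%s), mean off-diagonal r_MI = %.3f\n",
              nrow(x$r_mi), x$estimator, x$source, mean(off)))
  invisible(x)
}

#' Per-residue ensemble distance and pMI-variation statistics
#'
#' For every frame, `d_i` is the mean alpha-carbon distance from residue i
#' to all other residues, and `dpM_i` is the mean over j != i of
#' `pMI_i - pMI_j` evaluated at the frame's positions. Means and
#' (population) variances of both quantities across frames feed the
#' communication-propensity model.
#'
#' @param ensemble A [new_ensemble()].
#' @param per_frame_pmi Optional F x N matrix of per-frame pMI values
#'   (from [proximity_mi()] in ensemble mode). When omitted the pMI terms
#'   are zero and only distance statistics are produced.
#' @return An object of class `ensemble_stats` with fields
#'   `mean_pair_distances` (N x N), `d_i`, `var_d_i`, `delta_pmi_i`,
#'   `var_delta_pmi_i`, `frame_count`.
#' @export
ensemble_stats <- function(ensemble, per_frame_pmi = NULL) {
  f <- n_frames(ensemble)
  n <- dim(ensemble$frames)[2]
  if (!is.null(per_frame_pmi)) {
    per_frame_pmi <- as.matrix(per_frame_pmi)
    if (nrow(per_frame_pmi) != f || ncol(per_frame_pmi) != n) {
      abort("`per_frame_pmi` must be an F x N matrix matching the ensemble")
    }
  }
  d_frames <- matrix(NA_real_, f, n)
  dpm_frames <- matrix(0, f, n)
  mean_pair <- matrix(0, n, n)
  for (k in seq_len(f)) {
    xyz <- ensemble$frames[k, , , drop = TRUE]
    d <- cross_dist(xyz, xyz)
    mean_pair <- mean_pair + d
    d_frames[k, ] <- rowSums(d) / (n - 1)
    if (!is.null(per_frame_pmi)) {
      p <- per_frame_pmi[k, ]
      # mean over j != i of (p_i - p_j) = p_i - (sum(p) - p_i) / (n - 1)
      dpm_frames[k, ] <- p - (sum(p) - p) / (n - 1)
    }
  }
  mean_pair <- mean_pair / f
  pop_var <- function(m) {
    if (nrow(m) < 2L) return(rep(NA_real_, ncol(m)))
    colMeans(sweep(m, 2, colMeans(m))^2)
  }
  structure(
    list(
      mean_pair_distances = mean_pair,
      d_i = colMeans(d_frames),
      var_d_i = pop_var(d_frames),
      delta_pmi_i = colMeans(dpm_frames),
      var_delta_pmi_i = pop_var(dpm_frames),
      frame_count = f
    ),
    class = "ensemble_stats"
  )
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> %d residues over %d frames\n",
              length(x$d_i), x$frame_count))
  invisible(x)
}

#' @export
tidy.ensemble_stats <- function(x, ...) {
  tibble(
    residue = seq_along(x$d_i),
    d_i = x$d_i,
    var_d_i = x$var_d_i,
    delta_pmi_i = x$delta_pmi_i,
    var_delta_pmi_i = x$var_delta_pmi_i
  )
}
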