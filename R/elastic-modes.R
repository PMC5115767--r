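#' Gaussian network model of a structure
#'
#' The GNM treats a protein as an isotropic elastic network of N residue
#' nodes (alpha-carbons). Pairs within the interaction cutoff `rc` are
#' joined by springs of uniform force constant `gamma`; the network
#' topology is the N x N Kirchhoff (graph Laplacian) matrix whose diagonal
#' holds residue coordination numbers and whose off-diagonal entries are -1
#' for contacting pairs.
#'
#' @param structure A [new_structure()] with at least 2 residues.
#' @param rc Interaction cutoff distance in Angstrom (default 7.0, the
#'   standard alpha-carbon GNM choice).
#' @param spring_gamma Uniform spring force constant (energy/A^2, default 1).
#' @param kBT Thermal energy unit (default 1; fluctuation profiles are
#'   reported max-normalised so only the product kBT/gamma matters).
#' @return An object of class `kirchhoff_model` with the Laplacian in
#'   `$gamma_matrix`.
#' @export
build_kirchhoff <- function(structure, rc = 7.0, spring_gamma = 1, kBT = 1) {
  assert_scalar_number(rc, "rc", positive = TRUE)
  n <- nrow(structure$residues)
  if (n < 2L) abort("GNM needs at least 2 residues")
  d <- cross_dist(structure$ca, structure$ca)
  adj <- (d <= rc) * 1
  diag(adj) <- 0
  gamma_matrix <- diag(rowSums(adj)) - adj
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  if (comp$no > 1L) {
    warn(sprintf("contact graph has %d components; GNM will have %d zero modes",
                 comp$no, comp$no))
  }
  structure(
    list(gamma_matrix = gamma_matrix, cutoff_rc = rc, spring_gamma = spring_gamma,
         kBT = kBT, labels = residue_labels(structure$residues),
         n_components = comp$no),
    class = "kirchhoff_model"
  )
}

#' @export
print.kirchhoff_model <- function(x, ...) {
  cat(sprintf("<kirchhoff_model> N=%d, rc=%.2f A, %d springs\n",
              nrow(x$gamma_matrix), x$cutoff_rc, sum(x$gamma_matrix == -1) / 2))
  invisible(x)
}

#' GNM normal modes by Kirchhoff diagonalization
#'
#' Eigenvalues are returned ascending; eigenvector signs are fixed so each
#' mode's largest-magnitude entry is positive (deterministic output).
#' Eigenvalues below `1e-9 * max(lambda)` are counted as zero modes (one
#' per connected component of the contact graph).
#'
#' @param model A [build_kirchhoff()] model.
#' @param n_modes Number of modes to retain (`"all"` keeps all N).
#' @return An object of class `gnm_modes` with `eigenvalues`,
#'   `eigenvectors` (N x K, unit columns), `n_zero_modes` and model
#'   metadata.
#' @export
gnm_modes <- function(model, n_modes = "all") {
  gm <- model$gamma_matrix
  eig <- eigen(gm, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  values[abs(values) < 1e-12] <- pmax(values[abs(values) < 1e-12], 0)
  nz_tol <- 1e-9 * max(values)
  n_zero <- sum(values < nz_tol)
  for (k in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, k]))
    if (vectors[i, k] < 0) vectors[, k] <- -vectors[, k]
  }
  if (!identical(n_modes, "all")) {
    keep <- seq_len(min(as.integer(n_modes), ncol(vectors)))
    values <- values[keep]
    vectors <- vectors[, keep, drop = FALSE]
    n_zero <- sum(values < nz_tol)
  }
  structure(
    list(eigenvalues = values, eigenvectors = vectors, n_zero_modes = n_zero,
         spring_gamma = model$spring_gamma, kBT = model$kBT,
         cutoff_rc = model$cutoff_rc, labels = model$labels),
    class = "gnm_modes"
  )
}

#' @export
print.gnm_modes <- function(x, ...) {
  cat(sprintf("<gnm_modes> %d modes (%d zero), slowest non-zero lambda = %.4g\n",
              length(x$eigenvalues), x$n_zero_modes,
              x$eigenvalues[x$n_zero_modes + 1]))
  invisible(x)
}

#' Per-mode summary of a GNM mode set
#'
#' @param x A [gnm_modes()] object.
#' @param ... Unused.
#' @return Tibble with mode index, eigenvalue, zero-mode flag and
#'   collectivity.
#' @export
tidy.gnm_modes <- function(x, ...) {
  tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    zero_mode = seq_along(x$eigenvalues) <= x$n_zero_modes,
    collectivity = vapply(seq_along(x$eigenvalues), function(k) {
      mode_collectivity(x$eigenvectors[, k])
    }, numeric(1))
  )
}

nonzero_mode_indices <- function(modes) {
  setdiff(seq_along(modes$eigenvalues), seq_len(modes$n_zero_modes))
}

#' Mean-square fluctuations from a subset of GNM modes
#'
#' `MSF_i = (3 kBT / gamma) * sum_k u_k(i)^2 / lambda_k` over the selected
#' non-zero modes; with all non-zero modes this equals the diagonal of the
#' Kirchhoff pseudo-inverse scaled by `3 kBT / gamma`.
#'
#' @param modes A [gnm_modes()] object.
#' @param mode_indices Integer indices of modes to include (1 = slowest,
#'   including zero modes in the count); default all non-zero modes.
#' @param kBT,gamma Override the model's thermal energy / spring constant.
#' @return Numeric vector of per-residue MSF (length N).
#' @export
mode_msf <- function(modes, mode_indices = NULL, kBT = NULL, gamma = NULL) {
  kBT <- kBT %||% modes$kBT
  gamma <- gamma %||% modes$spring_gamma
  mode_indices <- mode_indices %||% nonzero_mode_indices(modes)
  if (any(mode_indices <= modes$n_zero_modes)) {
    abort("zero modes cannot contribute to fluctuations (lambda = 0)")
  }
  u <- modes$eigenvectors[, mode_indices, drop = FALSE]
  lam <- modes$eigenvalues[mode_indices]
  msf <- (3 * kBT / gamma) * as.numeric(u^2 %*% (1 / lam))
  names(msf) <- modes$labels
  msf
}

#' Slow-mode mobility profile and hinge residues
#'
#' The essential mobility profile is the cumulative mean-square fluctuation
#' over the `k_slowest` slowest non-zero GNM modes, max-normalised to 1.
#' Hinge residues — the rigid pivot points of the global motions — are
#' strict local minima of the profile lying below a quantile threshold.
#'
#' @param modes A [gnm_modes()] object.
#' @param k_slowest Number of slowest non-zero modes (default 5).
#' @param hinge_quantile Profile quantile below which a local minimum
#'   counts as a hinge (default 0.25).
#' @return An object of class `mode_profile`; `tidy()` gives a per-residue
#'   tibble with `mobility` and `hinge`.
#' @export
slow_mode_profile <- function(modes, k_slowest = 5, hinge_quantile = 0.25) {
  nz <- nonzero_mode_indices(modes)
  if (length(nz) < 1L) abort("no non-zero modes available")
  k_slowest <- min(k_slowest, length(nz))
  msf <- mode_msf(modes, mode_indices = nz[seq_len(k_slowest)])
  profile <- msf / max(msf)
  n <- length(profile)
  thresh <- quantile(profile, hinge_quantile, names = FALSE)
  hinge <- rep(FALSE, n)
  tol <- 1e-9  # ignore floating-point wrinkles on flat profiles
  if (n >= 3L) {
    for (i in 2:(n - 1)) {
      hinge[i] <- profile[i] < profile[i - 1] - tol &&
        profile[i] < profile[i + 1] - tol &&
        profile[i] <= thresh
    }
  }
  structure(
    list(profile = profile, hinge = hinge, k_slowest = k_slowest,
         hinge_quantile = hinge_quantile, labels = names(profile)),
    class = "mode_profile"
  )
}

#' @export
tidy.mode_profile <- function(x, ...) {
  tibble(
    index = seq_along(x$profile),
    label = x$labels,
    mobility = unname(x$profile),
    hinge = x$hinge
  )
}

#' @export
print.mode_profile <- function(x, ...) {
  cat(sprintf("<mode_profile> %d residues, %d slowest modes, %d hinge(s)\n",
              length(x$profile), x$k_slowest, sum(x$hinge)))
  invisible(x)
}

#' Degree of collectivity of a mode vector
#'
#' `kappa = exp(-sum p_i log p_i) / N` with `p_i = u_i^2 / sum u^2`: the
#' entropy-based fraction of residues effectively participating in the
#' mode. 1 means uniform participation, 1/N a single residue.
#'
#' @param mode_vector Numeric vector (any non-zero norm; normalised
#'   internally).
#' @return Scalar in (0, 1].
#' @export
mode_collectivity <- function(mode_vector) {
  p <- mode_vector^2
  s <- sum(p)
  if (s <= 0) abort("mode vector has zero norm")
  p <- p / s
  nz <- p > 0
  exp(-sum(p[nz] * log(p[nz]))) / length(mode_vector)
}

# Reduce 3N Cartesian component vectors to N per-residue magnitudes.
pc_residue_magnitudes <- function(pcs, m) {
  comp <- pcs$components[, seq_len(m), drop = FALSE]
  if (pcs$space == "resdisp") return(comp)
  n <- nrow(comp) / 3L
  out <- apply(comp, 2, function(v) {
    mag <- sqrt(rowSums(matrix(v, ncol = 3L, byrow = TRUE)^2))
    mag / sqrt(sum(mag^2))
  })
  matrix(out, nrow = n)
}

#' Cumulative overlap between GNM slow modes and ensemble PCs
#'
#' `CO = sqrt( sum_{k<=K} sum_{j<=m} (u_k . v_j)^2 / K )`: how much of the
#' K slowest GNM modes' subspace is captured by the first m principal
#' components of an ensemble. Cartesian (3N) PCs are projected to
#' per-residue displacement magnitudes and re-normalised so both sets live
#' in the same N-dimensional space; `pc_model`s built in `"resdisp"` space
#' are used as-is.
#'
#' @param modes A [gnm_modes()] object.
#' @param k_slowest Number of slowest non-zero modes (default 5).
#' @param pcs A [ensemble_pca()] model.
#' @param m_components Number of leading PCs (default 5).
#' @param symmetric If `TRUE`, return the symmetric subspace overlap
#'   (root-mean over both mode and PC counts).
#' @return Scalar in [0, 1].
#' @export
cumulative_overlap <- function(modes, k_slowest = 5, pcs, m_components = 5,
                               symmetric = FALSE) {
  nz <- nonzero_mode_indices(modes)
  k_slowest <- min(k_slowest, length(nz))
  u <- modes$eigenvectors[, nz[seq_len(k_slowest)], drop = FALSE]
  m_components <- min(m_components, ncol(pcs$components))
  v <- pc_residue_magnitudes(pcs, m_components)
  if (nrow(v) != nrow(u)) {
    abort(sprintf("dimension mismatch: %d mode residues vs %d PC residues",
                  nrow(u), nrow(v)))
  }
  # re-orthonormalise the projected PC set so overlap stays in [0, 1]
  v <- qr.Q(qr(v))[, seq_len(min(m_components, ncol(v))), drop = FALSE]
  dots2 <- crossprod(u, v)^2
  denom <- if (symmetric) sqrt(k_slowest * ncol(v)) else k_slowest
  co <- sqrt(sum(dots2) / denom)
  min(co, 1)
}

#' Inter-residue distance-fluctuation map
#'
#' `<(d_ij - <d_ij>)^2> = MSF_i + MSF_j - 2 C_ij` in the GNM, with `C_ij`
#' the mode-restricted residue covariance. Large entries mark residue pairs
#' whose separation breathes in the selected modes; rigid blocks show small
#' values.
#'
#' @inheritParams mode_msf
#' @return Symmetric non-negative N x N matrix with zero diagonal.
#' @export
distance_fluctuation_map <- function(modes, mode_indices = NULL,
                                     kBT = NULL, gamma = NULL) {
  kBT <- kBT %||% modes$kBT
  gamma <- gamma %||% modes$spring_gamma
  mode_indices <- mode_indices %||% nonzero_mode_indices(modes)
  if (any(mode_indices <= modes$n_zero_modes)) {
    abort("zero modes cannot contribute to fluctuations (lambda = 0)")
  }
  u <- modes$eigenvectors[, mode_indices, drop = FALSE]
  lam <- modes$eigenvalues[mode_indices]
  cov_ij <- (3 * kBT / gamma) * (u %*% (t(u) / lam))
  msf <- diag(cov_ij)
  m <- outer(msf, rep(1, length(msf))) + outer(rep(1, length(msf)), msf) - 2 * cov_ij
  m <- (m + t(m)) / 2
  m[m < 0] <- 0
  diag(m) <- 0
  dimnames(m) <- list(modes$labels, modes$labels)
  m
}

#' Plot a slow-mode mobility profile
#'
#' @param object A [slow_mode_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mode_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$mobility)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = df[df$hinge, , drop = FALSE],
      colour = "firebrick", size = 2
    ) +
    ggplot2::labs(
      x = "Residue", y = "Normalised mobility",
      title = sprintf("Slow-mode mobility (%d modes); hinges in red", object$k_slowest)
    ) +
    ggplot2::theme_minimal()
}
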