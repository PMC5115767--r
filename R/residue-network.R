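#' Edge eligibility from persistent structural contacts
#'
#' An edge between two residues is eligible when their minimum heavy-atom
#' distance is within `cutoff` in at least a `persistence` fraction of
#' frames. A static structure counts as a single frame. Ensemble frames
#' carry alpha-carbon coordinates only, so per-frame contacts use CA
#' distances there.
#'
#' @param geometry A [new_structure()] or [new_ensemble()].
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @param persistence Minimum fraction of frames with the contact present
#'   (default 0.5).
#' @param mode Distance convention for static structures (`"heavy_min"`
#'   default, `"ca"` optional).
#' @return Tibble with `i`, `j` (`i < j`) and `persistence` (observed
#'   fraction).
#' @export
contact_eligibility <- function(geometry, cutoff = 4.5, persistence = 0.5,
                                mode = c("heavy_min", "ca")) {
  mode <- match.arg(mode)
  if (inherits(geometry, "coev_structure")) {
    cp <- contact_pairs(geometry, cutoff, mode = mode)
    return(tibble(i = cp$i, j = cp$j, persistence = 1))
  }
  if (!inherits(geometry, "conformer_ensemble")) {
    abort("`geometry` must be a coev_structure or conformer_ensemble")
  }
  f <- n_frames(geometry)
  n <- dim(geometry$frames)[2]
  count <- matrix(0, n, n)
  for (k in seq_len(f)) {
    xyz <- geometry$frames[k, , , drop = TRUE]
    d <- cross_dist(xyz, xyz)
    count <- count + (d <= cutoff)
  }
  frac <- count / f
  diag(frac) <- 0
  keep <- which(upper.tri(frac) & frac >= persistence, arr.ind = TRUE)
  tibble(i = keep[, 1], j = keep[, 2], persistence = frac[keep]) |>
    dplyr::arrange(.data$i, .data$j)
}

#' Build the coevolution- and dynamics-weighted residue network
#'
#' Eligible residue contacts become edges whose length is
#' `w_ij = -log(r_combined)`, with
#' `r_combined = (1 - alpha) * r_dyn + alpha * r_coev`: a blend of the
#' generalized correlation coefficient of residue dynamics and a
#' coevolution score (pair z-scores min-max rescaled to [0, 1] over the
#' eligible edges). `alpha = 0` gives a purely dynamic network. Weights
#' are clipped into `[-log(1 - eps), -log(eps)]` so edge lengths stay
#' finite and positive.
#'
#' @param eligibility Edge tibble from [contact_eligibility()] (columns
#'   `i`, `j`).
#' @param dynamic_corr A `corr_matrix` ([generalized_correlation()] or
#'   [analytic_gnm_correlation()]).
#' @param coevo_corr Optional symmetric matrix of pair coevolution scores
#'   (e.g. the `z` table of [mutual_information()] mapped to residue
#'   indices); `NULL` forces `alpha = 0`.
#' @param alpha Blend weight in [0, 1] (default 0.5; forced to 0 when
#'   `coevo_corr` is `NULL`).
#' @param eps Clipping floor for correlations (default 1e-4).
#' @param labels Optional residue labels for reporting.
#' @return An object of class `residue_network` with an `edges` tibble and
#'   an `igraph` graph.
#' @export
build_network <- function(eligibility, dynamic_corr, coevo_corr = NULL,
                          alpha = 0.5, eps = 1e-4, labels = NULL) {
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1]")
  if (nrow(eligibility) == 0L) abort("no eligible edges")
  r_dyn <- dynamic_corr$r_mi
  n <- nrow(r_dyn)
  ii <- eligibility$i
  jj <- eligibility$j
  if (max(c(ii, jj)) > n) abort("eligibility indices exceed correlation matrix size")
  rd <- r_dyn[cbind(ii, jj)]
  if (is.null(coevo_corr)) {
    alpha <- 0
    rc <- rep(0, length(rd))
  } else {
    raw <- coevo_corr[cbind(ii, jj)]
    raw[is.na(raw)] <- min(raw, na.rm = TRUE)
    rng <- range(raw)
    rc <- if (diff(rng) < 1e-12) rep(0.5, length(raw)) else (raw - rng[1]) / diff(rng)
  }
  r_comb <- (1 - alpha) * rd + alpha * rc
  w <- -log(clamp(r_comb, eps, 1 - eps))
  edges <- tibble(i = ii, j = jj, r = r_comb, weight = w)
  labels <- labels %||% as.character(seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii, to = jj, weight = w),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n)))
  )
  structure(
    list(edges = edges, graph = g, n_nodes = n, labels = labels,
         alpha = alpha, eps = eps),
    class = "residue_network"
  )
}

#' @export
print.residue_network <- function(x, ...) {
  cat(sprintf("<residue_network> %d nodes, %d edges, alpha = %.2f\n",
              x$n_nodes, nrow(x$edges), x$alpha))
  invisible(x)
}

#' @export
tidy.residue_network <- function(x, ...) {
  dplyr::mutate(x$edges,
                label_i = x$labels[.data$i],
                label_j = x$labels[.data$j])
}

#' One-row network summary
#'
#' @param x A `residue_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, blend alpha and global efficiency.
#' @export
glance.residue_network <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes,
    n_edges = nrow(x$edges),
    alpha = x$alpha,
    efficiency = network_efficiency(x)
  )
}

# Dense symmetric weight matrix with Inf for non-edges.
weight_matrix <- function(network) {
  n <- network$n_nodes
  w <- matrix(Inf, n, n)
  diag(w) <- 0
  w[cbind(network$edges$i, network$edges$j)] <- network$edges$weight
  w[cbind(network$edges$j, network$edges$i)] <- network$edges$weight
  w
}

#' Normalised betweenness centrality of network residues
#'
#' The fraction of weighted shortest paths between all residue pairs that
#' pass through each residue, counting all co-optimal paths, normalised
#' per connected component by the `(N-1)(N-2)/2` pairs that exclude the
#' residue.
#'
#' @param network A [build_network()] object.
#' @return Tibble with `residue`, `label`, `betweenness` (raw path-count
#'   sum) and `centrality` (normalised to [0, 1]).
#' @export
betweenness_centrality <- function(network) {
  g <- network$graph
  raw <- igraph::betweenness(g, directed = FALSE,
                             weights = igraph::E(g)$weight, normalized = FALSE)
  comp <- igraph::components(g)
  norm <- vapply(seq_len(network$n_nodes), function(v) {
    nc <- comp$csize[comp$membership[v]]
    if (nc < 3L) return(NA_real_)
    (nc - 1) * (nc - 2) / 2
  }, numeric(1))
  centrality <- ifelse(is.na(norm), 0, raw / norm)
  tibble(
    residue = seq_len(network$n_nodes),
    label = network$labels,
    betweenness = unname(raw),
    centrality = unname(centrality)
  )
}

#' Communication propensity of residues
#'
#' Residues whose effective distance to the rest of the protein — mean
#' inter-residue distance `d_i` and mean proximity-MI difference
#' `dpM_i` — fluctuates little across the ensemble communicate
#' efficiently. The default `"ratio"` form is
#' `CP_i = 3 kBT / (w1 Var(d_i) + w2 Var(dpM_i))`, so small fluctuations
#' give large CP; the `"literal_product"` form
#' `CP_i = 3 kBT * (w1 Var(d_i) + w2 Var(dpM_i))` is retained behind a
#' flag for auditability.
#'
#' @param stats An [ensemble_stats()] object (>= 2 frames).
#' @param w1,w2 Non-negative weighting factors for the distance and pMI
#'   fluctuation terms (not both 0).
#' @param kBT Thermal energy; the default 0.0019872041 * 300 kcal/mol
#'   corresponds to T = 300 K.
#' @param form `"ratio"` (default) or `"literal_product"`.
#' @return Tibble with `residue`, `cp` (`NA` where the denominator
#'   vanishes in ratio form).
#' @export
communication_propensity <- function(stats, w1 = 1, w2 = 1,
                                     kBT = 0.0019872041 * 300,
                                     form = c("ratio", "literal_product")) {
  form <- match.arg(form)
  if (stats$frame_count < 2L) abort("communication propensity needs >= 2 frames")
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0) {
    abort("w1 and w2 must be non-negative and not both zero")
  }
  denom <- w1 * stats$var_d_i + w2 * stats$var_delta_pmi_i
  cp <- if (form == "ratio") {
    out <- 3 * kBT / denom
    if (any(denom <= 0)) {
      warn(sprintf("%d residue(s) have zero fluctuation variance; CP reported as NA",
                   sum(denom <= 0)))
      out[denom <= 0] <- NA_real_
    }
    out
  } else {
    3 * kBT * denom
  }
  tibble(residue = seq_along(cp), cp = as.numeric(cp))
}

#' All-pairs shortest communication paths (Floyd-Warshall)
#'
#' Computes the full matrix of shortest path lengths over the weighted
#' residue network by Floyd-Warshall relaxation, plus for every pair one
#' canonical shortest path (deterministic tie-break: lexicographically
#' smallest node sequence) and the number of co-optimal shortest paths.
#'
#' @param network A [build_network()] object (all weights positive).
#' @return An object of class `shortest_paths` with `distances` (N x N,
#'   `Inf` for unreachable pairs), `next_hop` and `n_paths` matrices.
#'   Extract paths with [extract_path()].
#' @export
shortest_paths_fw <- function(network) {
  w <- weight_matrix(network)
  if (any(network$edges$weight <= 0)) abort("edge weights must be positive")
  n <- nrow(w)
  d <- w
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  tol <- 1e-12
  # canonical next hop: smallest neighbour v of i with w(i,v) + d(v,j) = d(i,j)
  nxt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    nb <- which(is.finite(w[i, ]) & seq_len(n) != i)
    for (j in seq_len(n)) {
      if (i == j || !is.finite(d[i, j])) next
      ok <- nb[abs(w[i, nb] + d[nb, j] - d[i, j]) <= tol * max(1, d[i, j])]
      ok <- c(ok, nb[nb == j & abs(w[i, nb] - d[i, j]) <= tol])
      if (length(ok)) nxt[i, j] <- min(ok)
    }
  }
  n_paths <- count_shortest_paths(w, d, tol)
  structure(
    list(distances = d, next_hop = nxt, n_paths = n_paths,
         labels = network$labels),
    class = "shortest_paths"
  )
}

# Number of distinct shortest paths per pair, by DP over the shortest-path
# DAG from each source (nodes processed in order of distance).
count_shortest_paths <- function(w, d, tol) {
  n <- nrow(w)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    g <- rep(0, n)
    g[i] <- 1
    ord <- order(d[i, ])
    for (j in ord) {
      if (j == i || !is.finite(d[i, j])) next
      preds <- which(is.finite(w[, j]) & seq_len(n) != j)
      on_path <- preds[abs(d[i, preds] + w[preds, j] - d[i, j]) <= tol * max(1, d[i, j])]
      g[j] <- sum(g[on_path])
    }
    out[i, ] <- g
  }
  diag(out) <- 1
  out
}

#' Reconstruct the canonical shortest path between two residues
#'
#' @param sp A [shortest_paths_fw()] result.
#' @param source,target 1-based residue indices.
#' @return Integer vector of node indices from `source` to `target`, or
#'   `NULL` when unreachable.
#' @export
extract_path <- function(sp, source, target) {
  if (source == target) return(source)
  if (!is.finite(sp$distances[source, target])) return(NULL)
  path <- source
  cur <- source
  while (cur != target) {
    cur <- sp$next_hop[cur, target]
    if (is.na(cur) || cur %in% path) abort("path reconstruction failed")
    path <- c(path, cur)
  }
  path
}

#' Global efficiency of a residue network
#'
#' Mean of inverse shortest-path lengths over all ordered residue pairs;
#' unreachable pairs contribute 0. Scaling all edge weights by c divides
#' the efficiency by c.
#'
#' @param network A [build_network()] object.
#' @param sp Optional precomputed [shortest_paths_fw()] result.
#' @return Scalar efficiency.
#' @export
network_efficiency <- function(network, sp = NULL) {
  d <- if (is.null(sp)) {
    w <- weight_matrix(network)
    n <- nrow(w)
    dd <- w
    for (k in seq_len(n)) dd <- pmin(dd, outer(dd[, k], dd[k, ], "+"))
    dd
  } else {
    sp$distances
  }
  n <- nrow(d)
  if (n < 2L) abort("efficiency needs at least one residue pair")
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

#' Optimise CP weighting factors for network efficiency
#'
#' Grid search over `(w1, w2)`: for each grid point communication
#' propensities are computed, the `prune_quantile` lowest-CP nodes are
#' removed from the network (low-propensity residues are poor
#' communicators), and the global efficiency of the pruned network is
#' measured. Returns the grid point maximising efficiency
#' (lexicographically smallest `(w1, w2)` on ties) with the full surface.
#'
#' @param stats An [ensemble_stats()] object.
#' @param network A [build_network()] object.
#' @param w1_grid,w2_grid Non-negative numeric grids (not both all-zero).
#' @param prune_quantile Fraction of lowest-CP nodes removed before
#'   measuring efficiency (default 0.1).
#' @param kBT Thermal energy passed to [communication_propensity()].
#' @return List with `w1`, `w2`, `efficiency` and `surface` (tibble of all
#'   grid points).
#' @export
optimize_weights <- function(stats, network, w1_grid, w2_grid,
                             prune_quantile = 0.1,
                             kBT = 0.0019872041 * 300) {
  if (length(w1_grid) == 0L || length(w2_grid) == 0L) abort("grids must be non-empty")
  if (any(w1_grid < 0) || any(w2_grid < 0)) abort("grids must be non-negative")
  grid <- expand.grid(w1 = sort(w1_grid), w2 = sort(w2_grid))
  grid <- grid[grid$w1 + grid$w2 > 0, , drop = FALSE]
  if (nrow(grid) == 0L) abort("grids must contain a point with w1 + w2 > 0")
  eff <- vapply(seq_len(nrow(grid)), function(r) {
    cp <- suppressWarnings(
      communication_propensity(stats, grid$w1[r], grid$w2[r], kBT = kBT)
    )
    efficiency_after_prune(network, cp$cp, prune_quantile)
  }, numeric(1))
  surface <- tibble(w1 = grid$w1, w2 = grid$w2, efficiency = eff)
  if (diff(range(eff)) < 1e-14) {
    warn("efficiency surface is degenerate (all grid points equal)")
  }
  best <- surface[order(-surface$efficiency, surface$w1, surface$w2), ][1, ]
  list(w1 = best$w1, w2 = best$w2, efficiency = best$efficiency,
       surface = surface)
}

# Efficiency of the network restricted to nodes above the CP quantile.
efficiency_after_prune <- function(network, cp, prune_quantile) {
  keep <- seq_len(network$n_nodes)
  if (prune_quantile > 0) {
    scored <- which(!is.na(cp))
    thr <- quantile(cp[scored], prune_quantile, names = FALSE)
    drop <- scored[cp[scored] < thr]
    keep <- setdiff(keep, drop)
  }
  if (length(keep) < 2L) return(0)
  sub_edges <- network$edges[network$edges$i %in% keep & network$edges$j %in% keep, ]
  if (nrow(sub_edges) == 0L) return(0)
  remap <- match(seq_len(network$n_nodes), keep)
  sub <- structure(
    list(edges = tibble(i = remap[sub_edges$i], j = remap[sub_edges$j],
                        r = sub_edges$r, weight = sub_edges$weight),
         n_nodes = length(keep),
         labels = network$labels[keep]),
    class = "residue_network"
  )
  network_efficiency(sub)
}

#' Shortest-path ensembles with occupancies
#'
#' Splits a conformer ensemble into `blocks` contiguous equal blocks,
#' builds one residue network per block (via `builder`), computes the
#' canonical shortest source-to-target path per block, and reports each
#' distinct node sequence with its occupancy — the fraction of blocks in
#' which it is the optimal route. Blocks where the target is unreachable
#' count toward a "no path" category so occupancies always total 1.
#'
#' @param ensemble A [new_ensemble()].
#' @param source,target 1-based residue indices (distinct).
#' @param blocks Number of blocks B (>= 2; occupancy is undefined for a
#'   single block).
#' @param builder Function taking a block's `conformer_ensemble` and
#'   returning a [build_network()] object.
#' @param k_suboptimal Also report up to k best suboptimal paths per block
#'   (default 0).
#' @return An object of class `path_ensemble`; `tidy()` lists paths with
#'   occupancies and mean lengths.
#' @export
path_ensemble <- function(ensemble, source, target, blocks = 10, builder,
                          k_suboptimal = 0) {
  if (blocks < 2L) abort("occupancy needs at least 2 blocks")
  if (source == target) abort("source and target must differ")
  f <- n_frames(ensemble)
  if (f < blocks) abort("fewer frames than blocks")
  bounds <- floor(seq(0, f, length.out = blocks + 1))
  seen <- list()
  no_path <- 0L
  subopt <- list()
  for (b in seq_len(blocks)) {
    idx <- (bounds[b] + 1):bounds[b + 1]
    block_ens <- new_ensemble(
      ensemble$reference,
      ensemble$frames[idx, , , drop = FALSE],
      frame_labels = ensemble$frame_labels[idx]
    )
    net <- builder(block_ens)
    sp <- shortest_paths_fw(net)
    path <- extract_path(sp, source, target)
    if (is.null(path)) {
      no_path <- no_path + 1L
      next
    }
    key <- paste(path, collapse = "-")
    if (is.null(seen[[key]])) {
      seen[[key]] <- list(path = path, count = 0L, lengths = numeric(0))
    }
    seen[[key]]$count <- seen[[key]]$count + 1L
    seen[[key]]$lengths <- c(seen[[key]]$lengths, sp$distances[source, target])
    if (k_suboptimal > 0) {
      ks <- igraph::k_shortest_paths(
        net$graph, from = as.character(source), to = as.character(target),
        k = k_suboptimal + 1L, weights = igraph::E(net$graph)$weight
      )
      subopt[[b]] <- lapply(ks$vpaths, function(v) as.integer(igraph::as_ids(v)))
    }
  }
  paths <- purrr::map(seen, identity)
  ord <- order(-vapply(paths, `[[`, integer(1), "count"),
               names(paths))
  paths <- paths[ord]
  structure(
    list(source = source, target = target, blocks = blocks,
         paths = paths, no_path_blocks = no_path,
         suboptimal = if (k_suboptimal > 0) subopt else NULL),
    class = "path_ensemble"
  )
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("<path_ensemble> %d -> %d over %d blocks: %d distinct path(s)\n",
              x$source, x$target, x$blocks, length(x$paths)))
  invisible(x)
}

#' Path ensemble as a tibble
#'
#' @param x A [path_ensemble()] result.
#' @param ... Unused.
#' @return Tibble with `path` (dash-joined node indices), `occupancy` and
#'   `mean_length`; a final `"(no path)"` row accounts for blocks without
#'   a route so occupancies sum to 1.
#' @export
tidy.path_ensemble <- function(x, ...) {
  counts <- unname(vapply(x$paths, `[[`, integer(1), "count"))
  out <- tibble(
    path = unname(vapply(x$paths, function(p) paste(p$path, collapse = "-"),
                         character(1))),
    n_blocks = counts,
    occupancy = counts / x$blocks,
    mean_length = unname(vapply(x$paths, function(p) mean(p$lengths), numeric(1)))
  )
  if (x$no_path_blocks > 0L) {
    out <- dplyr::bind_rows(out, tibble(
      path = "(no path)", n_blocks = x$no_path_blocks,
      occupancy = x$no_path_blocks / x$blocks, mean_length = NA_real_
    ))
  }
  out
}

#' Plot a residue centrality or CP profile
#'
#' @param object Tibble with a `residue` column and one value column
#'   (e.g. from [betweenness_centrality()] or
#'   [communication_propensity()]).
#' @param value Name of the value column (default the last column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_residue_profile <- function(object, value = NULL, ...) {
  value <- value %||% names(object)[ncol(object)]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data[[value]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Residue", y = value) +
    ggplot2::theme_minimal()
}
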