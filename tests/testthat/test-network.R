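test_that("network weights follow the -log(r) contract with clipping", {
  st <- make_structure(fixture_spec("dumbbell_dimer", n_residues = 8, seed = 5))
  n <- nrow(st$residues)
  elig <- contact_eligibility(st, 4.5)
  r <- matrix(0.5, n, n)
  diag(r) <- 1
  r[1, 2] <- r[2, 1] <- 1        # clipped to 1 - eps
  r[1, 3] <- r[3, 1] <- exp(-1)  # weight exactly 1
  dyn <- structure(list(r_mi = r, estimator = "gaussian", source = "ensemble"),
                   class = "corr_matrix")
  net <- build_network(elig, dyn, alpha = 0)
  eps <- net$eps
  e12 <- net$edges[net$edges$i == 1 & net$edges$j == 2, ]
  expect_equal(e12$weight, -log(1 - eps))
  e13 <- net$edges[net$edges$i == 1 & net$edges$j == 3, ]
  expect_equal(e13$weight, 1)

  # alpha = 0: edge set equals the persistent-contact list, weights -log r
  expect_equal(net$edges[, c("i", "j")], elig[, c("i", "j")])
  expect_equal(net$edges$weight,
               -log(pmin(pmax(r[cbind(elig$i, elig$j)], eps), 1 - eps)))
  expect_true(all(net$edges$weight > 0 & is.finite(net$edges$weight)))

  expect_error(build_network(elig, dyn, alpha = 1.2), "alpha")
  expect_error(build_network(elig[0, ], dyn), "no eligible")

  # efficiency is insensitive to the clipping floor when correlations are
  # not saturated
  r2 <- matrix(0.5, n, n)
  r2[1, 2] <- r2[2, 1] <- 0.9
  diag(r2) <- 1
  dyn2 <- structure(list(r_mi = r2, estimator = "gaussian", source = "ensemble"),
                    class = "corr_matrix")
  net_a <- build_network(elig, dyn2, alpha = 0, eps = 1e-4)
  net_b <- build_network(elig, dyn2, alpha = 0, eps = 1e-6)
  expect_lt(abs(network_efficiency(net_a) - network_efficiency(net_b)) /
              network_efficiency(net_a), 0.01)
})

test_that("betweenness matches trivial cases and exhaustive enumeration", {
  path3 <- manual_network(rbind(c(1, 2, 1), c(2, 3, 1)), 3)
  bc <- betweenness_centrality(path3)
  expect_equal(bc$centrality, c(0, 1, 0))

  # 50 random graphs with <= 8 nodes against full simple-path enumeration
  for (s in 1:50) {
    n <- sample(4:8, 1)
    net <- random_network(n, p_edge = 0.45, seed = s)
    got <- betweenness_centrality(net)$centrality
    want <- oracle_betweenness(net$edges, n)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("Floyd-Warshall distances agree with igraph and stay consistent", {
  # relaxation beats the direct edge on a weighted triangle
  tri <- manual_network(rbind(c(1, 2, 1), c(2, 3, 1), c(1, 3, 3)), 3)
  sp <- shortest_paths_fw(tri)
  expect_equal(sp$distances[1, 3], 2)
  expect_equal(extract_path(sp, 1, 3), c(1, 2, 3))

  # single edge
  one <- manual_network(rbind(c(1, 2, 0.7)), 2)
  sp1 <- shortest_paths_fw(one)
  expect_equal(sp1$distances[1, 2], 0.7)
  expect_equal(extract_path(sp1, 1, 2), c(1, 2))

  # cross-algorithm oracle on 50 random 30-node graphs
  for (s in 1:50) {
    net <- random_network(30, p_edge = 0.12, seed = 100 + s)
    sp <- shortest_paths_fw(net)
    ig <- igraph::distances(net$graph, weights = igraph::E(net$graph)$weight)
    expect_equal(sp$distances, ig, tolerance = 1e-10, ignore_attr = TRUE)
  }

  # canonical paths are reproducible from the distance matrix
  net <- random_network(12, p_edge = 0.3, seed = 77)
  sp <- shortest_paths_fw(net)
  w <- coevnet:::weight_matrix(net)
  for (pair in list(c(1, 12), c(3, 9), c(5, 7))) {
    p <- extract_path(sp, pair[1], pair[2])
    len <- sum(w[cbind(p[-length(p)], p[-1])])
    expect_equal(len, sp$distances[pair[1], pair[2]], tolerance = 1e-10)
  }

  # co-optimal path counts: two equal parallel routes
  sq <- manual_network(rbind(c(1, 2, 1), c(2, 4, 1), c(1, 3, 1), c(3, 4, 1)), 4)
  spq <- shortest_paths_fw(sq)
  expect_equal(spq$n_paths[1, 4], 2)
  # lexicographic tie-break picks the route through node 2
  expect_equal(extract_path(spq, 1, 4), c(1, 2, 4))

  # unreachable pairs are infinite
  disc <- manual_network(rbind(c(1, 2, 1)), 3)
  expect_equal(shortest_paths_fw(disc)$distances[1, 3], Inf)
})

test_that("adding an edge never increases any shortest distance", {
  for (s in 1:5) {
    net <- random_network(10, p_edge = 0.25, seed = 200 + s)
    d0 <- shortest_paths_fw(net)$distances
    # add one absent edge
    absent <- which(!is.finite(coevnet:::weight_matrix(net)) &
                      upper.tri(matrix(0, 10, 10)), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    add <- absent[1, ]
    edges2 <- dplyr::bind_rows(net$edges,
                               tibble::tibble(i = add[1], j = add[2],
                                              r = NA_real_, weight = 0.5))
    net2 <- manual_network(as.matrix(edges2[, c("i", "j", "weight")]), 10)
    d1 <- shortest_paths_fw(net2)$distances
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("network efficiency matches brute force and is homogeneous", {
  one <- manual_network(rbind(c(1, 2, 0.4)), 2)
  expect_equal(network_efficiency(one), 1 / 0.4)

  net <- random_network(5, p_edge = 0.6, seed = 9)
  sp <- shortest_paths_fw(net)
  # brute-force mean of inverse path lengths over ordered pairs
  acc <- 0
  for (i in 1:5) {
    for (j in setdiff(1:5, i)) {
      best <- oracle_best_paths(net$edges, 5, i, j)
      acc <- acc + (if (is.finite(best$len)) 1 / best$len else 0)
    }
  }
  expect_equal(network_efficiency(net, sp), acc / 20, tolerance = 1e-10)

  # scaling all weights by c divides efficiency by c
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 3
  scaled <- manual_network(as.matrix(scaled$edges[, c("i", "j", "weight")]), 5)
  expect_equal(network_efficiency(scaled), network_efficiency(net) / 3,
               tolerance = 1e-10)
})

test_that("communication propensity follows the ratio form", {
  # default thermal energy corresponds to T = 300 K
  expect_equal(eval(formals(communication_propensity)$kBT), 0.0019872041 * 300)

  st3 <- make_structure(fixture_spec("chain", n_residues = 3))
  f1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0))
  frames <- array(NA_real_, c(2, 3, 3))
  frames[1, , ] <- f1
  frames[2, , ] <- f2
  es <- ensemble_stats(new_ensemble(st3, frames))

  kBT <- 0.0019872041 * 300
  cp <- suppressWarnings(communication_propensity(es, w1 = 1, w2 = 0))
  # var(d_1) = 0.0625 by hand; CP = 3 kBT / 0.0625
  expect_equal(cp$cp[1], 3 * kBT / 0.0625)
  # middle residue has zero variance: NA in ratio form
  expect_true(is.na(cp$cp[2]))

  # doubling all variances halves CP
  es2 <- es
  es2$var_d_i <- es$var_d_i * 2
  cp2 <- suppressWarnings(communication_propensity(es2, w1 = 1, w2 = 0))
  expect_equal(cp2$cp[c(1, 3)], cp$cp[c(1, 3)] / 2)

  # literal product form
  cpl <- communication_propensity(es, w1 = 1, w2 = 0, form = "literal_product")
  expect_equal(cpl$cp[1], 3 * kBT * 0.0625)

  expect_error(communication_propensity(es, w1 = 0, w2 = 0), "not both zero")
})

test_that("weight optimisation rejects a noisy pMI term", {
  # star network through node 3; nodes 1-2 and 4-5 weakly linked so the
  # graph stays connected if the hub is pruned
  net <- manual_network(rbind(
    c(1, 3, 0.5), c(2, 3, 0.5), c(3, 4, 0.5), c(3, 5, 0.5),
    c(1, 2, 3), c(4, 5, 3)
  ), 5)
  stats <- structure(list(
    mean_pair_distances = matrix(1, 5, 5),
    d_i = rep(1, 5),
    var_d_i = c(1, 1, 0.1, 1, 1),          # hub fluctuates least
    delta_pmi_i = rep(0, 5),
    var_delta_pmi_i = c(0.01, 0.01, 100, 0.01, 0.01),  # pMI term pure noise
    frame_count = 10L
  ), class = "ensemble_stats")

  opt <- optimize_weights(stats, net, w1_grid = 1, w2_grid = c(0, 1),
                          prune_quantile = 0.2)
  expect_equal(opt$w2, 0)
  expect_equal(nrow(opt$surface), 2L)

  # single grid point returns that point (degenerate surface warns)
  expect_warning(opt1 <- optimize_weights(stats, net, w1_grid = 2, w2_grid = 0),
                 "degenerate")
  expect_equal(c(opt1$w1, opt1$w2), c(2, 0))

  # surface values are reproducible by direct re-evaluation
  for (r in seq_len(nrow(opt$surface))) {
    cp <- suppressWarnings(
      communication_propensity(stats, opt$surface$w1[r], opt$surface$w2[r])
    )
    expect_equal(opt$surface$efficiency[r],
                 coevnet:::efficiency_after_prune(net, cp$cp, 0.2))
  }
})

test_that("path ensembles find the bottleneck and split symmetric routes", {
  # single-bridge dumbbell: the bridge edge is the only inter-unit route
  spec <- fixture_spec("dumbbell_dimer", n_residues = 12, interface_edges = 1,
                       seed = 4)
  st <- make_structure(spec)
  modes <- gnm_modes(build_kirchhoff(st))
  ens <- sample_conformers_gnm(st, modes, 60, amplitude = 0.05, seed = 6)
  elig0 <- contact_eligibility(st, 4.5)
  bridge <- elig0[st$residues$chain[elig0$i] != st$residues$chain[elig0$j], ]
  expect_equal(nrow(bridge), 1L)

  builder <- function(block_ens) {
    be <- contact_eligibility(block_ens, cutoff = 4.5)
    bd <- generalized_correlation(block_ens)
    build_network(be, bd, alpha = 0)
  }
  pe <- path_ensemble(ens, bridge$i[1], bridge$j[1], blocks = 4,
                      builder = builder)
  tab <- tidy(pe)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occupancy, 1.0)
  expect_equal(tab$path, paste(c(bridge$i[1], bridge$j[1]), collapse = "-"))

  # occupancies (including any no-path category) always sum to 1
  expect_equal(sum(tab$occupancy), 1)

  # two exactly symmetric routes with per-block noise: occupancy 0.5 +- 0.15
  base <- rbind(c(1, 2, 1), c(2, 3, 1), c(3, 6, 1),
                c(1, 4, 1), c(4, 5, 1), c(5, 6, 1))
  st6 <- make_structure(fixture_spec("chain", n_residues = 6))
  ens6 <- new_ensemble(st6, array(rep(st6$ca, each = 40), c(40, 6, 3)))
  set.seed(99)
  noisy_builder <- function(block_ens) {
    e <- base
    e[, 3] <- e[, 3] + runif(nrow(e), 0, 0.05)
    manual_network(e, 6)
  }
  pe2 <- path_ensemble(ens6, 1, 6, blocks = 20, builder = noisy_builder)
  tab2 <- tidy(pe2)
  expect_equal(nrow(tab2), 2L)
  expect_equal(sort(tab2$path), c("1-2-3-6", "1-4-5-6"))
  expect_true(all(abs(tab2$occupancy - 0.5) <= 0.15))
  expect_equal(sum(tab2$occupancy), 1)

  # reported lengths are consistent with the block networks (deterministic
  # builder)
  det_builder <- function(block_ens) manual_network(base, 6)
  pe3 <- path_ensemble(ens6, 1, 6, blocks = 4, builder = det_builder)
  tab3 <- tidy(pe3)
  expect_equal(tab3$mean_length[1], 3, tolerance = 1e-10)

  # guards
  expect_error(path_ensemble(ens6, 1, 6, blocks = 1, builder = det_builder),
               "at least 2")
  expect_error(path_ensemble(ens6, 2, 2, blocks = 4, builder = det_builder),
               "must differ")

  # suboptimal paths are reported when requested
  pe4 <- path_ensemble(ens6, 1, 6, blocks = 2, builder = det_builder,
                       k_suboptimal = 2)
  expect_false(is.null(pe4$suboptimal))
  expect_true(length(pe4$suboptimal[[1]]) >= 2)
})
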