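# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formula
# evaluation, alternative algorithms.

# Exhaustive contact oracle: O(N^2 * atoms^2) double loop.
oracle_contacts <- function(structure, cutoff, mode) {
  n <- nrow(structure$residues)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- if (mode == "ca") {
        sqrt(sum((structure$ca[i, ] - structure$ca[j, ])^2))
      } else {
        best <- Inf
        for (a in seq_len(nrow(structure$heavy[[i]]))) {
          for (b in seq_len(nrow(structure$heavy[[j]]))) {
            best <- min(best, sqrt(sum((structure$heavy[[i]][a, ] -
                                          structure$heavy[[j]][b, ])^2)))
          }
        }
        best
      }
      if (d <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Horn's quaternion method for optimal superposition RMSD: an
# eigendecomposition route independent of the SVD-based Kabsch fit.
oracle_superposition_rmsd <- function(p, q) {
  pp <- sweep(p, 2, colMeans(p))
  qq <- sweep(q, 2, colMeans(q))
  m <- crossprod(pp, qq)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE)$values)
  e2 <- (sum(pp^2) + sum(qq^2) - 2 * lam) / nrow(p)
  sqrt(max(e2, 0))
}

# Direct weighted-frequency MI of two character columns (nats).
oracle_mi <- function(a, b) {
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint); pb <- colSums(joint)
  s <- 0
  for (x in rownames(joint)) {
    for (y in colnames(joint)) {
      if (joint[x, y] > 0) s <- s + joint[x, y] * log(joint[x, y] / (pa[x] * pb[y]))
    }
  }
  unname(s)
}

oracle_entropy <- function(col) {
  p <- table(col[col != "-"]) / sum(col != "-")
  -sum(p * log(p))
}

# All simple paths between two nodes of a small weighted graph
# (edge list with columns i, j, weight); returns min length and the
# set of co-optimal paths.
oracle_best_paths <- function(edges, n, from, to, tol = 1e-9) {
  adj <- vector("list", n)
  wmat <- matrix(Inf, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$weight[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    wmat[i, j] <- wmat[j, i] <- w
  }
  best <- list(len = Inf, paths = list())
  recurse <- function(path, len) {
    cur <- path[length(path)]
    if (cur == to) {
      if (len < best$len - tol) {
        best <<- list(len = len, paths = list(path))
      } else if (abs(len - best$len) <= tol) {
        best$paths[[length(best$paths) + 1]] <<- path
      }
      return()
    }
    for (nb in adj[[cur]]) {
      if (!(nb %in% path)) recurse(c(path, nb), len + wmat[cur, nb])
    }
  }
  recurse(from, 0)
  best
}

# Exhaustive normalised betweenness on a connected graph with <= 8 nodes.
oracle_betweenness <- function(edges, n) {
  raw <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      best <- oracle_best_paths(edges, n, j, k)
      if (!is.finite(best$len)) next
      g <- length(best$paths)
      for (i in setdiff(seq_len(n), c(j, k))) {
        gi <- sum(vapply(best$paths, function(p) i %in% p, logical(1)))
        raw[i] <- raw[i] + gi / g
      }
    }
  }
  raw / ((n - 1) * (n - 2) / 2)
}

# Random connected weighted graph as a build_network-compatible object.
random_network <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p_edge
    # always keep a random spanning tree to stay connected
    perm <- sample(n)
    tree <- cbind(perm[-n], perm[-1])
    tree <- t(apply(tree, 1, sort))
    keep[apply(pairs, 1, function(x) any(tree[, 1] == x[1] & tree[, 2] == x[2]))] <- TRUE
    if (sum(keep) >= n - 1) break
  }
  edges <- tibble::tibble(
    i = pairs[keep, 1], j = pairs[keep, 2],
    r = NA_real_, weight = round(runif(sum(keep), 0.2, 2), 3)
  )
  structure(
    list(edges = edges,
         graph = igraph::graph_from_data_frame(
           data.frame(from = edges$i, to = edges$j, weight = edges$weight),
           directed = FALSE,
           vertices = data.frame(name = as.character(seq_len(n)))
         ),
         n_nodes = n, labels = as.character(seq_len(n)), alpha = 0, eps = 1e-4),
    class = "residue_network"
  )
}

# Hand-built network from explicit edges (i, j, weight).
manual_network <- function(edge_mat, n) {
  edges <- tibble::tibble(
    i = edge_mat[, 1], j = edge_mat[, 2], r = NA_real_, weight = edge_mat[, 3]
  )
  structure(
    list(edges = edges,
         graph = igraph::graph_from_data_frame(
           data.frame(from = edges$i, to = edges$j, weight = edges$weight),
           directed = FALSE,
           vertices = data.frame(name = as.character(seq_len(n)))
         ),
         n_nodes = n, labels = as.character(seq_len(n)), alpha = 0, eps = 1e-4),
    class = "residue_network"
  )
}

# Minimal hand-written PDB text fixtures.
write_toy_pdb <- function(path, altloc = FALSE) {
  lines <- c(
    "HEADER    TOY",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    if (altloc) c(
      "ATOM      4  CA ASER A   3       9.600   1.000   0.000  0.30  0.00           C",
      "ATOM      5  CA BSER A   3       8.600   0.000   0.000  0.70  0.00           C"
    ) else
      "ATOM      4  CA  SER A   3       8.600   0.000   0.000  1.00  0.00           C",
    "TER",
    "END"
  )
  writeLines(lines, path)
  path
}
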