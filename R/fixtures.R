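#' Specification of a deterministic test fixture
#'
#' Fixture generators are pure functions of their spec: the seed fully
#' determines every output, so golden-file regression and property tests
#' are reproducible anywhere.
#'
#' @param kind `"chain"` (extended bead chain), `"ring"` (closed loop) or
#'   `"dumbbell_dimer"` (two compact globular clusters joined by a narrow
#'   interface — a minimal side-to-side dimer topology).
#' @param n_residues Residues per unit (>= 2).
#' @param spacing Bead spacing in Angstrom (default 3.8, the CA-CA virtual
#'   bond length).
#' @param interface_edges Number of inter-unit bridge contacts of the
#'   dumbbell dimer (default 1).
#' @param gap Face-to-face separation of the dimer units in Angstrom
#'   (default 6; bridge pairs are pulled to 4.0).
#' @param n_seqs,msa_length Alignment dimensions for [make_msa()]
#'   (`msa_length` defaults to the structure size).
#' @param planted_pairs 2-column matrix (or list of length-2 vectors) of
#'   covarying column pairs.
#' @param coupling_prob Probability that a planted pair follows its shared
#'   latent state (default 0.95).
#' @param conservation Per-column probability of drawing the consensus
#'   letter (scalar or length `msa_length`; default 0 = pure background).
#' @param reference_sequence Optional sequence forced into row 1 (id
#'   `"ref"`) and used as the column consensus.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(kind = c("chain", "dumbbell_dimer", "ring"),
                         n_residues = 10L, spacing = 3.8,
                         interface_edges = 1L, gap = 6.0,
                         n_seqs = 200L, msa_length = NULL,
                         planted_pairs = NULL, coupling_prob = 0.95,
                         conservation = 0, reference_sequence = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (n_residues < 2L) abort("n_residues must be >= 2")
  structure(
    list(kind = kind, n_residues = as.integer(n_residues), spacing = spacing,
         interface_edges = as.integer(interface_edges), gap = gap,
         n_seqs = as.integer(n_seqs), msa_length = msa_length,
         planted_pairs = planted_pairs, coupling_prob = coupling_prob,
         conservation = conservation, reference_sequence = reference_sequence,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

fixture_letters <- function(n) {
  rep_len(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n)
}

#' Generate a toy structure from a fixture spec
#'
#' `"chain"` places beads along x at the given spacing; `"ring"` closes
#' the chain into a circle; `"dumbbell_dimer"` builds two compact cubic
#' clusters (chains A and B) separated by `gap`, with `interface_edges`
#' bead pairs pulled to 4.0 Angstrom to form a narrow interface. Heavy
#' atoms coincide with the alpha-carbons, so `"ca"` and `"heavy_min"`
#' contact modes agree on fixtures.
#'
#' @param spec A [fixture_spec()].
#' @return A [new_structure()] object.
#' @export
make_structure <- function(spec) {
  n <- spec$n_residues
  s <- spec$spacing
  if (spec$kind == "chain") {
    ca <- cbind((seq_len(n) - 1) * s, 0, 0)
    chains <- rep("A", n)
    resno <- seq_len(n)
  } else if (spec$kind == "ring") {
    r <- s / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    ca <- cbind(r * cos(th), r * sin(th), 0)
    chains <- rep("A", n)
    resno <- seq_len(n)
  } else {
    unit <- dimer_unit_grid(n, s)
    face_a <- unit$grid[unit$grid[, 1] == max(unit$grid[, 1]), , drop = FALSE]
    face_b <- unit$grid[unit$grid[, 1] == 0, , drop = FALSE]
    shared <- merge(as.data.frame(face_a[, 2:3, drop = FALSE]),
                    as.data.frame(face_b[, 2:3, drop = FALSE]))
    shared <- shared[order(shared[, 1], shared[, 2]), , drop = FALSE]
    if (nrow(shared) < spec$interface_edges) {
      abort("not enough facing bead pairs for the requested interface_edges")
    }
    offset <- max(unit$grid[, 1]) * s + spec$gap
    ca_a <- unit$coords
    # B's ix = 0 face looks at A's max-ix face across the gap
    ca_b <- sweep(unit$coords, 2, c(offset, 0, 0), "+")
    pull <- (spec$gap - 4.0) / 2
    for (e in seq_len(spec$interface_edges)) {
      iy <- shared[e, 1]; iz <- shared[e, 2]
      ia <- which(unit$grid[, 1] == max(unit$grid[, 1]) &
                    unit$grid[, 2] == iy & unit$grid[, 3] == iz)
      ib <- which(unit$grid[, 1] == 0 & unit$grid[, 2] == iy & unit$grid[, 3] == iz)
      ca_a[ia, 1] <- ca_a[ia, 1] + pull
      ca_b[ib, 1] <- ca_b[ib, 1] - pull
    }
    ca <- rbind(ca_a, ca_b)
    chains <- rep(c("A", "B"), each = n)
    resno <- c(seq_len(n), seq_len(n))
  }
  aa1 <- fixture_letters(nrow(ca))
  residues <- tibble(
    chain = chains, resno = as.integer(resno), ins = "",
    resname = bio3d::aa123(aa1), aa1 = aa1
  )
  new_structure(residues, ca,
                source_id = sprintf("fixture_%s_n%d_seed%d", spec$kind,
                                    spec$n_residues, spec$seed))
}

# Cubic lattice positions for one dimer unit: integer grid + coordinates.
dimer_unit_grid <- function(n, spacing) {
  k <- ceiling(n^(1 / 3))
  grid <- expand.grid(iz = 0:(k - 1), iy = 0:(k - 1), ix = 0:(k - 1))
  grid <- as.matrix(grid[, c("ix", "iy", "iz")])[seq_len(n), , drop = FALSE]
  list(grid = grid, coords = grid * spacing)
}

#' Generate a synthetic alignment with planted covariation
#'
#' Background columns are drawn independently from the database
#' composition, optionally biased toward a consensus letter with
#' per-column probability `conservation`. Each planted pair follows a
#' two-state coupled model: a shared latent state per sequence selects
#' letters (A/C in the first column, G/V in the second); with probability
#' `1 - coupling_prob` each column redraws its state independently. At
#' `coupling_prob = 1` the generating joint is {AG: 1/2, CV: 1/2}, whose
#' mutual information is exactly log 2.
#'
#' @param spec A [fixture_spec()].
#' @return A [new_alignment()] object.
#' @export
make_msa <- function(spec) {
  l <- spec$msa_length %||% spec$n_residues
  n <- spec$n_seqs
  if (n < 2L) abort("n_seqs must be >= 2")
  planted <- spec$planted_pairs
  if (!is.null(planted)) {
    planted <- if (is.list(planted)) do.call(rbind, planted) else as.matrix(planted)
    if (any(planted < 1) || any(planted > l)) abort("planted pairs outside alignment length")
    if (anyDuplicated(as.vector(planted))) abort("planted pairs overlap")
  }
  cons <- rep_len(spec$conservation, l)
  consensus <- if (!is.null(spec$reference_sequence)) {
    strsplit(spec$reference_sequence, "")[[1]]
  } else {
    NULL
  }
  bg <- aa_background_frequencies
  mat <- with_seed(spec$seed, {
    consensus <- consensus %||% sample(AA20, l, replace = TRUE, prob = bg)
    m <- matrix("", n, l)
    for (j in seq_len(l)) {
      from_cons <- stats::runif(n) < cons[j]
      m[, j] <- ifelse(from_cons, consensus[j],
                       sample(AA20, n, replace = TRUE, prob = bg))
    }
    if (!is.null(planted)) {
      x_states <- c("A", "C")
      y_states <- c("G", "V")
      for (p in seq_len(nrow(planted))) {
        state <- sample(1:2, n, replace = TRUE)
        recouple <- stats::runif(n) >= spec$coupling_prob
        state_y <- state
        state_y[recouple] <- sample(1:2, sum(recouple), replace = TRUE)
        m[, planted[p, 1]] <- x_states[state]
        m[, planted[p, 2]] <- y_states[state_y]
      }
    }
    m
  })
  ids <- sprintf("seq%04d", seq_len(n))
  if (!is.null(spec$reference_sequence)) {
    mat[1, ] <- strsplit(spec$reference_sequence, "")[[1]]
    ids[1] <- "ref"
  }
  new_alignment(ids, mat, reference_row = if (!is.null(spec$reference_sequence)) "ref")
}

#' Frozen end-to-end reference case
#'
#' One fixed bundle — dumbbell-dimer structure, planted-covariation
#' alignment whose reference row is the structure's sequence, and a
#' GNM-sampled conformer ensemble — used for golden-file regression of the
#' whole pipeline.
#'
#' @param seed Pinned seed (default 42).
#' @param n_frames Ensemble size (default 60).
#' @return List with `spec`, `structure`, `msa`, `modes`, `ensemble`.
#' @export
make_reference_case <- function(seed = 42L, n_frames = 60L) {
  spec <- fixture_spec(
    kind = "dumbbell_dimer", n_residues = 12L, interface_edges = 1L,
    n_seqs = 250L, msa_length = 24L,
    planted_pairs = rbind(c(3L, 15L), c(7L, 20L)),
    coupling_prob = 0.95, conservation = 0.3, seed = seed
  )
  structure <- make_structure(spec)
  spec$reference_sequence <- structure_sequence(structure)
  msa <- make_msa(spec)
  km <- build_kirchhoff(structure, rc = 7.0)
  modes <- gnm_modes(km)
  ensemble <- sample_conformers_gnm(structure, modes, n_frames = n_frames,
                                    amplitude = 0.5, seed = seed + 1L)
  list(spec = spec, structure = structure, msa = msa, modes = modes,
       ensemble = ensemble)
}
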