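#' Protein structures as residue-level records
#'
#' A `coev_structure` holds one conformation of a protein at residue
#' resolution: an ordered residue roster, one alpha-carbon coordinate per
#' residue and the heavy (non-hydrogen) atom coordinates of each residue.
#' All downstream models (elastic network, proximity MI, residue network)
#' operate on this container.
#'
#' @param residues Tibble with columns `chain`, `resno`, `ins`, `resname`,
#'   `aa1` (one-letter code); one row per residue, unique on
#'   `(chain, resno, ins)`.
#' @param ca Numeric N x 3 matrix of alpha-carbon coordinates (Angstrom).
#' @param heavy List of numeric matrices, one per residue, each holding that
#'   residue's heavy-atom coordinates (Angstrom). Defaults to the
#'   alpha-carbon coordinates when no heavy atoms are supplied.
#' @param source_id Text label recording where the structure came from.
#'
#' @return An object of class `coev_structure`.
#' @export
new_structure <- function(residues, ca, heavy = NULL, source_id = "structure") {
  residues <- as_tibble(residues)
  ca <- as.matrix(ca)
  storage.mode(ca) <- "double"
  n <- nrow(residues)
  if (nrow(ca) != n || ncol(ca) != 3L) {
    abort("`ca` must be an N x 3 matrix matching `residues`")
  }
  if (!all(is.finite(ca))) abort("alpha-carbon coordinates must be finite")
  key <- paste(residues$chain, residues$resno, residues$ins, sep = "\r")
  if (anyDuplicated(key)) abort("(chain, resno, ins) residue keys must be unique")
  if (is.null(heavy)) {
    heavy <- lapply(seq_len(n), function(i) ca[i, , drop = FALSE])
  }
  if (length(heavy) != n) abort("`heavy` must have one entry per residue")
  heavy <- lapply(heavy, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3L || !all(is.finite(m))) {
      abort("heavy-atom coordinates must be finite N x 3 matrices")
    }
    m
  })
  structure(
    list(residues = residues, ca = ca, heavy = heavy, source_id = source_id),
    class = "coev_structure"
  )
}

#' @export
print.coev_structure <- function(x, ...) {
  cat(sprintf(
    "<coev_structure> %s: %d residues, %d chains, %d heavy atoms\n",
    x$source_id, nrow(x$residues), length(unique(x$residues$chain)),
    sum(vapply(x$heavy, nrow, integer(1)))
  ))
  invisible(x)
}

#' @export
length.coev_structure <- function(x) nrow(x$residues)

#' One-letter amino-acid sequence of a structure
#'
#' @param structure A [new_structure()] object.
#' @return Character scalar.
#' @export
structure_sequence <- function(structure) {
  paste(structure$residues$aa1, collapse = "")
}

#' Per-residue roster of a structure as a tibble
#'
#' @param x A `coev_structure`.
#' @param ... Unused.
#' @return Tibble with residue identifiers, labels and CA coordinates.
#' @export
tidy.coev_structure <- function(x, ...) {
  dplyr::mutate(
    x$residues,
    label = residue_labels(x$residues),
    x = x$ca[, 1], y = x$ca[, 2], z = x$ca[, 3]
  )
}

is_cif_path <- function(path) grepl("\\.(cif|mmcif)$", tolower(path))

parse_coords_file <- function(path) {
  # rm.alt = FALSE: alternate locations are resolved here by occupancy,
  # not by bio3d's take-altloc-A default
  if (is_cif_path(path)) {
    bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
  } else {
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE,
                                     rm.alt = FALSE))
  }
}

n_models <- function(pdb) {
  xyz <- pdb$xyz
  if (is.matrix(xyz)) nrow(xyz) else 1L
}

# Build a coev_structure from a parsed bio3d object for one model.
build_structure <- function(pdb, model = 1L, chains = NULL, keep_hetero = FALSE,
                            source_id = "structure") {
  nm <- n_models(pdb)
  if (model < 1L || model > nm) {
    abort(sprintf("model %d requested but file has %d model(s)", model, nm))
  }
  atom <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  coords <- matrix(xyz, ncol = 3L, byrow = TRUE)
  atom$x <- coords[, 1]
  atom$y <- coords[, 2]
  atom$z <- coords[, 3]

  if (!keep_hetero) atom <- atom[atom$type == "ATOM", , drop = FALSE]
  atom <- atom[!(atom$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!is.null(chains)) atom <- atom[atom$chain %in% chains, , drop = FALSE]

  # drop hydrogens/deuterium by element symbol, falling back to atom-name
  # conventions (leading digits then H) when the element column is absent
  elesy <- atom$elesy
  is_h <- !is.na(elesy) & elesy %in% c("H", "D")
  no_sym <- is.na(elesy) | elesy == ""
  is_h[no_sym] <- grepl("^[0-9]*[HD]", atom$elety[no_sym])
  atom <- atom[!is_h, , drop = FALSE]
  if (nrow(atom) == 0L) abort("no residues selected")

  # alternate locations: highest occupancy wins, ties broken by file order
  alt <- atom$alt
  has_alt <- !is.na(alt) & !(alt %in% c("", " "))
  if (any(has_alt)) {
    occ <- atom$o
    occ[is.na(occ)] <- 1
    akey <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
    ord <- order(akey, -occ, seq_len(nrow(atom)))
    keep <- !duplicated(akey[ord])
    atom <- atom[sort(ord[keep]), , drop = FALSE]
  }

  ins <- atom$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(atom$chain, atom$resno, ins, sep = "\r")
  ord <- order(atom$chain, atom$resno, ins)
  atom <- atom[ord, , drop = FALSE]
  rkey <- rkey[ord]
  idx <- split(seq_len(nrow(atom)), factor(rkey, levels = unique(rkey)))

  rows <- lapply(idx, function(ii) {
    sub <- atom[ii, , drop = FALSE]
    ca_row <- which(sub$elety == "CA")
    if (length(ca_row) == 0L) return(NULL)
    list(
      chain = sub$chain[1], resno = sub$resno[1],
      ins = if (is.na(sub$insert[1])) "" else sub$insert[1],
      resname = sub$resid[1],
      aa1 = bio3d::aa321(sub$resid[1]),
      ca = c(sub$x[ca_row[1]], sub$y[ca_row[1]], sub$z[ca_row[1]]),
      heavy = cbind(sub$x, sub$y, sub$z)
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warn(sprintf("%d residue(s) without an alpha-carbon atom were dropped", dropped))
  }
  rows <- unname(rows[!vapply(rows, is.null, logical(1))])
  if (length(rows) == 0L) abort("no residues selected")

  residues <- tibble(
    chain = vapply(rows, `[[`, character(1), "chain"),
    resno = vapply(rows, `[[`, integer(1), "resno"),
    ins = vapply(rows, `[[`, character(1), "ins"),
    resname = vapply(rows, `[[`, character(1), "resname"),
    aa1 = vapply(rows, `[[`, character(1), "aa1")
  )
  ca <- do.call(rbind, lapply(rows, `[[`, "ca"))
  heavy <- lapply(rows, `[[`, "heavy")
  new_structure(residues, ca, heavy, source_id = source_id)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Hydrogens, waters and (by default) heteroatoms are excluded; alternate
#' locations are resolved to the highest-occupancy copy (file order breaks
#' ties); residues lacking an alpha-carbon are dropped with a warning.
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param model Model index for multi-model files (default 1).
#' @param chains Optional character vector of chain identifiers to keep.
#' @param keep_hetero Keep non-water HETATM records in the heavy-atom lists.
#' @return A [new_structure()] object, residues ordered by
#'   `(chain, resno, ins)`.
#' @export
read_structure <- function(path, model = 1L, chains = NULL, keep_hetero = FALSE) {
  pdb <- parse_coords_file(path)
  build_structure(pdb, model = model, chains = chains, keep_hetero = keep_hetero,
                  source_id = sprintf("%s#%d", basename(path), model))
}

#' Conformer ensembles of alpha-carbon coordinates
#'
#' A `conformer_ensemble` stores F aligned frames of alpha-carbon
#' coordinates sharing one residue roster: the time-resolved (or
#' crystal-ensemble) counterpart of a single [new_structure()].
#'
#' @param reference A `coev_structure` providing the roster (N residues).
#' @param frames Numeric F x N x 3 array of coordinates, or an F x 3N
#'   matrix (x1 y1 z1 x2 ...) which is reshaped.
#' @param frame_labels Optional character labels, one per frame.
#' @param rmsd Optional per-frame RMSD to the reference (recorded by
#'   [superpose_ensemble()]).
#' @return An object of class `conformer_ensemble`.
#' @export
new_ensemble <- function(reference, frames, frame_labels = NULL, rmsd = NULL) {
  stopifnot(inherits(reference, "coev_structure"))
  n <- nrow(reference$residues)
  if (is.matrix(frames)) {
    if (ncol(frames) != 3L * n) abort("frame matrix must have 3N columns")
    frames <- aperm(array(t(frames), dim = c(3L, n, nrow(frames))), c(3, 2, 1))
  }
  if (length(dim(frames)) != 3L || dim(frames)[2] != n || dim(frames)[3] != 3L) {
    abort("`frames` must be an F x N x 3 array matching the reference roster")
  }
  if (dim(frames)[1] < 1L) abort("ensemble needs at least one frame")
  if (!all(is.finite(frames))) abort("frame coordinates must be finite")
  f <- dim(frames)[1]
  frame_labels <- frame_labels %||% sprintf("frame%d", seq_len(f))
  structure(
    list(reference = reference, frames = frames, frame_labels = frame_labels,
         rmsd = rmsd),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %d frames x %d residues (%s)\n",
    dim(x$frames)[1], dim(x$frames)[2], x$reference$source_id
  ))
  invisible(x)
}

n_frames <- function(ensemble) dim(ensemble$frames)[1]

# F x 3N view of the frames (x1 y1 z1 x2 ...).
flatten_frames <- function(ensemble) {
  fr <- ensemble$frames
  f <- dim(fr)[1]
  out <- matrix(NA_real_, f, dim(fr)[2] * 3L)
  for (k in seq_len(f)) {
    out[k, ] <- as.numeric(t(fr[k, , , drop = TRUE]))
  }
  out
}

#' Read a multi-model PDB as a conformer ensemble
#'
#' Each MODEL becomes one frame; the roster is taken from the first model.
#'
#' @inheritParams read_structure
#' @return A [new_ensemble()].
#' @export
read_ensemble <- function(path, chains = NULL) {
  pdb <- parse_coords_file(path)
  nm <- n_models(pdb)
  ref <- build_structure(pdb, model = 1L, chains = chains,
                         source_id = basename(path))
  frames <- array(NA_real_, dim = c(nm, nrow(ref$residues), 3L))
  frames[1, , ] <- ref$ca
  if (nm > 1L) {
    for (m in 2:nm) {
      sm <- build_structure(pdb, model = m, chains = chains)
      if (nrow(sm$residues) != nrow(ref$residues)) {
        abort(sprintf("model %d has a different residue roster", m))
      }
      frames[m, , ] <- sm$ca
    }
  }
  new_ensemble(ref, frames, frame_labels = sprintf("model%d", seq_len(nm)))
}

#' Read/write plain-text coordinate frames
#'
#' The text format holds one `FRAME k` header line per frame followed by N
#' whitespace-separated `x y z` rows in roster order.
#'
#' @param path File path.
#' @param reference A `coev_structure` supplying the roster.
#' @return [read_frames()] returns a [new_ensemble()];
#'   [write_frames()] returns `path` invisibly.
#' @export
read_frames <- function(path, reference) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^\\s*FRAME\\b", lines)
  if (length(starts) == 0L) abort("no FRAME headers found")
  n <- nrow(reference$residues)
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- array(NA_real_, dim = c(length(starts), n, 3L))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):ends[k]]
    if (length(block) != n) {
      abort(sprintf("frame %d has %d rows, expected %d", k, length(block), n))
    }
    vals <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    frames[k, , ] <- vals
  }
  new_ensemble(reference, frames)
}

#' @rdname read_frames
#' @param ensemble A `conformer_ensemble` to write.
#' @export
write_frames <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("FRAME %d", k), con)
    m <- ensemble$frames[k, , , drop = TRUE]
    writeLines(apply(m, 1, function(r) sprintf("%.6f %.6f %.6f", r[1], r[2], r[3])), con)
  }
  invisible(path)
}

#' Write an ensemble as a multi-model alpha-carbon PDB
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  res <- ensemble$reference$residues
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", k), con)
    m <- ensemble$frames[k, , , drop = TRUE]
    writeLines(sprintf(
      "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(res)), res$resname, res$chain, res$resno,
      ifelse(res$ins == "", " ", res$ins), m[, 1], m[, 2], m[, 3], 1, 0
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Residue-residue contact pairs of a structure
#'
#' Either alpha-carbon distances (`mode = "ca"`, the elastic-network
#' convention) or the minimum distance over all heavy-atom pairs
#' (`mode = "heavy_min"`, the proximity-MI and network-eligibility
#' convention) defines a contact.
#'
#' @param structure A `coev_structure`.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param mode `"ca"` or `"heavy_min"`.
#' @return Tibble with columns `i`, `j` (`i < j`, 1-based residue indices)
#'   and `dist` (the defining distance, Angstrom).
#' @export
contact_pairs <- function(structure, cutoff, mode = c("ca", "heavy_min")) {
  mode <- match.arg(mode)
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  n <- nrow(structure$residues)
  if (n == 0L) abort("structure is empty")
  d <- residue_distance_matrix(structure, mode)
  keep <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  tibble(i = keep[, 1], j = keep[, 2], dist = d[keep]) |>
    dplyr::arrange(.data$i, .data$j)
}

# N x N distance matrix under either contact convention.
residue_distance_matrix <- function(structure, mode = c("ca", "heavy_min")) {
  mode <- match.arg(mode)
  if (mode == "ca") {
    d <- cross_dist(structure$ca, structure$ca)
  } else {
    n <- nrow(structure$residues)
    d <- matrix(0, n, n)
    # prune with CA distances: heavy-min distance >= d_CA - r_i - r_j where
    # r is the residue's max CA-to-atom extent
    ext <- vapply(seq_len(n), function(i) {
      max(cross_dist(structure$heavy[[i]], structure$ca[i, , drop = FALSE]))
    }, numeric(1))
    dca <- cross_dist(structure$ca, structure$ca)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lower <- dca[i, j] - ext[i] - ext[j]
        dij <- if (lower > 50) lower else min(cross_dist(structure$heavy[[i]], structure$heavy[[j]]))
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  diag(d) <- 0
  d
}

# Kabsch superposition: rotation + translation of P (N x 3) onto Q (N x 3).
kabsch <- function(p, q) {
  pc <- colMeans(p)
  qc <- colMeans(q)
  pp <- sweep(p, 2, pc)
  qq <- sweep(q, 2, qc)
  h <- crossprod(pp, qq)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, p_center = pc, q_center = qc)
}

apply_kabsch <- function(p, fit) {
  sweep(sweep(p, 2, fit$p_center) %*% t(fit$rotation), 2, fit$q_center, "+")
}

#' Rigid-body superposition of conformers onto a reference
#'
#' Frames are superposed by least-squares (Kabsch) alpha-carbon fitting on
#' the residues common to all inputs; rosters are intersected on
#' `(chain, resno, ins)` keys and dropped residues are reported.
#'
#' @param frames A `conformer_ensemble` or a list of `coev_structure`s.
#' @param reference Reference `coev_structure`; defaults to the ensemble's
#'   own reference (or the first structure of the list).
#' @return A [new_ensemble()] on the common roster, with per-frame RMSD in
#'   `$rmsd`.
#' @export
superpose_ensemble <- function(frames, reference = NULL) {
  if (inherits(frames, "conformer_ensemble")) {
    reference <- reference %||% frames$reference
    rosters <- list(frames$reference$residues)
    get_frame <- function(k) frames$frames[k, , , drop = TRUE]
    f <- n_frames(frames)
    frame_roster_keys <- residue_keys(frames$reference$residues)
    labels <- frames$frame_labels
  } else if (is.list(frames) && all(vapply(frames, inherits, logical(1), "coev_structure"))) {
    reference <- reference %||% frames[[1]]
    rosters <- lapply(frames, `[[`, "residues")
    get_frame <- function(k) frames[[k]]$ca
    f <- length(frames)
    frame_roster_keys <- NULL
    labels <- vapply(frames, `[[`, character(1), "source_id")
  } else {
    abort("`frames` must be a conformer_ensemble or a list of structures")
  }

  ref_keys <- residue_keys(reference$residues)
  common <- Reduce(intersect, c(list(ref_keys), lapply(rosters, residue_keys)))
  if (length(common) < nrow(reference$residues)) {
    inform(sprintf(
      "superpose_ensemble: %d residue(s) outside the common roster dropped",
      nrow(reference$residues) - length(common)
    ))
  }
  if (length(common) < 3L) abort("fewer than 3 common residues: superposition under-determined")

  ref_idx <- match(common, ref_keys)
  ref_sub <- subset_structure(reference, ref_idx)
  q <- ref_sub$ca

  out <- array(NA_real_, dim = c(f, length(common), 3L))
  rmsd <- numeric(f)
  for (k in seq_len(f)) {
    keys_k <- if (is.null(frame_roster_keys)) residue_keys(rosters[[k]]) else frame_roster_keys
    p <- get_frame(k)[match(common, keys_k), , drop = FALSE]
    fit <- kabsch(p, q)
    aligned <- apply_kabsch(p, fit)
    out[k, , ] <- aligned
    rmsd[k] <- sqrt(mean(rowSums((aligned - q)^2)))
  }
  new_ensemble(ref_sub, out, frame_labels = labels, rmsd = rmsd)
}

residue_keys <- function(residues) {
  paste(residues$chain, residues$resno, residues$ins, sep = "\r")
}

# Restrict a structure to a residue-index subset (order preserved).
subset_structure <- function(structure, idx) {
  new_structure(
    structure$residues[idx, , drop = FALSE],
    structure$ca[idx, , drop = FALSE],
    structure$heavy[idx],
    source_id = structure$source_id
  )
}

#' Principal component analysis of a conformer ensemble
#'
#' Decomposes coordinate covariance about the ensemble mean. In `"xyz"`
#' space components live in 3N Cartesian coordinates. In `"resdisp"`
#' space the analysis is N-dimensional: every Cartesian axis of the
#' centred displacement field contributes one N-vector sample (the signed
#' per-residue scalar displacement along that axis), and the 3F stacked
#' samples are decomposed together. Under the isotropic assumption the
#' axes are exchangeable, so this estimates the N x N residue covariance
#' directly — the space GNM mode vectors live in, which is what
#' [cumulative_overlap()] needs.
#'
#' @param ensemble A superposed [new_ensemble()] with at least 2 frames.
#' @param space `"xyz"` (default) or `"resdisp"`.
#' @return An object of class `pc_model` with `components` (dim x K,
#'   orthonormal columns), `variances` (descending), `mean_coords` (N x 3)
#'   and `space`.
#' @export
ensemble_pca <- function(ensemble, space = c("xyz", "resdisp")) {
  space <- match.arg(space)
  f <- n_frames(ensemble)
  if (f < 2L) abort("ensemble has no variability")
  x <- flatten_frames(ensemble)
  mean_flat <- colMeans(x)
  n <- dim(ensemble$frames)[2]
  mean_coords <- matrix(mean_flat, ncol = 3L, byrow = TRUE)
  if (space == "resdisp") {
    centered <- sweep(x, 2, mean_flat)
    x <- do.call(rbind, lapply(1:3, function(a) {
      centered[, seq(a, 3L * n, by = 3L), drop = FALSE]
    }))
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  }
  variances <- pc$sdev^2
  structure(
    list(components = pc$rotation, variances = variances,
         mean_coords = mean_coords, space = space, n_frames = f),
    class = "pc_model"
  )
}

#' @export
print.pc_model <- function(x, ...) {
  cat(sprintf(
    "<pc_model> %s space, %d components, top variance %.4g\n",
    x$space, ncol(x$components), x$variances[1]
  ))
  invisible(x)
}

#' @export
tidy.pc_model <- function(x, ...) {
  tibble(
    component = seq_along(x$variances),
    variance = x$variances,
    prop_variance = x$variances / sum(x$variances)
  )
}
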