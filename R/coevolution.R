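#' Background amino-acid frequencies
#'
#' Database-wide amino-acid composition (fractions summing to 1, standard
#' 20-letter alphabet in alphabetical one-letter order) used as the default
#' null distribution Q(i) of the Kullback-Leibler conservation score.
#'
#' @format Named numeric vector of length 20.
#' @export
aa_background_frequencies <- local({
  q <- c(
    A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
    I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
    R = 5.53, S = 6.65, T = 5.36, V = 6.85, W = 1.10, Y = 2.92
  )
  q / sum(q)
})

AA20 <- names(aa_background_frequencies)

#' Multiple sequence alignments
#'
#' A `coev_msa` is a rectangular alignment over the 20 amino acids plus the
#' gap symbol `-`. Lower case is upper-cased, `.` is unified with `-`, and
#' any other symbol (ambiguity codes, `*`) is mapped to gap with a warning.
#'
#' @param ids Character vector of sequence identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths) or an
#'   n x L character matrix.
#' @param reference_row Optional identifier of the row used for
#'   column-to-structure mapping.
#' @return An object of class `coev_msa` with an n x L character matrix in
#'   `$mat`.
#' @export
new_alignment <- function(ids, seqs, reference_row = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- ids[which(lens != lens[1])[1]]
      abort(sprintf("alignment rows have unequal lengths (first offender: %s)", bad))
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
  }
  if (length(ids) != nrow(mat)) abort("`ids` must match the number of sequences")
  if (length(ids) < 2L) abort("alignment needs at least 2 sequences")
  mat <- toupper(mat)
  mat[mat == "."] <- "-"
  bad <- !(mat %in% c(AA20, "-"))
  if (any(bad)) {
    warn(sprintf("%d non-standard symbol(s) mapped to gap", sum(bad)))
    mat[bad] <- "-"
  }
  dimnames(mat) <- NULL
  if (!is.null(reference_row) && !(reference_row %in% ids)) {
    abort("`reference_row` is not a sequence identifier in the alignment")
  }
  structure(
    list(ids = ids, mat = mat, column_count = ncol(mat),
         reference_row = reference_row),
    class = "coev_msa"
  )
}

#' @export
print.coev_msa <- function(x, ...) {
  cat(sprintf("<coev_msa> %d sequences x %d columns\n", nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path FASTA or Stockholm file.
#' @param format `"auto"` (sniff the first line), `"fasta"` or
#'   `"stockholm"`.
#' @param reference_row Optional identifier of the reference row.
#' @return A [new_alignment()] object.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm"),
                           reference_row = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- as.character(ss)
  } else {
    parsed <- parse_stockholm(path)
    ids <- parsed$ids
    seqs <- parsed$seqs
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[which(lens != lens[1])[1]]
    abort(sprintf("alignment rows have unequal lengths (first offender: %s)", bad))
  }
  new_alignment(ids, unname(seqs), reference_row = reference_row)
}

# Minimal Stockholm 1.0 reader: sequence lines only, wrapped blocks
# concatenated per identifier; markup (#=) and comments skipped.
parse_stockholm <- function(path) {
  lines <- readLines(path)
  acc <- list()
  order_ids <- character(0)
  for (ln in lines) {
    if (grepl("^\\s*$", ln) || grepl("^#", ln) || grepl("^//", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L) next
    id <- parts[1]
    if (!(id %in% order_ids)) order_ids <- c(order_ids, id)
    acc[[id]] <- paste0(acc[[id]] %||% "", parts[2])
  }
  if (length(order_ids) == 0L) abort("no sequences found in Stockholm file")
  list(ids = order_ids, seqs = unlist(acc[order_ids]))
}

#' Kullback-Leibler conservation per alignment column
#'
#' For each column the observed amino-acid frequencies P(i) (gaps excluded)
#' are compared with background frequencies Q(i):
#' `KL = sum_i P(i) log(P(i)/Q(i))` in nats. Fully conserved columns score
#' `log(1/Q(aa))`; columns matching the background score 0. Columns whose
#' gap fraction exceeds `gap_flag_fraction` are flagged; all-gap columns
#' get `NA`.
#'
#' @param msa A [new_alignment()] object.
#' @param background Positive 20-vector summing to 1 (default
#'   [aa_background_frequencies]).
#' @param gap_flag_fraction Flag columns with more gaps than this fraction
#'   (default 0.5).
#' @param weights Optional per-sequence weights (default unweighted).
#' @return Tibble with `column`, `kl`, `gap_fraction`, `flagged`.
#' @export
kl_conservation <- function(msa, background = aa_background_frequencies,
                            gap_flag_fraction = 0.5, weights = NULL) {
  if (any(background <= 0)) abort("background frequencies must be strictly positive")
  if (abs(sum(background) - 1) > 1e-6) abort("background frequencies must sum to 1")
  background <- setNames(as.numeric(background), names(background) %||% AA20)[AA20]
  n <- nrow(msa$mat)
  weights <- weights %||% rep(1, n)
  kl <- gap_frac <- numeric(msa$column_count)
  for (j in seq_len(msa$column_count)) {
    col <- msa$mat[, j]
    keep <- col != "-"
    gap_frac[j] <- 1 - sum(weights[keep]) / sum(weights)
    if (!any(keep)) {
      kl[j] <- NA_real_
      next
    }
    w <- weights[keep]
    p <- vapply(AA20, function(a) sum(w[col[keep] == a]), numeric(1)) / sum(w)
    nz <- p > 0
    kl[j] <- sum(p[nz] * log(p[nz] / background[nz]))
  }
  tibble(
    column = seq_len(msa$column_count),
    kl = kl,
    gap_fraction = gap_frac,
    flagged = gap_frac > gap_flag_fraction
  )
}

# Henikoff position-based sequence weights (gap treated as a 21st symbol),
# normalised to mean 1.
henikoff_weights <- function(mat) {
  n <- nrow(mat)
  w <- numeric(n)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- table(col)
    r <- length(counts)
    w <- w + 1 / (r * as.numeric(counts[col]))
  }
  w / mean(w)
}

# Identity-cluster weights: 1 / (number of sequences at >= threshold
# identity, counting self), normalised to mean 1.
cluster_weights <- function(mat, threshold = 0.62) {
  n <- nrow(mat)
  sim <- matrix(0, n, n)
  for (j in seq_len(ncol(mat))) {
    sim <- sim + outer(mat[, j], mat[, j], "==")
  }
  sim <- sim / ncol(mat)
  w <- 1 / rowSums(sim >= threshold)
  w / mean(w)
}

# Weighted MI (nats) between two encoded columns; rows gapped in either
# column are excluded; pseudocount added per joint cell over the observed
# 20x20 alphabet.
pair_mi <- function(a, b, w, pseudocount = 0) {
  keep <- a > 0L & b > 0L
  if (sum(keep) < 2L) return(NA_real_)
  a <- a[keep]
  b <- b[keep]
  w <- w[keep]
  joint <- matrix(pseudocount, 20L, 20L)
  agg <- rowsum(w, group = a + 20L * (b - 1L))
  joint[as.integer(rownames(agg))] <- joint[as.integer(rownames(agg))] + agg[, 1]
  joint <- joint / sum(joint)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' Mutual-information coevolution matrix of an alignment
#'
#' Computes raw pairwise column MI (nats) from weighted, optionally
#' pseudocounted amino-acid frequencies, an optional average-product
#' correction (APC), and optional z-scores against a column-shuffle null:
#' for each pair, one column is permuted across sequences
#' `null_shuffles` times (marginals preserved, covariation destroyed) and
#' `z = (MI - mu_null) / sd_null`.
#'
#' @param msa A [new_alignment()] object.
#' @param sequence_weighting `"henikoff"` (position-based, default),
#'   `"cluster"` (identity clusters at `cluster_threshold`), or `"none"`.
#' @param cluster_threshold Identity threshold for cluster weighting
#'   (default 0.62).
#' @param pseudocount Pseudocount added to each joint frequency cell
#'   (default 0).
#' @param apc Apply average-product correction to the raw matrix
#'   (default `FALSE`).
#' @param null_shuffles Number of shuffles for the z-score null; 0 skips
#'   z-scoring, values in 1..19 are rejected as too small to estimate a
#'   standard deviation.
#' @param seed RNG seed for the shuffle null.
#' @return An object of class `mi_matrix` with `raw`, `z` (or `NULL`),
#'   `null_mean`/`null_sd`, `weights`, `apc_applied`.
#' @export
mutual_information <- function(msa,
                               sequence_weighting = c("henikoff", "cluster", "none"),
                               cluster_threshold = 0.62,
                               pseudocount = 0,
                               apc = FALSE,
                               null_shuffles = 0,
                               seed = 1L) {
  sequence_weighting <- match.arg(sequence_weighting)
  if (null_shuffles > 0 && null_shuffles < 20) {
    abort("null_shuffles must be 0 (no z-scores) or >= 20 (null too small to estimate sd)")
  }
  mat <- msa$mat
  l <- ncol(mat)
  w <- switch(sequence_weighting,
    henikoff = henikoff_weights(mat),
    cluster = cluster_weights(mat, cluster_threshold),
    none = rep(1, nrow(mat))
  )
  enc <- matrix(match(mat, AA20, nomatch = 0L), nrow = nrow(mat))

  raw <- matrix(NA_real_, l, l)
  for (x in seq_len(l - 1)) {
    for (y in (x + 1):l) {
      raw[x, y] <- raw[y, x] <- pair_mi(enc[, x], enc[, y], w, pseudocount)
    }
  }

  if (apc) {
    raw <- apply_apc(raw)
  }

  z <- null_mean <- null_sd <- NULL
  if (null_shuffles > 0) {
    null_mean <- null_sd <- matrix(NA_real_, l, l)
    z <- matrix(NA_real_, l, l)
    with_seed(seed, {
      perms <- replicate(null_shuffles, sample.int(nrow(mat)))
      for (x in seq_len(l - 1)) {
        for (y in (x + 1):l) {
          nulls <- vapply(seq_len(null_shuffles), function(s) {
            pair_mi(enc[, x], enc[perms[, s], y], w, pseudocount)
          }, numeric(1))
          mu <- mean(nulls, na.rm = TRUE)
          sdv <- sd(nulls, na.rm = TRUE)
          null_mean[x, y] <- null_mean[y, x] <- mu
          null_sd[x, y] <- null_sd[y, x] <- sdv
          zv <- if (is.na(sdv) || sdv < 1e-12) 0 else (raw[x, y] - mu) / sdv
          z[x, y] <- z[y, x] <- zv
        }
      }
    })
  }

  structure(
    list(raw = raw, z = z, null_mean = null_mean, null_sd = null_sd,
         weights = w, apc_applied = apc, n_seq = nrow(mat)),
    class = "mi_matrix"
  )
}

# Average-product correction: MI_ij - mean_i * mean_j / mean_all.
apply_apc <- function(m) {
  mean_i <- rowMeans(m, na.rm = TRUE)
  mean_all <- mean(m[upper.tri(m)], na.rm = TRUE)
  if (!is.finite(mean_all) || mean_all == 0) return(m)
  corr <- outer(mean_i, mean_i) / mean_all
  out <- m - corr
  diag(out) <- NA_real_
  out
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf(
    "<mi_matrix> %d columns, %d sequences, APC %s, z-scores %s\n",
    nrow(x$raw), x$n_seq, if (x$apc_applied) "on" else "off",
    if (is.null(x$z)) "absent" else "present"
  ))
  invisible(x)
}

#' Pairwise MI scores as a long tibble
#'
#' @param x A [mutual_information()] result.
#' @param ... Unused.
#' @return Tibble with `col_i`, `col_j` (`i < j`), `mi` and (when
#'   available) `z`.
#' @export
tidy.mi_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$raw), arr.ind = TRUE)
  out <- tibble(col_i = ut[, 1], col_j = ut[, 2], mi = x$raw[ut])
  if (!is.null(x$z)) out$z <- x$z[ut]
  dplyr::arrange(out, .data$col_i, .data$col_j)
}

mi_score_table <- function(mi, score = c("z", "raw")) {
  score <- match.arg(score)
  tab <- if (score == "z") mi$z else mi$raw
  if (is.null(tab)) {
    abort(sprintf("requested '%s' scores are not populated in this mi_matrix", score))
  }
  tab
}

#' Cumulative mutual information per column
#'
#' `cMI_x = sum over y of score(x, y) for score(x, y) > t` (strict): the
#' total coevolutionary signal a column shares with the rest of the
#' alignment. The default threshold 6.5 applies to the z-score scale.
#'
#' @param mi A [mutual_information()] result (or a bare symmetric score
#'   matrix).
#' @param score `"z"` (default) or `"raw"`.
#' @param threshold_t Score threshold t (default 6.5).
#' @return Tibble with `column` and `cmi`.
#' @export
cumulative_mi <- function(mi, score = c("z", "raw"), threshold_t = 6.5) {
  tab <- if (is.matrix(mi)) mi else mi_score_table(mi, score)
  keep <- !is.na(tab) & tab > threshold_t
  cmi <- rowSums(tab * keep, na.rm = TRUE)
  tibble(column = seq_len(nrow(tab)), cmi = as.numeric(cmi))
}

#' Map alignment columns onto structure residues
#'
#' The ungapped reference row is locally aligned (Smith-Waterman,
#' BLOSUM62) against the structure's one-letter sequence; matched
#' positions give a bijective column-to-residue mapping, unmatched columns
#' are flagged unmapped.
#'
#' @param msa A [new_alignment()] object.
#' @param structure A [new_structure()] object.
#' @param reference_row Identifier of the alignment row corresponding to
#'   the structure (defaults to the alignment's `reference_row`, else its
#'   first row).
#' @param min_identity Minimum percent identity over the aligned span
#'   (default 90).
#' @return Tibble with `column`, `residue` (1-based structure index or
#'   `NA`) and `mapped`.
#' @export
map_columns <- function(msa, structure, reference_row = NULL, min_identity = 90) {
  reference_row <- reference_row %||% msa$reference_row %||% msa$ids[1]
  if (!(reference_row %in% msa$ids)) abort("reference row not found in alignment")
  row <- msa$mat[match(reference_row, msa$ids), ]
  ref_cols <- which(row != "-")
  ref_seq <- paste(row[ref_cols], collapse = "")
  struct_seq <- structure_sequence(structure)
  if (nchar(ref_seq) < 3L) abort("reference row has fewer than 3 residues")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seq), Biostrings::AAString(struct_seq),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4
  )
  identity <- Biostrings::pid(aln)
  if (!is.finite(identity)) identity <- 0
  if (identity < min_identity) {
    abort(sprintf(
      "reference row matches the structure at %.1f%% identity (< %.0f%%); choose a different reference_row",
      identity, min_identity
    ))
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  p_pos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  s_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  residue_of_refpos <- rep(NA_integer_, nchar(ref_seq))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") p_pos <- p_pos + 1L
    if (sa[k] != "-") s_pos <- s_pos + 1L
    if (pa[k] != "-" && sa[k] != "-") residue_of_refpos[p_pos] <- s_pos
  }
  residue <- rep(NA_integer_, msa$column_count)
  residue[ref_cols] <- residue_of_refpos
  tibble(
    column = seq_len(msa$column_count),
    residue = residue,
    mapped = !is.na(residue)
  )
}

#' Transfer per-column cMI scores to structure residues
#'
#' @param cmi_tbl Output of [cumulative_mi()].
#' @param column_map Output of [map_columns()].
#' @param n_residues Number of residues in the structure.
#' @return Numeric vector of length `n_residues`; unmapped residues `NA`.
#' @export
residue_cmi <- function(cmi_tbl, column_map, n_residues) {
  out <- rep(NA_real_, n_residues)
  mapped <- column_map[column_map$mapped, , drop = FALSE]
  out[mapped$residue] <- cmi_tbl$cmi[mapped$column]
  out
}

#' Proximity mutual information (pMI)
#'
#' The pMI of a residue is the mean cMI of all residues within a structural
#' proximity cutoff of it (default 5 Angstrom, minimum heavy-atom
#' distance; self included by default since d(x,x) = 0). With a conformer
#' ensemble the neighbourhood is recomputed per frame from alpha-carbon
#' distances and per-frame pMI values are averaged.
#'
#' @param cmi Per-residue cMI vector (see [residue_cmi()]); `NA` for
#'   unscored residues.
#' @param geometry A [new_structure()] (static mode) or a
#'   [new_ensemble()] (ensemble mode).
#' @param cutoff Proximity cutoff in Angstrom (default 5).
#' @param include_self Include the residue's own cMI in its neighbourhood
#'   (default `TRUE`).
#' @return An object of class `pmi_profile`: `$pmi` (per-residue,
#'   ensemble-averaged in ensemble mode), `$per_frame` (F x N matrix or
#'   `NULL`).
#' @export
proximity_mi <- function(cmi, geometry, cutoff = 5, include_self = TRUE) {
  assert_scalar_number(cutoff, "cutoff", positive = TRUE)
  if (inherits(geometry, "coev_structure")) {
    if (length(cmi) != nrow(geometry$residues)) {
      abort("`cmi` must have one entry per structure residue")
    }
    d <- residue_distance_matrix(geometry, "heavy_min")
    pmi <- pmi_from_distances(cmi, d, cutoff, include_self)
    per_frame <- NULL
  } else if (inherits(geometry, "conformer_ensemble")) {
    n <- dim(geometry$frames)[2]
    if (length(cmi) != n) abort("`cmi` must have one entry per ensemble residue")
    f <- n_frames(geometry)
    per_frame <- matrix(NA_real_, f, n)
    for (k in seq_len(f)) {
      xyz <- geometry$frames[k, , , drop = TRUE]
      d <- cross_dist(xyz, xyz)
      per_frame[k, ] <- pmi_from_distances(cmi, d, cutoff, include_self)
    }
    pmi <- colMeans(per_frame)
  } else {
    abort("`geometry` must be a coev_structure or conformer_ensemble")
  }
  if (any(is.na(pmi) & !is.na(cmi))) {
    inform("some residues have empty neighbourhoods; pMI reported as NA")
  }
  structure(
    list(pmi = pmi, per_frame = per_frame, cutoff = cutoff,
         include_self = include_self),
    class = "pmi_profile"
  )
}

pmi_from_distances <- function(cmi, d, cutoff, include_self) {
  n <- length(cmi)
  vapply(seq_len(n), function(x) {
    nb <- which(d[x, ] <= cutoff)
    if (!include_self) nb <- setdiff(nb, x)
    pool <- cmi[nb]
    pool <- pool[!is.na(pool)]
    if (length(pool) == 0L) NA_real_ else mean(pool)
  }, numeric(1))
}

#' @export
tidy.pmi_profile <- function(x, ...) {
  tibble(residue = seq_along(x$pmi), pmi = x$pmi)
}

#' Structural sectors of coevolving residues
#'
#' Residues with cMI strictly above the given percentile of the scored
#' residues form candidate nodes; connected components of the contact
#' subgraph induced on them with at least `min_size` members are labelled
#' sectors, ordered by decreasing size.
#'
#' @param cmi Per-residue cMI vector (`NA` allowed).
#' @param contacts Contact pair tibble from [contact_pairs()] (columns
#'   `i`, `j`).
#' @param percentile Percentile threshold in (0, 100) (default 90).
#' @param min_size Minimum sector size (default 3).
#' @return Tibble with `residue` and `sector` (integer label, 1 = largest);
#'   empty (with a warning) when no residue exceeds the threshold.
#' @export
sector_clusters <- function(cmi, contacts, percentile = 90, min_size = 3L) {
  if (percentile <= 0 || percentile >= 100) abort("percentile must be in (0, 100)")
  scored <- which(!is.na(cmi))
  thr <- quantile(cmi[scored], percentile / 100, names = FALSE)
  nodes <- scored[cmi[scored] > thr]
  if (length(nodes) == 0L) {
    warn("no residues above the cMI percentile threshold; empty sector assignment")
    return(tibble(residue = integer(0), sector = integer(0)))
  }
  sub <- contacts[contacts$i %in% nodes & contacts$j %in% nodes, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$i), to = as.character(sub$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes))
  )
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep_comp <- which(sizes >= min_size)
  if (length(keep_comp) == 0L) {
    warn("no connected component reaches the minimum sector size")
    return(tibble(residue = integer(0), sector = integer(0)))
  }
  ord <- keep_comp[order(sizes[keep_comp], decreasing = TRUE)]
  out <- purrr::map_dfr(seq_along(ord), function(s) {
    members <- as.integer(names(comp$membership)[comp$membership == ord[s]])
    tibble(residue = sort(members), sector = s)
  })
  out
}
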