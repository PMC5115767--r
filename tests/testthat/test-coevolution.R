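toy_msa <- function(cols) {
  # cols: list of character vectors (columns), all the same length
  mat <- do.call(cbind, cols)
  new_alignment(sprintf("s%d", seq_len(nrow(mat))), mat)
}

test_that("alignment reading handles FASTA, ragged rows and Stockholm gaps", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD-E", ">b", "ACDFE", ">c", "GCD.E"), fa)
  msa <- read_alignment(fa)
  expect_equal(nrow(msa$mat), 3L)
  expect_equal(msa$column_count, 5L)
  expect_equal(msa$mat[1, 4], "-")
  expect_equal(msa$mat[3, 4], "-")  # '.' unified as gap

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "ACD", ">c", "ACDE"), ragged)
  expect_error(read_alignment(ragged), "b")

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0", "",
    "a ACD.E", "b ACDFE", "c GCD-E", "//"
  ), sto)
  msa2 <- read_alignment(sto)
  expect_equal(msa2$mat, msa$mat, ignore_attr = TRUE)

  lower <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acdxe", ">b", "ACDFE"), lower)
  expect_warning(msa3 <- read_alignment(lower), "non-standard")
  expect_equal(msa3$mat[1, ], c("A", "C", "D", "-", "E"))
})

test_that("KL conservation matches analytic and brute-force values", {
  # column holding each amino acid once vs uniform background: KL = 0
  uniform <- setNames(rep(1 / 20, 20), coevnet:::AA20)
  msa_u <- toy_msa(list(coevnet:::AA20))
  expect_equal(kl_conservation(msa_u, background = uniform)$kl, 0, tolerance = 1e-12)

  # fully conserved Ala column: KL = log(1 / q_A)
  msa_a <- toy_msa(list(rep("A", 8), rep("G", 8)))
  kl <- kl_conservation(msa_a)
  qa <- aa_background_frequencies[["A"]]
  expect_equal(kl$kl[1], log(1 / qa), tolerance = 1e-12)

  # 6-sequence toy column {A,A,A,G,G,V} against an independent direct sum
  col <- c("A", "A", "A", "G", "G", "V")
  msa6 <- toy_msa(list(col, rep("C", 6)))
  got <- kl_conservation(msa6, background = uniform)$kl[1]
  p <- table(col) / 6
  want <- sum(p * log(p / (1 / 20)))
  expect_equal(got, unname(want), tolerance = 1e-12)

  # all-gap column is missing, not zero; gappy columns are flagged
  msa_g <- toy_msa(list(rep("-", 4), c("A", "-", "-", "-"), rep("A", 4)))
  klg <- kl_conservation(msa_g)
  expect_true(is.na(klg$kl[1]))
  expect_true(klg$flagged[2])
  expect_false(klg$flagged[3])
})

test_that("raw MI reproduces entropy, independence and perfect covariation", {
  colx <- c("A", "A", "C", "C", "G", "G", "V", "V")
  # a column against an identical copy: MI(X, X) = H(X)
  msa <- toy_msa(list(colx, colx, rep("W", 8)))
  mi <- mutual_information(msa, sequence_weighting = "none")
  expect_equal(mi$raw[1, 2], oracle_entropy(colx), tolerance = 1e-12)
  expect_equal(mi$raw[1, 2], log(4), tolerance = 1e-12)

  # constant column vs anything: MI = 0
  expect_equal(mi$raw[1, 3], 0, tolerance = 1e-12)

  # perfect 2-state covariation (4 AB, 4 CD): MI = log 2 and its z-score
  # exceeds that of an independent pair in the same alignment
  set.seed(3)
  ca <- rep(c("A", "C"), each = 4)
  cb <- rep(c("G", "V"), each = 4)
  ind1 <- sample(c("I", "L"), 8, replace = TRUE)
  ind2 <- sample(c("S", "T"), 8, replace = TRUE)
  msa2 <- toy_msa(list(ca, cb, ind1, ind2))
  mi2 <- mutual_information(msa2, sequence_weighting = "none",
                            null_shuffles = 40, seed = 9)
  expect_equal(mi2$raw[1, 2], log(2), tolerance = 1e-12)
  expect_gt(mi2$z[1, 2], mi2$z[3, 4])

  # too-small null is rejected
  expect_error(mutual_information(msa2, null_shuffles = 5), "null too small")
})

test_that("raw MI is symmetric, non-negative and row-order invariant", {
  spec <- fixture_spec("chain", n_residues = 8, n_seqs = 40, msa_length = 8,
                       planted_pairs = rbind(c(1, 5)), seed = 21)
  msa <- make_msa(spec)
  mi <- mutual_information(msa)
  ut <- upper.tri(mi$raw)
  expect_true(all(mi$raw[ut] >= -1e-12))
  expect_equal(mi$raw, t(mi$raw))
  # reorder rows: MI unchanged
  perm <- sample(seq_len(nrow(msa$mat)))
  msa_p <- new_alignment(msa$ids[perm], msa$mat[perm, ])
  mi_p <- mutual_information(msa_p)
  expect_equal(mi$raw, mi_p$raw, tolerance = 1e-10)
  # against the direct-count oracle (unweighted)
  mi_u <- mutual_information(msa, sequence_weighting = "none")
  for (pair in list(c(1, 5), c(2, 3), c(4, 8))) {
    expect_equal(mi_u$raw[pair[1], pair[2]],
                 oracle_mi(msa$mat[, pair[1]], msa$mat[, pair[2]]),
                 tolerance = 1e-12)
  }
})

test_that("cumulative MI sums scores above a strict threshold", {
  s <- matrix(0, 5, 5)
  s[1, 2] <- s[2, 1] <- 7
  s[1, 3] <- s[3, 1] <- 6.5   # exactly t: excluded (strict >)
  s[2, 4] <- s[4, 2] <- 10
  s[3, 5] <- s[5, 3] <- 2
  diag(s) <- NA
  got <- cumulative_mi(s, threshold_t = 6.5)
  # brute-force double loop
  want <- vapply(1:5, function(x) {
    tot <- 0
    for (y in setdiff(1:5, x)) if (s[x, y] > 6.5) tot <- tot + s[x, y]
    tot
  }, numeric(1))
  expect_equal(got$cmi, want)
  expect_equal(got$cmi, c(7, 17, 0, 10, 0))

  # all scores at or below t: zero everywhere
  expect_true(all(cumulative_mi(s, threshold_t = 10)$cmi == 0))

  # monotone non-increasing in t
  spec <- fixture_spec("chain", n_residues = 6, n_seqs = 60, msa_length = 6,
                       planted_pairs = rbind(c(2, 5)), seed = 4)
  mi <- mutual_information(make_msa(spec), null_shuffles = 25, seed = 2)
  # monotonicity holds on the non-negative score range (adding negative
  # z-scores to the sum would break it by construction)
  ts <- c(0, 2, 4, 6.5, 10)
  cmis <- vapply(ts, function(t) sum(cumulative_mi(mi, threshold_t = t)$cmi),
                 numeric(1))
  expect_true(all(diff(cmis) <= 1e-10))
})

test_that("column-to-residue mapping tracks gaps and rejects strangers", {
  st <- make_structure(fixture_spec("chain", n_residues = 10))
  seq10 <- structure_sequence(st)

  # identity mapping
  msa_id <- new_alignment(c("ref", "other"),
                          c(seq10, paste(rep("A", 10), collapse = "")),
                          reference_row = "ref")
  map_id <- map_columns(msa_id, st)
  expect_equal(map_id$residue, 1:10)

  # one internal gap in the reference row shifts downstream columns
  gapped <- paste0(substr(seq10, 1, 4), "-", substr(seq10, 5, 10))
  msa_gap <- new_alignment(c("ref", "other"),
                           c(gapped, paste(rep("A", 11), collapse = "")),
                           reference_row = "ref")
  map_gap <- map_columns(msa_gap, st)
  expect_equal(map_gap$residue[1:4], 1:4)
  expect_true(is.na(map_gap$residue[5]))
  expect_equal(map_gap$residue[6:11], 5:10)

  # unrelated reference row
  msa_bad <- new_alignment(c("ref", "other"),
                           c("WWWWWWWWWW", seq10), reference_row = "ref")
  expect_error(map_columns(msa_bad, st), "identity")
})

test_that("proximity MI equals brute-force neighbourhood means", {
  # 6 residues on a line, 3 A apart: neighbourhoods at 5 A are +-1 residue
  ca <- cbind(3 * (0:5), 0, 0)
  st <- new_structure(
    tibble::tibble(chain = "A", resno = 1:6, ins = "", resname = "ALA", aa1 = "A"),
    ca
  )
  cmi <- c(10, 0, 6, 2, 8, 4)
  pm <- proximity_mi(cmi, st, cutoff = 5)
  want <- vapply(1:6, function(x) {
    nb <- which(abs(ca[, 1] - ca[x, 1]) <= 5)
    mean(cmi[nb])
  }, numeric(1))
  expect_equal(pm$pmi, want)

  # bounded by the neighbourhood pool
  expect_true(all(pm$pmi >= min(cmi) & pm$pmi <= max(cmi)))

  # isolated residue with include_self: its own cMI
  iso <- new_structure(
    tibble::tibble(chain = "A", resno = 1:2, ins = "", resname = "ALA", aa1 = "A"),
    rbind(c(0, 0, 0), c(100, 0, 0))
  )
  pmi_iso <- proximity_mi(c(3, 7), iso, cutoff = 5)
  expect_equal(pmi_iso$pmi, c(3, 7))

  # without self-inclusion an isolated residue has no neighbourhood
  expect_message(pmi_ns <- proximity_mi(c(3, 7), iso, cutoff = 5,
                                        include_self = FALSE),
                 "empty")
  expect_true(all(is.na(pmi_ns$pmi)))

  # an ensemble of identical frames reproduces the static result
  frames <- array(rep(ca, each = 4), c(4, 6, 3))
  pm_ens <- proximity_mi(cmi, new_ensemble(st, frames), cutoff = 5)
  expect_equal(pm_ens$pmi, pm$pmi)
  expect_equal(dim(pm_ens$per_frame), c(4L, 6L))
})

test_that("sector clustering finds separated high-cMI components", {
  # two spatially separate triples of high-cMI residues
  dimer <- make_structure(fixture_spec("dumbbell_dimer", n_residues = 9,
                                       interface_edges = 0, gap = 20))
  n <- 18
  cmi <- rep(0, n)
  high_a <- c(1, 2, 4)   # mutually adjacent in unit A's grid
  high_b <- c(10, 11, 13)
  cmi[c(high_a, high_b)] <- 100
  contacts <- contact_pairs(dimer, 4.5, "ca")
  sect <- sector_clusters(cmi, contacts, percentile = 60)
  expect_equal(sort(unique(sect$sector)), c(1L, 2L))
  expect_equal(nrow(sect), 6L)
  a_lab <- sect$sector[match(high_a, sect$residue)]
  expect_equal(length(unique(a_lab)), 1L)

  # degenerate scores: nothing strictly above the percentile
  expect_warning(empty <- sector_clusters(rep(1, n), contacts, percentile = 90),
                 "no residues")
  expect_equal(nrow(empty), 0L)

  # a lone high-cMI residue is excluded by the size filter
  cmi2 <- rep(0, n)
  cmi2[c(1, 2, 4)] <- 100
  cmi2[18] <- 100
  expect_silent(sect2 <- sector_clusters(cmi2, contacts, percentile = 60))
  expect_false(18 %in% sect2$residue)
  expect_equal(nrow(sect2), 3L)
})

test_that("planted covarying pairs surface in the top z-scores", {
  planted <- rbind(c(2, 9), c(5, 17), c(11, 22), c(14, 26))
  spec <- fixture_spec("chain", n_residues = 30, n_seqs = 250, msa_length = 30,
                       planted_pairs = planted, coupling_prob = 0.95, seed = 8)
  msa <- make_msa(spec)
  mi <- mutual_information(msa, null_shuffles = 25, seed = 3)
  ut <- which(upper.tri(mi$z), arr.ind = TRUE)
  ord <- order(mi$z[ut], decreasing = TRUE)
  top_k <- ut[ord[1:4], , drop = FALSE]
  hits <- sum(apply(planted, 1, function(p) {
    any(top_k[, 1] == p[1] & top_k[, 2] == p[2])
  }))
  expect_gte(hits, 0.8 * 4)
})
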