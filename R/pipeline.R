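#' Configuration of a full network analysis run
#'
#' Collects every tunable of the pipeline with the standard defaults:
#' GNM cutoff 7.0 A, five slowest modes, MI z-score threshold 6.5,
#' proximity-MI cutoff 5 A, persistent-contact eligibility (4.5 A in at
#' least half the frames), equal dynamics/coevolution blend, and 10 path
#' blocks.
#'
#' @param structure A [new_structure()] or a PDB/mmCIF path.
#' @param msa Optional [new_alignment()] or alignment path; without it
#'   the network is purely dynamic (`alpha` forced to 0).
#' @param ensemble Optional [new_ensemble()] or multi-model PDB path;
#'   without it `n_frames` conformers are sampled from the GNM.
#' @param rc GNM cutoff (A).
#' @param k_slowest Slow modes in the mobility profile.
#' @param mi_score,mi_threshold Score scale and threshold t of
#'   [cumulative_mi()].
#' @param null_shuffles Shuffles for MI z-scores.
#' @param pmi_cutoff Proximity-MI cutoff (A).
#' @param contact_cutoff,persistence Edge-eligibility parameters.
#' @param alpha Dynamics/coevolution blend in [0, 1].
#' @param w1,w2 CP weighting factors (used when no grids are given).
#' @param w1_grid,w2_grid Optional grids for [optimize_weights()].
#' @param blocks Path-ensemble block count B.
#' @param pairs Optional 2-column matrix of source/target residue indices
#'   for path ensembles.
#' @param n_frames GNM-sampled ensemble size when no ensemble is given.
#' @param amplitude GNM sampling amplitude (kBT/gamma).
#' @param corr_source `"ensemble"` (generalized correlation from frames)
#'   or `"gnm_analytic"`.
#' @param seed Seed for every stochastic stage.
#' @param output_dir Optional directory for file outputs; `NULL` keeps
#'   results in memory only.
#' @return A `run_config` list.
#' @export
run_config <- function(structure, msa = NULL, ensemble = NULL,
                       rc = 7.0, k_slowest = 5L,
                       mi_score = "z", mi_threshold = 6.5,
                       null_shuffles = 25L, pmi_cutoff = 5.0,
                       contact_cutoff = 4.5, persistence = 0.5,
                       alpha = 0.5, w1 = 1, w2 = 1,
                       w1_grid = NULL, w2_grid = NULL,
                       blocks = 10L, pairs = NULL,
                       n_frames = 60L, amplitude = 0.5,
                       corr_source = c("ensemble", "gnm_analytic"),
                       seed = 1L, output_dir = NULL) {
  structure(
    list(structure = structure, msa = msa, ensemble = ensemble, rc = rc,
         k_slowest = k_slowest, mi_score = mi_score,
         mi_threshold = mi_threshold, null_shuffles = null_shuffles,
         pmi_cutoff = pmi_cutoff, contact_cutoff = contact_cutoff,
         persistence = persistence, alpha = alpha, w1 = w1, w2 = w2,
         w1_grid = w1_grid, w2_grid = w2_grid, blocks = blocks,
         pairs = pairs, n_frames = n_frames, amplitude = amplitude,
         corr_source = match.arg(corr_source), seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

resolve_structure <- function(x) {
  if (inherits(x, "coev_structure")) x else read_structure(x)
}

resolve_msa <- function(x) {
  if (is.null(x) || inherits(x, "coev_msa")) x else read_alignment(x)
}

#' Run the full coevolution-dynamics network pipeline
#'
#' Stages in dependency order: structure, GNM modes and mobility profile,
#' conformer ensemble (read or GNM-sampled), coevolution scores mapped to
#' residues, generalized correlations, eligibility and weighted network,
#' centrality, ensemble statistics and communication propensity
#' (optionally grid-optimised), and shortest-path ensembles for the
#' requested residue pairs. Identical config and seed give identical
#' results.
#'
#' @param config A [run_config()].
#' @return A `coevnet_run` object; `$residue_table` is the per-residue
#'   tibble, `$network`, `$paths`, `$manifest` carry the rest. When
#'   `config$output_dir` is set, all tables are written there with a
#'   manifest of content hashes.
#' @export
run_pipeline <- function(config) {
  st <- resolve_structure(config$structure)
  n <- nrow(st$residues)

  km <- build_kirchhoff(st, rc = config$rc)
  modes <- gnm_modes(km)
  profile <- slow_mode_profile(modes, k_slowest = config$k_slowest)

  ens <- config$ensemble
  if (is.null(ens)) {
    ens <- sample_conformers_gnm(st, modes, n_frames = config$n_frames,
                                 amplitude = config$amplitude,
                                 seed = config$seed)
  } else if (!inherits(ens, "conformer_ensemble")) {
    ens <- superpose_ensemble(read_ensemble(ens), st)
  }

  msa <- resolve_msa(config$msa)
  alpha <- config$alpha
  kl_res <- rep(NA_real_, n)
  cmi_res <- rep(NA_real_, n)
  coev_res <- NULL
  pmi <- NULL
  if (is.null(msa)) {
    if (alpha > 0) {
      warn("no alignment supplied: coevolution stage skipped, alpha forced to 0")
      alpha <- 0
    }
  } else {
    mi <- mutual_information(msa, null_shuffles = config$null_shuffles,
                             seed = config$seed)
    cmi_tbl <- cumulative_mi(mi, score = config$mi_score,
                             threshold_t = config$mi_threshold)
    cmap <- map_columns(msa, st)
    cmi_res <- residue_cmi(cmi_tbl, cmap, n)
    kl_tbl <- kl_conservation(msa)
    mapped <- cmap[cmap$mapped, , drop = FALSE]
    kl_res[mapped$residue] <- kl_tbl$kl[mapped$column]
    ztab <- mi_score_table(mi, config$mi_score)
    coev_res <- matrix(NA_real_, n, n)
    coev_res[mapped$residue, mapped$residue] <- ztab[mapped$column, mapped$column]
    pmi <- proximity_mi(cmi_res, ens, cutoff = config$pmi_cutoff)
  }
  if (is.null(pmi)) {
    pmi <- list(pmi = rep(NA_real_, n), per_frame = NULL)
  }

  dyn <- if (config$corr_source == "gnm_analytic") {
    analytic_gnm_correlation(modes)
  } else {
    generalized_correlation(ens)
  }
  elig <- contact_eligibility(ens, cutoff = config$contact_cutoff,
                              persistence = config$persistence)
  labels <- residue_labels(st$residues)
  net <- build_network(elig, dyn, coevo_corr = coev_res, alpha = alpha,
                       labels = labels)
  centrality <- betweenness_centrality(net)

  stats <- ensemble_stats(ens, per_frame_pmi = pmi$per_frame)
  if (!is.null(config$w1_grid) && !is.null(config$w2_grid)) {
    opt <- optimize_weights(stats, net, config$w1_grid, config$w2_grid)
    w1 <- opt$w1
    w2 <- opt$w2
  } else {
    opt <- NULL
    w1 <- config$w1
    w2 <- config$w2
  }
  cp <- suppressWarnings(communication_propensity(stats, w1 = w1, w2 = w2))
  sp <- shortest_paths_fw(net)
  eff <- network_efficiency(net, sp)

  paths <- list()
  if (!is.null(config$pairs)) {
    pair_mat <- as.matrix(config$pairs)
    builder <- function(block_ens) {
      be <- contact_eligibility(block_ens, cutoff = config$contact_cutoff,
                                persistence = config$persistence)
      bd <- generalized_correlation(block_ens)
      build_network(be, bd, coevo_corr = coev_res, alpha = alpha,
                    labels = labels)
    }
    for (r in seq_len(nrow(pair_mat))) {
      key <- sprintf("%s->%s", labels[pair_mat[r, 1]], labels[pair_mat[r, 2]])
      paths[[key]] <- path_ensemble(ens, pair_mat[r, 1], pair_mat[r, 2],
                                    blocks = config$blocks, builder = builder)
    }
  }

  residue_table <- tibble(
    residue = seq_len(n),
    label = labels,
    chain = st$residues$chain,
    resno = st$residues$resno,
    resname = st$residues$resname,
    kl = kl_res,
    cmi = cmi_res,
    pmi = pmi$pmi,
    mobility = unname(profile$profile),
    hinge = profile$hinge,
    centrality = centrality$centrality,
    cp = cp$cp
  )

  run <- structure(
    list(config = config, structure = st, modes = modes, profile = profile,
         ensemble_summary = list(
           n_frames = n_frames(ens),
           mean_rmsd = if (!is.null(ens$rmsd)) mean(ens$rmsd) else NA_real_
         ),
         residue_table = residue_table, network = net, centrality = centrality,
         stats = stats, cp = cp, optimization = opt, efficiency = eff,
         paths = paths, manifest = NULL),
    class = "coevnet_run"
  )
  if (!is.null(config$output_dir)) {
    run$manifest <- write_run_outputs(run, config$output_dir)
  }
  run
}

#' @export
print.coevnet_run <- function(x, ...) {
  cat(sprintf(
    "<coevnet_run> %d residues, %d network edges, efficiency %.4g, %d path pair(s)\n",
    nrow(x$residue_table), nrow(x$network$edges), x$efficiency, length(x$paths)
  ))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `coevnet_run`.
#' @param ... Unused.
#' @return Tibble with residue/edge counts, efficiency, and CP weights.
#' @export
glance.coevnet_run <- function(x, ...) {
  tibble(
    n_residues = nrow(x$residue_table),
    n_edges = nrow(x$network$edges),
    n_frames = x$ensemble_summary$n_frames,
    alpha = x$network$alpha,
    efficiency = x$efficiency,
    w1 = x$optimization$w1 %||% x$config$w1,
    w2 = x$optimization$w2 %||% x$config$w2
  )
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.8g", x))
}

write_text_table <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  path
}

write_matrix_file <- function(m, path) {
  writeLines(apply(m, 1, function(r) paste(fmt_num(r), collapse = " ")), path)
  path
}

# Write all run outputs and return a manifest with content hashes.
write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  files["residues"] <- write_text_table(run$residue_table,
                                        file.path(dir, "residues.csv"))
  files["edges"] <- write_text_table(tidy(run$network),
                                     file.path(dir, "edges.csv"))
  files["kirchhoff_modes"] <- write_text_table(tidy(run$modes),
                                               file.path(dir, "modes.csv"))
  if (length(run$paths)) {
    path_report <- purrr::imap(run$paths, function(pe, key) {
      tab <- tidy(pe)
      list(pair = key, blocks = pe$blocks,
           paths = purrr::pmap(tab, function(path, n_blocks, occupancy, mean_length) {
             list(path = path, n_blocks = n_blocks, occupancy = occupancy,
                  mean_length = if (is.na(mean_length)) NULL else mean_length)
           }))
    })
    jsonlite::write_json(unname(path_report), file.path(dir, "paths.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    files["paths"] <- file.path(dir, "paths.json")
  }
  hashes <- as.character(tools::md5sum(unname(files)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("coevnet")),
    seed = run$config$seed,
    files = purrr::map2(unname(files), hashes,
                        function(f, h) list(file = basename(f), md5 = h))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Compare per-residue profiles of two runs
#'
#' Joins the residue tables of two runs on residue labels (intersection
#' must cover at least half of the smaller run) and reports, per profile
#' (mobility, centrality, cp, pmi, cmi, kl), the Spearman rank
#' correlation and maximum absolute difference, with per-residue deltas.
#'
#' @param run_a,run_b `coevnet_run` objects (or their residue tables).
#' @return List with `summary` (per-profile tibble) and `deltas`
#'   (per-residue tibble).
#' @export
compare_profiles <- function(run_a, run_b) {
  ta <- if (inherits(run_a, "coevnet_run")) run_a$residue_table else run_a
  tb <- if (inherits(run_b, "coevnet_run")) run_b$residue_table else run_b
  common <- intersect(ta$label, tb$label)
  if (length(common) == 0L) abort("runs share no residues")
  if (length(common) < 0.5 * min(nrow(ta), nrow(tb))) {
    abort("runs share fewer than half their residues; comparison not meaningful")
  }
  ia <- match(common, ta$label)
  ib <- match(common, tb$label)
  profiles <- intersect(c("mobility", "centrality", "cp", "pmi", "cmi", "kl"),
                        intersect(names(ta), names(tb)))
  summary <- purrr::map_dfr(profiles, function(p) {
    a <- ta[[p]][ia]
    b <- tb[[p]][ib]
    ok <- !is.na(a) & !is.na(b)
    tibble(
      profile = p,
      n = sum(ok),
      spearman = if (sum(ok) >= 3 && sd(a[ok]) > 0 && sd(b[ok]) > 0) {
        cor(a[ok], b[ok], method = "spearman")
      } else NA_real_,
      max_abs_diff = if (any(ok)) max(abs(a[ok] - b[ok])) else NA_real_
    )
  })
  deltas <- purrr::map_dfc(profiles, function(p) {
    out <- tibble(x = ta[[p]][ia] - tb[[p]][ib])
    names(out) <- paste0("d_", p)
    out
  })
  deltas <- dplyr::bind_cols(tibble(label = common), deltas)
  list(summary = summary, deltas = deltas)
}
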