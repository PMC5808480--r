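# Orchestration: run the full analysis over a set of structures
# (ensembles -> SEA -> clustering -> destructive bonds; stiffness ->
# tails/paths; optional survival and conservation correlations), writing
# every intermediate table plus a run manifest and a text summary.

#' Pipeline configuration
#'
#' @param structures named character vector of PDB paths (names are
#'   structure ids), or a named list of `enstab_structure` objects.
#' @param wt_id id of the wild-type structure (must appear exactly
#'   once).
#' @param ensemble an [ensemble_config()] for the conformer stage.
#' @param dist_cutoff,angle_cutoff hydrogen-bond criteria.
#' @param tail destructive-bond tail fraction.
#' @param counting_policy H-table counting policy
#'   (see [build_h_table()]).
#' @param stiffness_nodes node policy for the stiffness stage
#'   (default `"calpha"`).
#' @param site metal node label for the site-stiffness profile (e.g.
#'   `"CU:A"`), or NULL to use the first metal node if any.
#' @param tail_mean,tail_site tail fractions for the mean-stiffness and
#'   site-profile extractions.
#' @param survival optional path to a TSV `mutation<TAB>years` table;
#'   mutation ids must be variant structure ids.
#' @param conservation optional path to a TSV
#'   `chain<TAB>position<TAB>score` table.
#' @param seed integer seed recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(structures, wt_id,
                            ensemble = ensemble_config(),
                            dist_cutoff = 3.0, angle_cutoff = 135,
                            tail = 0.05,
                            counting_policy = "variant_present_bonds",
                            stiffness_nodes = "calpha", site = NULL,
                            tail_mean = 0.0017, tail_site = 0.0065,
                            survival = NULL, conservation = NULL,
                            seed = 1L) {
  ids <- names(structures)
  if (is.null(ids) || any(ids == "")) stop("structures must be named")
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  if (sum(ids == wt_id) != 1L) {
    stop("wt_id must designate exactly one structure")
  }
  if (is.character(structures)) {
    missing <- structures[!file.exists(structures)]
    if (length(missing) > 0L) {
      stop("structure paths do not exist: ", paste(missing, collapse = ", "))
    }
  }
  for (p in c(survival, conservation)) {
    if (!is.null(p) && !file.exists(p)) stop("input table missing: ", p)
  }
  structure(
    list(structures = structures, wt_id = wt_id, ensemble = ensemble,
         dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff,
         tail = tail, counting_policy = counting_policy,
         stiffness_nodes = stiffness_nodes, site = site,
         tail_mean = tail_mean, tail_site = tail_site,
         survival = survival, conservation = conservation,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

load_structures <- function(config) {
  if (is.character(config$structures)) {
    out <- lapply(config$structures, read_pdb)
    for (i in seq_along(out)) out[[i]]$id <- names(config$structures)[i]
    out
  } else {
    config$structures
  }
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: conformer ensembles for every
#' structure; the SEA table; mean-shift clustering of variants by SEA;
#' deviations/contributions and the H table; high-contribution variant
#' selection and destructive-bond detection; wild-type stiffness with
#' tail extraction, site profile and (when two metal nodes exist) the
#' transmission path; optional survival and conservation correlations
#' (skipped, and marked "not run", when the tables are absent). All
#' intermediate tables are written under `out_dir` as TSV, together
#' with `manifest.txt` (config echo, seed, wall times) and
#' `summary.txt`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty output directory.
#' @return (invisibly) a list with every stage result.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop("output directory ", out_dir, " is not empty; use force = TRUE")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  times <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    times[[stage]] <<- t1 - t0
    t0 <<- t1
    message("[enstab] stage done: ", stage)
  }

  structures <- load_structures(config)
  wt <- structures[[config$wt_id]]
  tick("load")

  ensembles <- lapply(structures, function(s) {
    model <- build_elastic_model(s, config$ensemble)
    modes <- compute_modes(model, n_nontrivial = config$ensemble$n_modes)
    generate_conformers(s, modes, config$ensemble, model = model)
  })
  tick("ensembles")

  sea <- compute_sea_table(ensembles, config$wt_id,
                           config$dist_cutoff, config$angle_cutoff)
  write_sea_table(sea, file.path(out_dir, "sea.tsv"))
  tick("sea")

  variant_ids <- setdiff(colnames(sea$values), config$wt_id)
  sea_points <- t(sea$values)
  cluster_bw <- tryCatch(estimate_bandwidth(sea_points),
                         error = function(e) NA_real_)
  sea_clusters <- if (is.finite(cluster_bw)) {
    mean_shift(sea_points, cluster_bw)
  } else NULL
  if (!is.null(sea_clusters)) {
    utils::write.table(
      data.frame(structure = rownames(sea_points),
                 cluster = sea_clusters$labels),
      file.path(out_dir, "sea_clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("clustering")

  contrib <- compute_deviations(sea)
  h <- build_h_table(contrib, config$counting_policy)
  utils::write.table(
    data.frame(variant = rownames(h$counts), h$counts, s_bar = h$s_bar,
               D = contrib$D[rownames(h$counts)], check.names = FALSE),
    file.path(out_dir, "h_table.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  selected <- tryCatch(select_high_contribution_variants(h),
                       warning = function(w) character(0))
  destructive <- if (length(selected) > 0L) {
    detect_destructive(contrib, selected, config$tail)
  } else NULL
  if (!is.null(destructive)) {
    utils::write.table(
      data.frame(bond = destructive$destructive_bonds,
                 xi_bar = destructive$xi_bar[destructive$destructive_bonds],
                 rank = seq_along(destructive$destructive_bonds)),
      file.path(out_dir, "destructive_bonds.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res <- residues_of_bonds(destructive$destructive_bonds)
    utils::write.table(res, file.path(out_dir, "destructive_residues.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tick("destructive")

  stiff_cfg <- ensemble_config(
    n_modes = config$ensemble$n_modes, cutoff = config$ensemble$cutoff,
    gamma = config$ensemble$gamma, node_policy = config$stiffness_nodes)
  stiff_model <- build_elastic_model(wt, stiff_cfg)
  stiff_modes <- compute_modes(stiff_model)
  kappa <- pairwise_stiffness(stiff_modes)
  kbar <- mean_stiffness(kappa)
  top_mean <- top_tail(kbar, config$tail_mean)
  metals <- rownames(kappa$kappa)[kappa$nodes$is_metal]
  site <- if (!is.null(config$site)) config$site else
    if (length(metals) > 0L) metals[1L] else NULL
  site_prof <- if (!is.null(site)) site_stiffness_profile(kappa, site) else NULL
  top_site <- if (!is.null(site_prof)) {
    top_tail(site_prof[!names(site_prof) %in% metals], config$tail_site)
  } else NULL
  path <- if (length(metals) >= 2L) {
    tryCatch(transmission_path(kappa, metals[1L], metals[2L],
                               config$ensemble$cutoff),
             error = function(e) NULL)
  } else NULL
  utils::write.table(
    data.frame(residue = names(kbar), mean_stiffness = kbar,
               site_stiffness = if (is.null(site_prof)) NA else
                 site_prof[names(kbar)]),
    file.path(out_dir, "stiffness_summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  tick("stiffness")

  survival_cor <- NULL
  if (!is.null(config$survival)) {
    surv <- utils::read.delim(config$survival, stringsAsFactors = FALSE)
    # correlate survival with each variant's deviation magnitude D
    common <- intersect(surv$mutation, names(contrib$D))
    if (length(common) >= 3L) {
      survival_cor <- pearson(contrib$D[common],
                              surv$years[match(common, surv$mutation)])
    }
  }
  conservation_cor <- NULL
  if (!is.null(config$conservation)) {
    cons <- utils::read.delim(config$conservation, stringsAsFactors = FALSE)
    lab <- paste0(cons$position, ".", cons$chain)
    common <- intersect(lab, names(kbar))
    if (length(common) >= 3L) {
      conservation_cor <- pearson(kbar[common],
                                  cons$score[match(common, lab)])
    }
  }
  tick("associations")

  manifest <- c(
    sprintf("enstab %s", as.character(utils::packageVersion("enstab"))),
    sprintf("seed: %d", config$seed),
    sprintf("wt: %s", config$wt_id),
    sprintf("structures: %s", paste(names(config$structures),
                                    collapse = ", ")),
    sprintf("ensemble: n_modes=%d dq=%g..%g/%g cutoff=%g nodes=%s amplitude=%g",
            config$ensemble$n_modes, config$ensemble$dq_min,
            config$ensemble$dq_max, config$ensemble$dq_step,
            config$ensemble$cutoff, config$ensemble$node_policy,
            config$ensemble$amplitude_scale),
    sprintf("hbond: dist<=%g angle>=%g", config$dist_cutoff,
            config$angle_cutoff),
    sprintf("stage seconds: %s",
            paste(sprintf("%s=%.1f", names(times), times), collapse = " "))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  summary_lines <- c(
    sprintf("structures: %d (%d variants + WT)", length(structures),
            length(variant_ids)),
    sprintf("conformers: %d per structure, %d total",
            length(ensembles[[1L]]$conformers),
            sum(vapply(ensembles, function(e) length(e$conformers), 1L))),
    sprintf("bond universe: %d", nrow(sea$values)),
    if (!is.null(sea_clusters)) {
      sprintf("SEA clusters: %d (bandwidth %.3g)", sea_clusters$n_clusters,
              cluster_bw)
    } else "SEA clusters: not run (degenerate bandwidth)",
    sprintf("selected high-contribution variants: %s",
            if (length(selected)) paste(selected, collapse = ", ") else
              "(none)"),
    if (!is.null(destructive)) {
      sprintf("destructive bonds: %d at threshold %.4g (explained %.2f)",
              length(destructive$destructive_bonds), destructive$threshold,
              destructive$explained_fraction)
    } else "destructive bonds: not run (empty selection)",
    sprintf("top mean-stiffness residues (%.2f%% tail): %s",
            100 * config$tail_mean, paste(top_mean, collapse = ", ")),
    if (!is.null(top_site)) {
      sprintf("top site-stiffness residues to %s (%.2f%% tail): %s", site,
              100 * config$tail_site, paste(top_site, collapse = ", "))
    } else "site stiffness: not run (no metal nodes)",
    if (!is.null(path)) {
      sprintf("transmission path: %s", paste(path, collapse = "-"))
    } else "transmission path: not run",
    if (!is.null(survival_cor)) {
      sprintf("survival ~ deviation: R = %.3f (p = %.3g)", survival_cor$R,
              survival_cor$p)
    } else "survival correlation: not run",
    if (!is.null(conservation_cor)) {
      sprintf("conservation ~ stiffness: R = %.3f (p = %.3g)",
              conservation_cor$R, conservation_cor$p)
    } else "conservation correlation: not run"
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(
    structures = structures, ensembles = ensembles, sea = sea,
    sea_clusters = sea_clusters, contrib = contrib, h = h,
    selected = selected, destructive = destructive, kappa = kappa,
    mean_stiffness = kbar, top_mean = top_mean, site = site,
    site_profile = site_prof, top_site = top_site, path = path,
    survival = survival_cor, conservation = conservation_cor,
    times = times
  ))
}
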