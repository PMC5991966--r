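# End-to-end orchestration: load -> frame -> core -> superpose ->
# RMSF/RMSD/DCCM -> embeddings -> clustering -> representatives -> networks
# -> screening re-score -> sequence comparisons, driven by a configuration
# list (or YAML file) and writing a manifest of artifacts.

#' Default pipeline configuration
#'
#' @param outdir Output directory for stage artifacts.
#' @param seed Seed used by every stochastic stage.
#' @return Configuration list; override entries as needed and pass to
#'   [run_pipeline()].
#' @export
pipeline_config <- function(outdir = tempfile("allostruct_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    # input: either `structures` (list of Structure) / `pdb_files` + chains,
    # or a synthetic ensemble specification
    structures = NULL,
    pdb_files = NULL,
    chains = NULL,
    synthetic = list(m = 160L, n = 27L, n_clusters = 3L, separation = 3.0,
                     mode_sds = c(1.0, 0.6), sigma = 0.3),
    regions = rab11_regions(),
    core = list(v_stop = 1.0, floor_frac = 0.4),
    embeddings = list(d_pca = 3L, d_ica = 2L, d_lle = 2L,
                      lle_k_candidates = c(4L, 6L, 8L, 10L)),
    clustering = list(linkage = "average", k = 3L),
    rin = list(cutoff = 7.0),
    sites = rab11_sites(),
    score_table = NULL,
    sequences = NULL
  )
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(pipeline_config(), cfg)
}

#' Run the full ensemble-analysis pipeline
#'
#' Stages run in dependency order; a stage failure halts the run with an
#' error naming the stage. All artifacts (CSV/TSV/JSON) are written under
#' `config$outdir`, and the returned report carries per-stage status,
#' parameters, the file manifest and headline numbers. Reruns with the same
#' configuration and inputs are deterministic.
#'
#' @param config A [pipeline_config()] list or the path to a YAML file with
#'   the same fields.
#' @return A `RunReport` list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), manifest = character(0), headline = list(),
                 config = config)
  emit <- function(name, writer) {
    path <- file.path(config$outdir, name)
    writer(path)
    report$manifest <<- c(report$manifest, path)
    path
  }
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- "ok"
    out
  }

  # --- input ----------------------------------------------------------------
  truth <- NULL
  ens <- stage("input", {
    if (!is.null(config$structures)) {
      structures <- config$structures
      ensemble_matrix(structures)
    } else if (!is.null(config$pdb_files)) {
      structures <- mapply(read_structure, config$pdb_files, config$chains,
                           SIMPLIFY = FALSE)
      ensemble_matrix(structures)
    } else {
      spec <- do.call(ensemble_spec,
                      c(config$synthetic, list(seed = config$seed)))
      gen <- make_ensemble(spec)
      truth <- gen$truth
      structures <- ensemble_structures(gen$ensemble)
      gen$ensemble
    }
  })
  # --- core + superposition -------------------------------------------------
  core <- stage("core", {
    floor_size <- max(30L, ceiling(config$core$floor_frac * n_residues(ens)))
    find_invariant_core(ens, v_stop = config$core$v_stop,
                        floor_size = min(floor_size, n_residues(ens)))
  })
  aligned <- stage("superpose", superpose_ensemble(ens, core))

  # --- flexibility ----------------------------------------------------------
  rmsf <- stage("rmsf", ensemble_rmsf(aligned))
  emit("rmsf.csv", function(p) utils::write.csv(
    data.frame(resno = aligned$frame, rmsf = rmsf), p, row.names = FALSE))

  rmsd_all <- stage("rmsd", pairwise_rmsd(aligned))
  emit("rmsd_all.csv", function(p) utils::write.csv(rmsd_all, p))
  region_rmsd <- list()
  for (rg in config$regions) {
    idx <- tryCatch(select_region(aligned$frame, rg), error = function(e) NULL)
    if (!is.null(idx)) {
      region_rmsd[[rg$name]] <- pairwise_rmsd(aligned, idx)
      emit(paste0("rmsd_", rg$name, ".csv"),
           local({ M <- region_rmsd[[rg$name]]
                   function(p) utils::write.csv(M, p) }))
    }
  }

  # --- correlated motions ---------------------------------------------------
  dccm <- stage("dccm", compute_dccm(aligned))
  emit("dccm.csv", function(p) write_dccm(dccm, csv = p))

  # --- embeddings + clustering + representatives ----------------------------
  emb <- stage("embed", {
    k_cands <- config$embeddings$lle_k_candidates
    k_cands <- k_cands[k_cands < n_members(aligned)]
    k_lle <- select_lle_k(aligned, k_cands, d = config$embeddings$d_lle)
    list(pca = ensemble_pca(aligned, config$embeddings$d_pca),
         ica = ensemble_fastica(aligned, config$embeddings$d_ica,
                                seed = config$seed),
         lle = ensemble_lle(aligned, k = as.integer(k_lle),
                            d = config$embeddings$d_lle),
         lle_k = as.integer(k_lle),
         lle_k_criterion = attr(k_lle, "criterion"))
  })
  for (nm in c("pca", "ica", "lle")) {
    sc <- emb[[nm]]$scores
    emit(paste0("scores_", nm, ".csv"), local({ s <- sc; function(p)
      utils::write.csv(data.frame(member_id = rownames(s), s), p,
                       row.names = FALSE) }))
  }

  clus <- stage("cluster", {
    lapply(list(pca = emb$pca, ica = emb$ica, lle = emb$lle), function(e) {
      D <- as.matrix(stats::dist(e$scores))
      hierarchical_cluster(D, k = config$clustering$k,
                           linkage = config$clustering$linkage)
    })
  })
  reps <- stage("representatives", {
    # representatives follow the LLE clustering (the embedding that separates
    # the most structure families in the fewest dimensions)
    clus$lle$clustroids
  })
  emit("clusters.tsv", function(p) {
    df <- do.call(rbind, lapply(names(clus), function(nm) {
      cm <- clus[[nm]]
      data.frame(embedding = nm, member_id = names(cm$labels),
                 cluster = unname(cm$labels),
                 is_clustroid = names(cm$labels) %in% cm$clustroids)
    }))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  # --- residue interaction networks for the representatives -----------------
  rins <- stage("rin", {
    rep_structs <- structures[match(reps, vapply(structures, `[[`,
                                                 character(1), "id"))]
    lapply(rep_structs, function(s) {
      g <- build_rin(s, cutoff = config$rin$cutoff)
      list(id = s$id, network = g, betweenness = rin_betweenness(g),
           com = center_of_mass_distances(s))
    })
  })
  emit("betweenness.csv", function(p) {
    df <- do.call(rbind, lapply(rins, function(r)
      data.frame(member_id = r$id, resno = names(r$betweenness),
                 betweenness = unname(r$betweenness))))
    utils::write.csv(df, p, row.names = FALSE)
  })

  # --- screening re-score (optional) ----------------------------------------
  rescore <- NULL
  if (!is.null(config$score_table)) {
    rescore <- stage("rescore", weighted_score(load_scores(config$score_table)))
    emit("rescore.csv", function(p) utils::write.csv(rescore, p,
                                                     row.names = FALSE))
  } else report$stages$rescore <- "skipped"

  # --- sequence comparisons (optional) --------------------------------------
  seqid <- NULL
  if (!is.null(config$sequences)) {
    seqid <- stage("seqid", {
      seqs <- if (is.character(config$sequences) &&
                  length(config$sequences) == 1L)
        read_fasta_seqs(config$sequences) else unlist(config$sequences)
      identity_matrix(seqs)
    })
    emit("identity_matrix.csv", function(p) utils::write.csv(seqid, p))
  } else report$stages$seqid <- "skipped"

  report$headline <- list(
    n_members = n_members(ens), n_residues = n_residues(ens),
    core_size = length(core),
    variance_fractions = emb$pca$variance_fractions,
    lle_k = emb$lle_k,
    representatives = unname(reps),
    top_ligands = if (!is.null(rescore)) utils::head(rescore$ligand, 5),
    identity_matrix = seqid)
  if (!is.null(truth)) report$truth <- truth
  report$results <- list(core = core, aligned = aligned, rmsf = rmsf,
                         rmsd = c(list(all = rmsd_all), region_rmsd),
                         dccm = dccm, embeddings = emb, clusters = clus,
                         rins = rins, rescore = rescore)
  emit("report.json", function(p) jsonlite::write_json(
    list(stages = report$stages,
         headline = report$headline[c("n_members", "n_residues", "core_size",
                                      "variance_fractions", "lle_k",
                                      "representatives")],
         manifest = basename(report$manifest)),
    p, auto_unbox = TRUE, digits = NA))
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport:", length(x$stages), "stages\n")
  for (nm in names(x$stages)) cat("  ", nm, ":", x$stages[[nm]], "\n")
  cat("representatives:", paste(x$headline$representatives, collapse = ", "),
      "\n")
  invisible(x)
}
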