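# Config-driven orchestration: simulate -> score -> xcorr -> cellenrich ->
# dcq -> pd, each stage reading only files written by earlier stages into
# the run directory, with a JSON run manifest recording the config hash,
# seeds, per-stage outputs and row counts.  All analysis inputs go through
# the io_formats readers, so a pipeline run also exercises every
# round-trip.

#' Default pipeline configuration
#'
#' Every numeric default of the pipeline surfaced as a config key:
#' FDR alpha 0.05, score cut-off 0, ranking length 2000, window 200 /
#' step 100, DCQ repeats 3 / lambda-min ratio 0.2 / quantity filter 2.0.
#'
#' @param seed integer seed driving all generators.
#' @param out_dir run directory (created if needed).
#' @return a nested config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "th17_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      deg = list(n_studies = 4L, n_genes = 2000L, rho = 0.7),
      cohort = list(n_samples = 60L, planted_fraction = 0.4, shift = 2),
      mixture = list(n_genes = 500L, n_cell_types = 10L,
                     markers_per_type = 30L),
      ranking = list(n_genes = 2500L, n_marker_ranks = 30L),
      pd = list(doses = c(1, 3, 10, 30), cv = 0.05)
    ),
    score = list(cutoff = 0),
    xcorr = list(alpha = 0.05),
    cellenrich = list(top_n = 2000L, window = 200L, step = 100L),
    dcq = list(repeats = 3L, lambda_min_ratio = 0.2, threshold = 2.0),
    pd = list(fit_hill = TRUE)
  )
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("run_pipeline: config must be a list or path")
  for (key in c("seed", "out_dir", "simulate", "score", "xcorr",
                "cellenrich", "dcq", "pd")) {
    if (is.null(config[[key]])) {
      stop(sprintf("run_pipeline: config missing required key '%s'", key))
    }
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop("run_pipeline: config$seed must be a single integer")
  }
  for (key in c("deg", "cohort", "mixture", "ranking", "pd")) {
    if (is.null(config$simulate[[key]])) {
      stop(sprintf("run_pipeline: config$simulate missing '%s'", key))
    }
  }
  config
}

#' Run the full demo pipeline
#'
#' Executes the stages in dependency order inside `config$out_dir`:
#' `simulate` writes synthetic inputs (plus truth sidecars), `score`
#' computes signature scores / clusters / prevalence on the cohort
#' matrix, `xcorr` the filtered cross-study correlation matrix,
#' `cellenrich` the weighted cell-type enrichment table, `dcq` the
#' deconvolution quantities, and `pd` the efficacy profile and Hill fits.
#' Deterministic given the config (seed included): re-running with the
#' same config reproduces every output byte-identically.
#'
#' @param config a config list from [default_pipeline_config()] (possibly
#'   modified) or a path to a JSON file with the same structure.  Schema
#'   violations error before any stage runs.
#' @return a `run_manifest` list (also written to
#'   `<out_dir>/manifest.json`): `config_hash`, `seed`, per-stage output
#'   paths with row counts, package/R versions, wall-clock seconds.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path_in <- function(...) file.path(config$out_dir, ...)
  seed <- as.integer(config$seed)
  stages <- list()
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  register <- function(stage, ...) {
    files <- list(...)
    stages[[stage]] <<- lapply(files, function(f) {
      n <- length(readLines(f))
      # TSVs carry a header line; GMT files do not
      list(path = f, n_rows = if (grepl("\\.gmt$", f)) n else n - 1L)
    })
  }

  ## simulate ----------------------------------------------------------
  sim <- config$simulate
  degs <- do.call(gen_deg_studies,
                  c(list(seed = seed), sim$deg))
  deg_paths <- vapply(degs, function(d) {
    write_deg_table(d, path_in(sprintf("deg_%s.tsv", attr(d, "study_id"))))
  }, "")
  cohort <- do.call(gen_cohort_matrix, c(list(seed = seed + 1L), sim$cohort))
  mat_path <- path_in("cohort_matrix.tsv")
  grp_path <- path_in("cohort_groups.tsv")
  write_expression_matrix(cohort$matrix, mat_path, grp_path)
  truth_path <- tsv(data.frame(sample = names(cohort$truth),
                               truth = unname(cohort$truth)),
                    path_in("cohort_truth.tsv"))
  sig_path <- path_in("signatures.gmt")
  write_gmt(gene_set_collection(list(TH17 = default_th17_signature),
                                "Th17 chemokine signature"), sig_path)
  mix <- do.call(gen_mixture_foldchange, c(list(seed = seed + 2L),
                                           sim$mixture))
  comp_path <- write_cell_compendium(mix$compendium,
                                     path_in("compendium.tsv"))
  fc_path <- tsv(data.frame(gene = names(mix$input$fold_change),
                            fold_change = unname(mix$input$fold_change)),
                 path_in("fold_changes.tsv"))
  wtruth_path <- tsv(data.frame(cell_type = names(mix$w_true),
                                w_true = unname(mix$w_true)),
                     path_in("mixture_truth.tsv"))
  rk_cfg <- sim$ranking
  planted <- gen_ranked_planting(seed + 3L, n_genes = rk_cfg$n_genes,
                                 marker_ranks =
                                   seq_len(rk_cfg$n_marker_ranks))
  rkdeg_path <- write_deg_table(planted$table, path_in("ranking_deg.tsv"))
  markers_path <- path_in("celltype_markers.gmt")
  write_gmt(gene_set_collection(
    list(planted_type = planted$markers,
         absent_type = sprintf("NOGENE%03d", 1:20)),
    c("markers planted near the top", "markers absent from the ranking")),
    markers_path)
  pd_cfg <- sim$pd
  pdsim <- do.call(gen_pd_table, c(list(seed = seed + 4L), pd_cfg))
  pd_path <- write_pd_table(pdsim$table, path_in("pd_table.tsv"))
  pdtruth_path <- tsv(pdsim$truth$grid, path_in("pd_truth.tsv"))
  do.call(register, c(list("simulate"), as.list(deg_paths),
                      list(mat_path, grp_path, truth_path, sig_path,
                           comp_path, fc_path, wtruth_path, rkdeg_path,
                           markers_path, pd_path, pdtruth_path)))

  ## score -------------------------------------------------------------
  mat <- read_expression_matrix(mat_path, grp_path)
  sigs <- read_gmt(sig_path)
  scores <- signature_score(mat, sigs)
  assign <- assign_clusters(scores, cutoff = config$score$cutoff)
  prev <- cluster_prevalence(assign)
  scores_path <- tsv(data.frame(sample = rownames(scores), scores,
                                label = assign$label, check.names = FALSE),
                     path_in("scores.tsv"))
  prev_path <- tsv(prev, path_in("prevalence.tsv"))
  register("score", scores_path, prev_path)

  ## xcorr -------------------------------------------------------------
  tables <- lapply(deg_paths, function(p) {
    read_deg_table(p, study_id = sub("^deg_(.*)\\.tsv$", "\\1", basename(p)))
  })
  filtered <- lapply(tables, filter_degs, alpha = config$xcorr$alpha)
  cm <- correlation_matrix(filtered)
  corr_path <- write_correlation_matrix(cm, path_in("correlation.tsv"))
  register("xcorr", corr_path)

  ## cellenrich --------------------------------------------------------
  rk_table <- read_deg_table(rkdeg_path, study_id = "ranking",
                             species = "mouse")
  ranked <- rank_genes(rk_table, top_n = config$cellenrich$top_n)
  marker_sets <- read_gmt(markers_path)
  enrich <- score_all_cell_types(ranked, marker_sets)
  enrich_path <- tsv(enrich, path_in("cell_enrichment.tsv"))
  register("cellenrich", enrich_path)

  ## dcq ---------------------------------------------------------------
  comp <- read_cell_compendium(comp_path)
  fc_df <- read_delim_file(fc_path)
  fc <- stats::setNames(fc_df$fold_change, fc_df$gene)
  dq <- dcq(dcq_input(fc, comp), repeats = config$dcq$repeats,
            lambda_min_ratio = config$dcq$lambda_min_ratio,
            seed = seed + 5L)
  dcq_path <- tsv(as.data.frame(dq), path_in("dcq_quantities.tsv"))
  register("dcq", dcq_path)

  ## pd ----------------------------------------------------------------
  pdt <- read_pd_table(pd_path)
  prof <- efficacy_profile(pdt)
  prof_df <- data.frame(endpoint = rownames(prof),
                        as.data.frame(unclass(prof)), check.names = FALSE)
  prof_path <- tsv(prof_df, path_in("efficacy_profile.tsv"))
  pd_files <- list(prof_path)
  if (isTRUE(config$pd$fit_hill)) {
    raw <- attr(prof, "raw")
    treated <- colnames(raw)
    exposures <- vapply(treated, function(g) {
      mean(pdt$trough_exposure[pdt$group == g], na.rm = TRUE)
    }, 0)
    fits <- lapply(c("IL-17", "IL-22"), function(ep) {
      if (!(ep %in% rownames(raw))) return(NULL)
      f <- fit_hill(exposures, raw[ep, ])
      data.frame(endpoint = ep, I_max = f$I_max, EC50 = f$EC50, h = f$h,
                 rss = f$rss, stringsAsFactors = FALSE)
    })
    fits <- do.call(rbind, fits)
    hill_path <- tsv(fits, path_in("hill_fits.tsv"))
    pd_files <- c(pd_files, hill_path)
  }
  do.call(register, c(list("pd"), pd_files))

  ## manifest ----------------------------------------------------------
  cfg_path <- path_in("config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    stages = stages,
    versions = list(
      package = as.character(utils::packageVersion("th17translate")),
      r = paste(R.version$major, R.version$minor, sep = ".")),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, path_in("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}
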