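# Stage orchestration over a run directory.
#
# Each stage reads the on-disk outputs of earlier stages, derives its own
# seed deterministically from the master seed and the stage name (so stages
# rerun independently yet reproducibly), and writes TSV/JSON outputs plus an
# entry in the run manifest.

pipeline_stages <- function() {
  c("simulate", "normalize", "diversity", "diffabund", "classify",
    "cytokines", "network")
}

require_files <- function(dir, files, stage, produced_by) {
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing)) {
    stop_pb("stage '", stage, "' needs output(s) of stage '", produced_by,
            "': missing ", paste(missing, collapse = ", "),
            " -- run '", produced_by, "' first")
  }
}

#' Run the analysis pipeline over a run directory
#'
#' Subcommands: `simulate` (synthetic cohort), `normalize` (genus merge +
#' log/whiten/detrend), `diversity` (rarefaction, alpha, UniFrac, PCoA,
#' PERMANOVA), `diffabund` (UC-vs-CD effect-size screen), `classify`
#' (LOOCV linear SVM), `cytokines` (panel statistics), `network` (dynamic
#' correlation network with scrambled null), or `all`. Stages are idempotent
#' given identical inputs and seed; reruns with the same seed reproduce the
#' stage outputs bit-identically.
#'
#' @param outdir Run directory (created if needed).
#' @param stages Character vector of subcommands, or `"all"`.
#' @param config A [run_config()]; its `rng_seed` is the master seed.
#' @param spec A [cohort_spec()] for the `simulate` stage (its seed is
#'   overridden by the derived stage seed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(outdir, stages = "all", config = run_config(),
                         spec = cohort_spec()) {
  if (identical(stages, "all")) stages <- pipeline_stages()
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) stop_pb("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list(seed = config$rng_seed,
         config = unclass(config),
         config_hash = rlang::hash(unclass(config)),
         package_version = as.character(utils::packageVersion("pregbiome")),
         stages = list())
  }
  for (st in stages) {
    t0 <- Sys.time()
    outputs <- run_stage(st, outdir, config, spec)
    manifest$stages[[st]] <- list(
      seed = derive_seed(config$rng_seed, st),
      outputs = as.list(outputs),
      wall_time_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  log_line(outdir, "completed stage(s): ", paste(stages, collapse = ", "))
  invisible(manifest)
}

log_line <- function(outdir, ...) {
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z "), ..., "\n", sep = "",
      file = file.path(outdir, "run.log"), append = TRUE)
}

run_stage <- function(stage, dir, config, spec) {
  seed <- derive_seed(config$rng_seed, stage)
  switch(stage,
    simulate = {
      spec$seed <- seed
      mb <- generate_microbiome(spec)
      cy <- generate_cytokines(spec, mb$meta)
      write_feature_table(mb$table, file.path(dir, "feature_table.tsv"))
      readr::write_tsv(mb$taxonomy, file.path(dir, "taxonomy.tsv"),
                       progress = FALSE)
      ape::write.tree(mb$tree, file.path(dir, "tree.nwk"))
      readr::write_tsv(mb$meta, file.path(dir, "metadata.tsv"),
                       progress = FALSE)
      readr::write_tsv(cy$panel, file.path(dir, "cytokines.tsv"),
                       progress = FALSE)
      jsonlite::write_json(list(microbiome = mb$truth, cytokines = cy$truth),
                           file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      c("feature_table.tsv", "taxonomy.tsv", "tree.nwk", "metadata.tsv",
        "cytokines.tsv", "ground_truth.json")
    },
    normalize = {
      require_files(dir, c("feature_table.tsv", "taxonomy.tsv", "metadata.tsv"),
                    stage, "simulate")
      table <- read_feature_table(file.path(dir, "feature_table.tsv"))
      tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
      meta <- read_metadata(file.path(dir, "metadata.tsv"))
      norm <- normalize_microbiome(table, tax, meta,
                                   pseudo_count = config$pseudo_count,
                                   detrend = TRUE)
      readr::write_tsv(tibble::as_tibble(unclass(norm), rownames = "sample_id"),
                       file.path(dir, "normalized.tsv"), progress = FALSE)
      jsonlite::write_json(
        list(pseudo_count = config$pseudo_count,
             merged_genus_count = ncol(norm), detrended = TRUE,
             seed = seed),
        file.path(dir, "normalized_provenance.json"), auto_unbox = TRUE)
      c("normalized.tsv", "normalized_provenance.json")
    },
    diversity = {
      require_files(dir, c("feature_table.tsv", "tree.nwk", "metadata.tsv"),
                    stage, "simulate")
      table <- read_feature_table(file.path(dir, "feature_table.tsv"))
      tree <- read_tree(file.path(dir, "tree.nwk"))
      meta <- read_metadata(file.path(dir, "metadata.tsv"))
      rar <- depth_filter_and_rarefy(table, depth = config$rarefaction_depth,
                                     seed = seed)
      alpha <- alpha_diversity(rar, tree)
      readr::write_tsv(alpha, file.path(dir, "alpha_diversity.tsv"),
                       progress = FALSE)
      keep <- meta$sample_id %in% alpha$sample_id
      grp <- ifelse(meta$group[keep] == "control", "control", "IBD")
      for (w in c(FALSE, TRUE)) {
        d <- unifrac(rar, tree, weighted = w)
        nm <- if (w) "weighted_unifrac" else "unweighted_unifrac"
        write_distance_matrix(d, file.path(dir, paste0(nm, ".tsv")))
        readr::write_tsv(pcoa_coordinates(d),
                         file.path(dir, paste0(nm, "_pcoa.tsv")),
                         progress = FALSE)
        pm <- permanova(d, grp, n_perm = config$permanova_permutations,
                        seed = seed)
        readr::write_tsv(dplyr::mutate(pm, metric = nm),
                         file.path(dir, paste0(nm, "_permanova.tsv")),
                         progress = FALSE)
      }
      ac <- alpha_compare(alpha, grp)
      readr::write_tsv(ac, file.path(dir, "alpha_tests.tsv"), progress = FALSE)
      c("alpha_diversity.tsv", "unweighted_unifrac.tsv",
        "weighted_unifrac.tsv", "alpha_tests.tsv")
    },
    diffabund = {
      require_files(dir, c("feature_table.tsv", "taxonomy.tsv", "metadata.tsv"),
                    stage, "simulate")
      table <- read_feature_table(file.path(dir, "feature_table.tsv"))
      tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
      meta <- read_metadata(file.path(dir, "metadata.tsv"))
      merged <- merge_to_genus(table, tax)
      ibd <- meta$group %in% c("UC", "CD")
      res <- lefse_like(unclass(merged)[meta$sample_id[ibd], , drop = FALSE],
                        droplevels(meta$group[ibd]),
                        kw_alpha = config$kw_alpha,
                        lda_threshold = config$lda_threshold, seed = seed)
      write_lefse_result(res, file.path(dir, "diffabund_uc_vs_cd.tsv"))
      "diffabund_uc_vs_cd.tsv"
    },
    classify = {
      require_files(dir, c("feature_table.tsv", "taxonomy.tsv", "metadata.tsv"),
                    stage, "simulate")
      table <- read_feature_table(file.path(dir, "feature_table.tsv"))
      tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
      meta <- read_metadata(file.path(dir, "metadata.tsv"))
      merged <- merge_to_genus(table, tax)
      ibd <- meta$group %in% c("UC", "CD")
      cv <- loocv_linear_svm(unclass(merged)[meta$sample_id[ibd], , drop = FALSE],
                             droplevels(meta$group[ibd]),
                             pseudo_count = config$pseudo_count)
      readr::write_tsv(tidy(cv), file.path(dir, "classify_predictions.tsv"),
                       progress = FALSE)
      readr::write_tsv(roc_coordinates(cv), file.path(dir, "classify_roc.tsv"),
                       progress = FALSE)
      readr::write_tsv(glance(cv), file.path(dir, "classify_summary.tsv"),
                       progress = FALSE)
      c("classify_predictions.tsv", "classify_roc.tsv", "classify_summary.tsv")
    },
    cytokines = {
      require_files(dir, c("cytokines.tsv", "metadata.tsv"), stage, "simulate")
      panel <- read_cytokine_panel(file.path(dir, "cytokines.tsv"))
      meta <- read_metadata(file.path(dir, "metadata.tsv"))
      subj <- dplyr::distinct(meta, .data$subject_id, .data$group) |>
        dplyr::mutate(group = ifelse(.data$group == "control", "control", "IBD"))
      readr::write_tsv(normality_screen(panel),
                       file.path(dir, "cytokine_normality.tsv"), progress = FALSE)
      ibd_panel <- panel[panel$subject_id %in%
                           subj$subject_id[subj$group == "IBD"], ]
      readr::write_tsv(paired_prepregnancy_tests(ibd_panel),
                       file.path(dir, "cytokine_paired_pre.tsv"),
                       progress = FALSE)
      tt <- trimester_trend_tests(ibd_panel)
      readr::write_tsv(tt$friedman, file.path(dir, "cytokine_friedman.tsv"),
                       progress = FALSE)
      readr::write_tsv(tt$dunn, file.path(dir, "cytokine_dunn.tsv"),
                       progress = FALSE)
      readr::write_tsv(between_group_tests(panel, subj),
                       file.path(dir, "cytokine_group_tests.tsv"),
                       progress = FALSE)
      c("cytokine_normality.tsv", "cytokine_paired_pre.tsv",
        "cytokine_friedman.tsv", "cytokine_dunn.tsv",
        "cytokine_group_tests.tsv")
    },
    network = {
      require_files(dir, "normalized.tsv", stage, "normalize")
      require_files(dir, c("cytokines.tsv", "metadata.tsv"), stage, "simulate")
      nz <- readr::read_tsv(file.path(dir, "normalized.tsv"),
                            col_types = readr::cols(), progress = FALSE)
      bz <- as.matrix(nz[-1]); rownames(bz) <- nz[[1]]
      meta <- read_metadata(file.path(dir, "metadata.tsv"))
      panel <- read_cytokine_panel(file.path(dir, "cytokines.tsv"))
      ibd <- meta$group %in% c("UC", "CD", "IBDU")
      tr <- build_transitions(bz[rownames(bz) %in% meta$sample_id[ibd], ,
                                 drop = FALSE], panel, meta)
      edges <- dynamic_correlations(tr)
      null <- scramble_null(tr, n_scrambles = config$n_scrambles,
                            seed = seed, threshold = config$dyn_p_threshold)
      net <- assemble_network(edges, threshold = config$dyn_p_threshold)
      write_network(net, file.path(dir, "network_edges.tsv"),
                    file.path(dir, "network.graphml"))
      readr::write_tsv(net$degrees, file.path(dir, "network_degrees.tsv"),
                       progress = FALSE)
      jsonlite::write_json(
        list(threshold = config$dyn_p_threshold,
             n_scrambles = config$n_scrambles, seed = seed,
             min_p_quantiles = as.list(null$min_p_quantiles),
             hub_bacteria = net$hub_bacteria),
        file.path(dir, "network_null_summary.json"), auto_unbox = TRUE,
        pretty = TRUE)
      c("network_edges.tsv", "network_degrees.tsv", "network.graphml",
        "network_null_summary.json")
    }
  )
}
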