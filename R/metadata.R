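# Cohort metadata, cytokine panel, and run configuration.

#' Validate per-sample cohort metadata
#'
#' @param meta Data frame with at least `sample_id`, `subject_id`,
#'   `timepoint` (one of `pre`, `T1`, `T2`, `T3`, `post`) and `group` (one of
#'   `CD`, `UC`, `IBDU`, `control`). Optional clinical columns: `flare`
#'   (logical), `medication`, `parity` (`nulliparous`/`multiparous`),
#'   `location` (`colonic`/`non_colonic`, CD only), `antibiotic` (logical),
#'   `bmi_class` (`lt25`/`ge25`). Missing values are `NA`, never sentinels.
#' @return The metadata as a tibble with `timepoint` and `group` as ordered
#'   factors; errors on contract violations.
#' @export
validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "subject_id", "timepoint", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_pb("metadata missing column(s): ",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop_pb("duplicated sample_id in metadata")
  bad_tp <- setdiff(unique(as.character(meta$timepoint)), timepoint_levels())
  if (length(bad_tp)) stop_pb("unknown timepoint(s): ",
                              paste(bad_tp, collapse = ", "))
  bad_g <- setdiff(unique(as.character(meta$group)), group_levels())
  if (length(bad_g)) stop_pb("unknown group(s): ", paste(bad_g, collapse = ", "))
  key <- paste(meta$subject_id, meta$timepoint)
  if (anyDuplicated(key)) {
    stop_pb("duplicated (subject_id, timepoint): ",
            key[duplicated(key)][1])
  }
  ctrl_extra <- meta$group == "control" & meta$timepoint %in% c("pre", "post")
  if (any(ctrl_extra)) {
    stop_pb("controls are sampled at T1-T3 only; offending sample(s): ",
            paste(meta$sample_id[ctrl_extra], collapse = ", "))
  }
  if ("location" %in% names(meta)) {
    bad_loc <- !is.na(meta$location) & meta$group != "CD"
    if (any(bad_loc)) stop_pb("disease location is defined for CD only")
  }
  meta$timepoint <- factor(meta$timepoint, levels = timepoint_levels(),
                           ordered = TRUE)
  meta$group <- factor(meta$group, levels = group_levels())
  meta
}

#' Read cohort metadata from TSV
#'
#' @param path TSV file; empty cells are missing values.
#' @return Validated metadata tibble (see [validate_metadata()]).
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        na = c("", "NA"))
  validate_metadata(df)
}

#' Validate a cytokine panel
#'
#' @param panel Data frame keyed by (`subject_id`, `timepoint`) with one
#'   column per cytokine in [cytokine_names()] (pg/mL, `NA` when a cytokine
#'   was not measured for a serum sample).
#' @return The panel as a tibble, cytokine columns in canonical order.
#' @export
validate_cytokine_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  need <- c("subject_id", "timepoint")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop_pb("cytokine panel missing column(s): ",
                            paste(miss, collapse = ", "))
  miss_cyt <- setdiff(cytokine_names(), names(panel))
  if (length(miss_cyt)) stop_pb("cytokine panel missing cytokine(s): ",
                                paste(miss_cyt, collapse = ", "))
  key <- paste(panel$subject_id, panel$timepoint)
  if (anyDuplicated(key)) stop_pb("duplicated (subject_id, timepoint) in panel")
  vals <- as.matrix(panel[cytokine_names()])
  if (any(vals < 0, na.rm = TRUE)) stop_pb("negative cytokine concentration")
  dplyr::select(panel, "subject_id", "timepoint",
                dplyr::all_of(cytokine_names()),
                dplyr::any_of("CRP"))
}

#' Read a cytokine panel from TSV
#'
#' @param path TSV file with `subject_id`, `timepoint` and the twelve
#'   cytokine columns; empty cells are missing measurements.
#' @return Validated cytokine tibble.
#' @export
read_cytokine_panel <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        na = c("", "NA"))
  validate_cytokine_panel(df)
}

#' Pipeline run configuration
#'
#' Bundles every tunable threshold with its default, so each output can
#' record the exact configuration (and seed) that produced it.
#'
#' @param rarefaction_depth Minimum and target sequence count per sample
#'   (default 5928).
#' @param pseudo_count Value added to relative abundances before log10
#'   (default 0.01).
#' @param permanova_permutations Number of label permutations (default 999).
#' @param lda_threshold Absolute log10 effect-size cutoff (default 2).
#' @param kw_alpha Kruskal-Wallis screening level (default 0.05).
#' @param dyn_p_threshold Dynamic-network edge p cutoff (default 0.01, the
#'   level suggested by the scrambled-bacteria null).
#' @param n_scrambles Number of scrambled-bacteria null replicates
#'   (default 100).
#' @param rng_seed Master seed recorded in every output.
#' @return A `run_config` list.
#' @export
run_config <- function(rarefaction_depth = 5928L, pseudo_count = 0.01,
                       permanova_permutations = 999L, lda_threshold = 2,
                       kw_alpha = 0.05, dyn_p_threshold = 0.01,
                       n_scrambles = 100L, rng_seed = 1L) {
  stopifnot(rarefaction_depth >= 1, pseudo_count > 0,
            permanova_permutations >= 1, lda_threshold >= 0,
            kw_alpha > 0, kw_alpha < 1, dyn_p_threshold > 0,
            dyn_p_threshold < 1, n_scrambles >= 1)
  structure(list(rarefaction_depth = as.integer(rarefaction_depth),
                 pseudo_count = pseudo_count,
                 permanova_permutations = as.integer(permanova_permutations),
                 lda_threshold = lda_threshold, kw_alpha = kw_alpha,
                 dyn_p_threshold = dyn_p_threshold,
                 n_scrambles = as.integer(n_scrambles),
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}
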