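# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: a pregnancy
# cohort of CD, UC and control subjects sampled longitudinally, with
# Dirichlet-multinomial genus counts (lower Dirichlet concentration in the
# IBD arm, giving lower richness and evenness), a UC/CD compositional offset
# that shrinks after the first trimester, a flare-associated genus, a parity
# effect on a disjoint genus set, a random coalescent genus tree, log-normal
# cytokine trajectories with the group/time structure the statistics are
# meant to detect, and optional planted dynamic couplings with a
# ground-truth edge list. Effect sizes live in the returned ground truth;
# no analysis stage reads them.

#' Specification of a synthetic cohort
#'
#' Defaults mirror the study design: 31 CD + 15 UC + 179 controls; IBD
#' subjects sampled at up to five timepoints (pre, T1-T3, post), controls at
#' T1-T3; sequencing depth uniform over a range straddling the 5928-read
#' filter.
#'
#' @param n_cd,n_uc,n_control Subjects per group.
#' @param n_genera Number of genera (default 40).
#' @param depth_range Uniform range of per-sample sequencing depth.
#' @param missingness Probability an IBD subject misses any given timepoint.
#' @param ibd_concentration,control_concentration Dirichlet concentration
#'   scales; the lower IBD value yields lower alpha diversity.
#' @param group_offset Log-scale UC-vs-CD offset on the designated genera.
#' @param group_time_shrink Multiplier applied to the UC/CD offset after T1
#'   (default 0.25: the disease-type difference attenuates in mid/late
#'   pregnancy).
#' @param n_group_genera Number of genera carrying the UC/CD offset.
#' @param flare_offset Log-scale enrichment of the flare-associated genus.
#' @param flare_rate Per-(subject, pregnancy timepoint) flare probability in
#'   IBD.
#' @param parity_offset Log-scale effect of multiparity on its genus set.
#' @param n_parity_genera Number of genera carrying the parity effect.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cd = 31L, n_uc = 15L, n_control = 179L,
                        n_genera = 40L, depth_range = c(3000L, 20000L),
                        missingness = 0.2,
                        ibd_concentration = 15, control_concentration = 50,
                        group_offset = 1, group_time_shrink = 0.25,
                        n_group_genera = 5L,
                        flare_offset = 1, flare_rate = 0.15,
                        parity_offset = 0.8, n_parity_genera = 3L,
                        seed = 1L) {
  stopifnot(n_cd >= 0, n_uc >= 0, n_control >= 0, n_genera >= 10,
            missingness >= 0, missingness < 1, depth_range[1] >= 1,
            diff(depth_range) >= 0)
  if (n_genera < n_group_genera + n_parity_genera + 1) {
    stop_pb("n_genera too small for the planted-effect genus sets")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

genus_ids <- function(n) sprintf("Genus%02d", seq_len(n))

#' Generate a synthetic microbiome cohort
#'
#' @param spec A [cohort_spec()].
#' @return List with `table` (counts `feature_table`; a couple of genera are
#'   represented by two features each so genus merging is exercised),
#'   `taxonomy`, `tree` (random coalescent over genera), `meta` (validated
#'   metadata) and `truth` (planted effect bookkeeping: genus sets, offsets,
#'   concentrations).
#' @export
generate_microbiome <- function(spec) {
  with_seed(derive_seed(spec$seed, "microbiome"), {
    g <- genus_ids(spec$n_genera)
    base_log <- stats::rnorm(spec$n_genera, mean = 0, sd = 1.2)
    names(base_log) <- g
    grp_gen <- g[seq_len(spec$n_group_genera)]
    flare_gen <- g[spec$n_group_genera + 1]
    par_gen <- g[spec$n_group_genera + 1 + seq_len(spec$n_parity_genera)]

    subjects <- tibble::tibble(
      subject_id = c(sprintf("CD%03d", seq_len(spec$n_cd)),
                     sprintf("UC%03d", seq_len(spec$n_uc)),
                     sprintf("HC%03d", seq_len(spec$n_control))),
      group = c(rep("CD", spec$n_cd), rep("UC", spec$n_uc),
                rep("control", spec$n_control))
    )
    subjects$parity <- ifelse(
      stats::runif(nrow(subjects)) <
        ifelse(subjects$group == "control", 0.38, 0.80),
      "nulliparous", "multiparous")
    subjects$location <- ifelse(
      subjects$group == "CD",
      ifelse(stats::runif(nrow(subjects)) < 0.3, "colonic", "non_colonic"),
      NA_character_)

    rows <- list()
    for (i in seq_len(nrow(subjects))) {
      s <- subjects[i, ]
      tps <- if (s$group == "control") c("T1", "T2", "T3") else {
        tp <- timepoint_levels()
        keep <- stats::runif(5) >= spec$missingness
        if (!any(keep)) keep[sample.int(5, 1)] <- TRUE
        tp[keep]
      }
      for (tp in tps) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = paste0(s$subject_id, "_", tp),
          subject_id = s$subject_id, timepoint = tp, group = s$group,
          flare = if (s$group == "control") NA else
            tp %in% c("T1", "T2", "T3") &&
            stats::runif(1) < spec$flare_rate,
          medication = if (s$group == "control") NA_character_ else
            sample(c("none", "5ASA", "immunosuppressant", "biological"), 1),
          parity = s$parity, location = s$location,
          antibiotic = stats::runif(1) < 0.03,
          bmi_class = sample(c("lt25", "ge25"), 1)
        )
      }
    }
    meta <- validate_metadata(dplyr::bind_rows(rows))

    depth <- sample(seq(spec$depth_range[1], spec$depth_range[2]),
                    nrow(meta), replace = TRUE)
    counts <- matrix(0L, nrow(meta), spec$n_genera,
                     dimnames = list(meta$sample_id, g))
    tp_num <- match(as.character(meta$timepoint), timepoint_levels())
    for (i in seq_len(nrow(meta))) {
      lo <- base_log
      shrink <- if (tp_num[i] > 2) spec$group_time_shrink else 1
      if (meta$group[i] == "UC") lo[grp_gen] <- lo[grp_gen] +
          shrink * spec$group_offset
      if (meta$group[i] == "CD") lo[grp_gen] <- lo[grp_gen] -
          shrink * spec$group_offset
      if (isTRUE(meta$flare[i])) lo[flare_gen] <- lo[flare_gen] +
          spec$flare_offset
      if (identical(meta$parity[i], "multiparous")) lo[par_gen] <-
          lo[par_gen] + spec$parity_offset
      conc <- if (meta$group[i] == "control") spec$control_concentration else
        spec$ibd_concentration
      alpha <- conc * exp(lo) / sum(exp(lo))
      p <- stats::rgamma(spec$n_genera, shape = alpha)
      p <- p / sum(p)
      counts[i, ] <- stats::rmultinom(1, size = depth[i], prob = p)[, 1]
    }
    # split the two most abundant genera into two features each so the
    # genus merge has something to do
    split_gen <- names(sort(colSums(counts), decreasing = TRUE))[1:2]
    feat_cols <- list(); feat_tax <- list()
    for (gn in colnames(counts)) {
      if (gn %in% split_gen) {
        a <- vapply(counts[, gn], function(n) stats::rbinom(1, n, 0.5),
                    integer(1))
        feat_cols[[paste0(gn, "_f1")]] <- a
        feat_cols[[paste0(gn, "_f2")]] <- counts[, gn] - a
        feat_tax[[paste0(gn, "_f1")]] <- gn
        feat_tax[[paste0(gn, "_f2")]] <- gn
      } else {
        feat_cols[[paste0(gn, "_f1")]] <- counts[, gn]
        feat_tax[[paste0(gn, "_f1")]] <- gn
      }
    }
    values <- do.call(cbind, feat_cols)
    rownames(values) <- rownames(counts)
    table <- feature_table(values, unit = "counts")
    taxonomy <- parse_taxonomy(
      names(feat_tax),
      sprintf("k__Bacteria;p__Phylum1;c__Class1;o__Order1;f__Family%02d;g__%s",
              match(unlist(feat_tax), g) %% 7 + 1, unlist(feat_tax))
    )
    # taxonomy genus labels carry the g__ prefix; trees index raw features
    tree <- ape::rcoal(length(feat_tax), tip.label = names(feat_tax))
    tree$edge.length <- stats::rexp(length(tree$edge.length), rate = 2)

    list(table = table, taxonomy = taxonomy, tree = tree, meta = meta,
         truth = list(group_genera = grp_gen, flare_genus = flare_gen,
                      parity_genera = par_gen,
                      group_offset = spec$group_offset,
                      group_time_shrink = spec$group_time_shrink,
                      ibd_concentration = spec$ibd_concentration,
                      control_concentration = spec$control_concentration))
  })
}

#' Generate synthetic serum cytokine trajectories
#'
#' Log-normal concentrations with: a prepregnancy elevation of the
#' proinflammatory members (IL-6, IL-8, IL-12, IL-17, TNF-alpha) in IBD that
#' drops at conception; a control-only linear trimester rise in IL-6 and
#' IL-10; IBD-vs-control offsets on IL-5 (down), IL-10 (down), IL-8 (up) and
#' IFN-gamma (up); a subject-level random effect; and per-(subject,
#' cytokine) missingness.
#'
#' @param spec A [cohort_spec()].
#' @param meta Metadata from [generate_microbiome()] (or any validated
#'   metadata).
#' @param conception_drop Log-scale size of the IBD prepregnancy-to-T1 drop.
#' @param trend Per-trimester log-scale control rise of IL-6/IL-10.
#' @param group_shift Log-scale IBD-vs-control offset magnitude.
#' @param cytokine_missingness Probability a (serum sample, cytokine) value
#'   is unmeasured.
#' @return List with `panel` (validated cytokine tibble, one row per
#'   (subject, timepoint) present in `meta`) and `truth`.
#' @export
generate_cytokines <- function(spec, meta, conception_drop = 0.7,
                               trend = 0.25, group_shift = 0.5,
                               cytokine_missingness = 0.1) {
  with_seed(derive_seed(spec$seed, "cytokines"), {
    cyts <- cytokine_names()
    proinf <- c("IL6", "IL8", "IL12", "IL17", "TNFa")
    trended <- c("IL6", "IL10")
    up_in_ibd <- c("IL8", "IFNg"); down_in_ibd <- c("IL5", "IL10")
    mu <- stats::setNames(stats::rnorm(length(cyts), mean = 2, sd = 0.4), cyts)

    subjects <- unique(meta$subject_id)
    subj_re <- stats::setNames(stats::rnorm(length(subjects), 0, 0.4), subjects)
    tp_num <- match(as.character(meta$timepoint), timepoint_levels())

    rows <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
      ibd <- meta$group[i] != "control"
      lv <- mu + subj_re[[meta$subject_id[i]]]
      if (ibd && tp_num[i] == 1) lv[proinf] <- lv[proinf] + conception_drop
      if (!ibd) lv[trended] <- lv[trended] + trend * (tp_num[i] - 2)
      if (ibd) {
        lv[up_in_ibd] <- lv[up_in_ibd] + group_shift
        lv[down_in_ibd] <- lv[down_in_ibd] - group_shift
      }
      conc <- exp(lv + stats::rnorm(length(cyts), 0, 0.3))
      conc[stats::runif(length(cyts)) < cytokine_missingness] <- NA
      tibble::as_tibble(as.list(conc)) |>
        dplyr::mutate(subject_id = meta$subject_id[i],
                      timepoint = as.character(meta$timepoint[i]),
                      .before = 1)
    })
    list(panel = validate_cytokine_panel(rows),
         truth = list(proinflammatory = proinf, trended = trended,
                      up_in_ibd = up_in_ibd, down_in_ibd = down_in_ibd,
                      conception_drop = conception_drop, trend = trend,
                      group_shift = group_shift))
  })
}

#' Plant dynamic couplings into analysis-scale trajectories
#'
#' For each requested edge, the target's trajectory is rewritten along every
#' subject's observed timepoint sequence:
#' `target(t+1) = target(t) + beta * source(t) + noise`, on the analysis
#' scales (bacteria: normalised log z-scores; cytokines: pg/mL). The
#' returned ground truth is what recovery tests compare against; nothing
#' else may read it.
#'
#' @param bacteria Samples x genera matrix of analysis-scale values with
#'   sample-id rownames.
#' @param panel Cytokine panel tibble (or `NULL` if only bacterial edges are
#'   planted).
#' @param meta Validated metadata covering the bacteria rows.
#' @param edges Tibble with `source`, `target`, `family` (one of the three
#'   families), `beta`.
#' @param noise_sd Innovation SD on the target's scale (default 0.5).
#' @param seed Integer seed.
#' @return List with modified `bacteria`, `panel`, and `truth` (the planted
#'   edge tibble).
#' @export
plant_dynamic_couplings <- function(bacteria, panel, meta, edges,
                                    noise_sd = 0.5, seed = 1L) {
  bad <- edges$source[edges$family != "cyt_to_dbact" &
                        !(edges$source %in% colnames(bacteria))]
  bad <- c(bad, edges$target[edges$family != "bact_to_dcyt" &
                               !(edges$target %in% colnames(bacteria))])
  if (length(bad)) stop_pb("planted coupling on absent genus: ",
                           paste(unique(bad), collapse = ", "))
  meta <- tibble::as_tibble(meta)
  with_seed(seed, {
    pm <- NULL
    if (!is.null(panel)) {
      pm <- panel_matrix(panel)
      pkey <- paste(panel$subject_id, panel$timepoint, sep = "@")
    }
    ord <- match(as.character(meta$timepoint), timepoint_levels())
    for (sj in unique(meta$subject_id)) {
      mi <- meta[meta$subject_id == sj, ]
      mi <- mi[order(ord[match(mi$sample_id, meta$sample_id)]), ]
      if (nrow(mi) < 2) next
      for (i in seq_len(nrow(mi) - 1)) {
        s1 <- mi$sample_id[i]; s2 <- mi$sample_id[i + 1]
        k1 <- if (is.null(pm)) NA else
          match(paste(sj, mi$timepoint[i], sep = "@"), pkey)
        k2 <- if (is.null(pm)) NA else
          match(paste(sj, mi$timepoint[i + 1], sep = "@"), pkey)
        # read all sources at the pre-update state, then apply the summed
        # increment per target, so edges sharing a target accumulate
        bact_inc <- numeric(0); cyt_inc <- numeric(0)
        for (e in seq_len(nrow(edges))) {
          src_val <- switch(edges$family[e],
            cyt_to_dbact = if (!is.na(k1)) pm[k1, edges$source[e]] else NA,
            bacteria[s1, edges$source[e]])
          if (is.na(src_val)) next
          inc <- edges$beta[e] * src_val + stats::rnorm(1, 0, noise_sd)
          tgt <- edges$target[e]
          if (edges$family[e] == "bact_to_dcyt") {
            cyt_inc[tgt] <- (if (tgt %in% names(cyt_inc)) cyt_inc[[tgt]] else 0) + inc
          } else {
            bact_inc[tgt] <- (if (tgt %in% names(bact_inc)) bact_inc[[tgt]] else 0) + inc
          }
        }
        for (tgt in names(bact_inc)) {
          bacteria[s2, tgt] <- bacteria[s1, tgt] + bact_inc[[tgt]]
        }
        if (!is.na(k1) && !is.na(k2)) {
          for (tgt in names(cyt_inc)) {
            pm[k2, tgt] <- max(0, pm[k1, tgt] + cyt_inc[[tgt]])
          }
        }
      }
    }
    if (!is.null(pm)) {
      panel[, colnames(pm)] <- pm
    }
    list(bacteria = bacteria, panel = panel,
         truth = edges[edges$beta != 0, , drop = FALSE])
  })
}
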