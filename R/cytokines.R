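# Serum cytokine panel statistics: paired prepregnancy-vs-trimester Wilcoxon
# tests, Friedman trend tests with Dunn post hoc comparisons, per-trimester
# Mann-Whitney group comparisons, Shapiro-Wilk normality screening, PCA with
# SVD imputation and prediction ellipses, and a clustered heatmap matrix.
#
# All hypothesis tests are nonparametric by design: normality is screened
# and logged, but never switches the tests (serum cytokine concentrations
# are heavily skewed and the panel is analysed uniformly).

panel_matrix <- function(panel, cytokines = cytokine_names()) {
  m <- as.matrix(panel[cytokines])
  rownames(m) <- paste(panel$subject_id, panel$timepoint, sep = "@")
  m
}

#' Shapiro-Wilk normality screen per cytokine
#'
#' Computed and logged for transparency; the downstream tests stay
#' nonparametric regardless of the outcome.
#'
#' @param panel Validated cytokine panel.
#' @return Tibble with `cytokine`, `n`, `W`, `p`, `normal_at_0.05`.
#' @export
normality_screen <- function(panel) {
  purrr::map_dfr(cytokine_names(), function(cy) {
    x <- panel[[cy]]
    x <- x[!is.na(x)]
    if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000) {
      return(tibble::tibble(cytokine = cy, n = length(x), W = NA_real_,
                            p = NA_real_, normal_at_0.05 = NA))
    }
    sw <- stats::shapiro.test(x)
    tibble::tibble(cytokine = cy, n = length(x), W = unname(sw$statistic),
                   p = sw$p.value, normal_at_0.05 = sw$p.value >= 0.05)
  })
}

#' Paired prepregnancy-versus-trimester Wilcoxon tests
#'
#' For each cytokine and each trimester, a Wilcoxon matched-pairs signed-rank
#' test compares the prepregnancy level with the trimester level over
#' subjects with both measurements. Zero differences are dropped (the
#' classical Wilcoxon convention); the exact null distribution is used for
#' small samples without ties, a normal approximation with continuity
#' correction otherwise. Contrasts with fewer than two complete pairs are
#' flagged as skipped.
#'
#' @param panel Validated cytokine panel including `pre` rows.
#' @param trimesters Timepoints compared against `pre`.
#' @return Tibble with `cytokine`, `contrast`, `test`, `n_pairs`,
#'   `statistic`, `p`, `skipped`.
#' @export
paired_prepregnancy_tests <- function(panel, trimesters = c("T1", "T2", "T3")) {
  purrr::map_dfr(cytokine_names(), function(cy) {
    purrr::map_dfr(trimesters, function(tp) {
      pre <- panel[panel$timepoint == "pre", c("subject_id", cy)]
      tri <- panel[panel$timepoint == tp, c("subject_id", cy)]
      m <- dplyr::inner_join(pre, tri, by = "subject_id",
                             suffix = c("_pre", "_tri"))
      m <- m[stats::complete.cases(m), ]
      base <- tibble::tibble(cytokine = cy,
                             contrast = paste0("pre_vs_", tp),
                             test = "wilcoxon_signed_rank",
                             n_pairs = nrow(m))
      if (nrow(m) < 2) {
        return(dplyr::mutate(base, statistic = NA_real_, p = NA_real_,
                             skipped = TRUE))
      }
      if (all(m[[2]] == m[[3]])) {
        # every difference is zero: nothing to rank, no evidence of change
        return(dplyr::mutate(base, statistic = 0, p = 1, skipped = FALSE))
      }
      wt <- suppressWarnings(
        stats::wilcox.test(m[[2]], m[[3]], paired = TRUE,
                           exact = nrow(m) <= 25, correct = TRUE)
      )
      dplyr::mutate(base, statistic = unname(wt$statistic), p = wt$p.value,
                    skipped = FALSE)
    })
  })
}

#' Friedman trimester-trend tests with Dunn post hoc comparisons
#'
#' Subjects with all three trimester measurements of a cytokine form a
#' randomised complete block design; the Friedman rank test asks whether the
#' cytokine changes across T1-T3. When the Friedman p is below `alpha`,
#' Dunn's pairwise z-tests on the rank sums follow, Bonferroni-adjusted over
#' the three trimester pairs.
#'
#' @param panel Validated cytokine panel.
#' @param trimesters The within-subject conditions (default T1-T3).
#' @param alpha Gate for running the post hoc tests (default 0.05).
#' @param p_adjust Multiplicity adjustment over pairs (default
#'   `"bonferroni"`).
#' @return List of tibbles: `friedman` (`cytokine`, `n_subjects`,
#'   `chi_squared`, `df`, `p`, `skipped`) and `dunn` (`cytokine`,
#'   `comparison`, `z`, `p_adjusted`).
#' @export
trimester_trend_tests <- function(panel, trimesters = c("T1", "T2", "T3"),
                                  alpha = 0.05, p_adjust = "bonferroni") {
  k <- length(trimesters)
  fried <- list(); dunn <- list()
  for (cy in cytokine_names()) {
    wide <- panel[panel$timepoint %in% trimesters,
                  c("subject_id", "timepoint", cy)] |>
      tidyr::pivot_wider(names_from = "timepoint", values_from = dplyr::all_of(cy))
    wide <- wide[stats::complete.cases(wide[trimesters]), ]
    n <- nrow(wide)
    if (n < 3) {
      fried[[cy]] <- tibble::tibble(cytokine = cy, n_subjects = n,
                                    chi_squared = NA_real_, df = k - 1L,
                                    p = NA_real_, skipped = TRUE)
      next
    }
    y <- as.matrix(wide[trimesters])
    if (all(apply(y, 1, function(v) length(unique(v)) == 1))) {
      # all ranks tied within every subject: no trend information
      fried[[cy]] <- tibble::tibble(cytokine = cy, n_subjects = n,
                                    chi_squared = 0, df = k - 1L, p = 1,
                                    skipped = FALSE)
      next
    }
    ft <- stats::friedman.test(y)
    fried[[cy]] <- tibble::tibble(cytokine = cy, n_subjects = n,
                                  chi_squared = unname(ft$statistic),
                                  df = unname(ft$parameter), p = ft$p.value,
                                  skipped = FALSE)
    if (!is.na(ft$p.value) && ft$p.value < alpha) {
      ranks <- t(apply(y, 1, rank))
      rbar <- colMeans(ranks)
      se <- sqrt(k * (k + 1) / (6 * n))
      pairs <- utils::combn(seq_len(k), 2)
      z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
      praw <- 2 * stats::pnorm(-abs(z))
      dunn[[cy]] <- tibble::tibble(
        cytokine = cy,
        comparison = paste(trimesters[pairs[1, ]], trimesters[pairs[2, ]],
                           sep = "_vs_"),
        z = unname(z),
        p_adjusted = pmin(1, stats::p.adjust(praw, method = p_adjust))
      )
    }
  }
  list(friedman = dplyr::bind_rows(fried),
       dunn = if (length(dunn)) dplyr::bind_rows(dunn) else
         tibble::tibble(cytokine = character(), comparison = character(),
                        z = numeric(), p_adjusted = numeric()))
}

#' Per-timepoint between-group Mann-Whitney tests
#'
#' For each cytokine and each timepoint, a two-sided Mann-Whitney U test
#' (midrank ties) compares the two groups (e.g. IBD versus control, or UC
#' versus CD). Timepoints where either group has fewer than two measured
#' subjects are flagged as skipped.
#'
#' @param panel Validated cytokine panel.
#' @param subject_groups Tibble with `subject_id` and `group` (two levels
#'   among the subjects present).
#' @param timepoints Timepoints to test (default T1-T3).
#' @return Tibble with `cytokine`, `timepoint`, `test`, `n1`, `n2`,
#'   `statistic`, `p`, `skipped`.
#' @export
between_group_tests <- function(panel, subject_groups,
                                timepoints = c("T1", "T2", "T3")) {
  df <- dplyr::inner_join(panel, subject_groups, by = "subject_id")
  lev <- unique(as.character(df$group))
  if (length(lev) != 2) stop_pb("exactly two groups required, got: ",
                                paste(lev, collapse = ", "))
  purrr::map_dfr(cytokine_names(), function(cy) {
    purrr::map_dfr(timepoints, function(tp) {
      sub <- df[df$timepoint == tp & !is.na(df[[cy]]), ]
      x1 <- sub[[cy]][sub$group == lev[1]]
      x2 <- sub[[cy]][sub$group == lev[2]]
      base <- tibble::tibble(cytokine = cy, timepoint = tp,
                             test = "mann_whitney",
                             n1 = length(x1), n2 = length(x2))
      if (length(x1) < 2 || length(x2) < 2) {
        return(dplyr::mutate(base, statistic = NA_real_, p = NA_real_,
                             skipped = TRUE))
      }
      wt <- suppressWarnings(
        stats::wilcox.test(x1, x2, exact = max(length(x1), length(x2)) <= 25,
                           correct = TRUE)
      )
      dplyr::mutate(base, statistic = unname(wt$statistic), p = wt$p.value,
                    skipped = FALSE)
    })
  })
}

# Iterative low-rank SVD imputation on a column-scaled matrix: missing
# entries start at 0 (the column mean after scaling) and are refined by
# repeated rank-k reconstruction until the filled values stabilise.
svd_impute <- function(m, rank, tol = 1e-6, max_iter = 100L) {
  miss <- is.na(m)
  if (!any(miss)) return(list(filled = m, iterations = 0L))
  filled <- m
  filled[miss] <- 0
  for (it in seq_len(max_iter)) {
    sv <- svd(filled)
    k <- min(rank, length(sv$d))
    rec <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], k) %*% t(sv$v[, seq_len(k), drop = FALSE])
    delta <- max(abs(rec[miss] - filled[miss]))
    filled[miss] <- rec[miss]
    if (delta < tol) break
  }
  list(filled = filled, iterations = it)
}

#' Cytokine panel PCA with SVD imputation and prediction ellipses
#'
#' Each cytokine is unit-variance scaled (centred, divided by SD); missing
#' entries are imputed by iterative low-rank SVD (rank = number of
#' components, tolerance 1e-6, at most 100 iterations); principal components
#' come from the singular value decomposition of the completed matrix. For
#' each group a 95% prediction ellipse is fitted on the first two scores
#' from the group mean and covariance with chi-squared(2) radius, i.e. the
#' region in which a new observation from that group falls with probability
#' 0.95 under a Gaussian model.
#'
#' @param panel Validated cytokine panel (rows = serum samples).
#' @param grouping Vector aligned with the rows of `panel` (e.g. disease
#'   group); used for the ellipses only.
#' @param n_components Number of components to keep (default 2).
#' @param max_missing Cytokines missing in more than this fraction of rows
#'   are excluded with a warning (default 0.5).
#' @return A `panel_pca` list: `scores` tibble (`subject_id`, `timepoint`,
#'   `group`, `PC1`, ...), `explained_variance` fractions, `ellipses` tibble
#'   (`group`, `center_x`, `center_y`, `semi_major`, `semi_minor`,
#'   `angle_rad`, `coverage`), `imputation_iterations`,
#'   `cytokines_used`.
#' @export
panel_pca <- function(panel, grouping, n_components = 2, max_missing = 0.5) {
  m <- panel_matrix(panel)
  frac_na <- colMeans(is.na(m))
  drop <- frac_na > max_missing
  if (any(drop)) {
    warn_pb("excluding cytokine(s) missing in >", 100 * max_missing, "% of ",
            "samples: ", paste(colnames(m)[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
  }
  keep_rows <- rowSums(!is.na(m)) >= 2
  m <- m[keep_rows, , drop = FALSE]
  g <- as.factor(grouping)[keep_rows]
  if (nrow(m) < 3 || ncol(m) < 2) stop_pb("need >= 3 samples and >= 2 cytokines")
  sc <- scale(m)
  imp <- svd_impute(sc, rank = n_components)
  sv <- svd(imp$filled)
  k <- min(n_components, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  expl <- sv$d^2 / sum(sv$d^2)

  st <- tibble::as_tibble(scores)
  st$subject_id <- panel$subject_id[keep_rows]
  st$timepoint <- as.character(panel$timepoint[keep_rows])
  st$group <- as.character(g)
  st <- dplyr::relocate(st, "subject_id", "timepoint", "group")

  r2 <- stats::qchisq(0.95, df = 2)
  ellipses <- purrr::map_dfr(levels(droplevels(g)), function(lv) {
    xy <- scores[g == lv, 1:2, drop = FALSE]
    if (nrow(xy) < 3) {
      return(tibble::tibble(group = lv, center_x = NA_real_,
                            center_y = NA_real_, semi_major = NA_real_,
                            semi_minor = NA_real_, angle_rad = NA_real_,
                            coverage = 0.95))
    }
    ctr <- colMeans(xy)
    cv <- stats::cov(xy)
    ev <- eigen(cv, symmetric = TRUE)
    tibble::tibble(group = lv, center_x = ctr[1], center_y = ctr[2],
                   semi_major = sqrt(r2 * ev$values[1]),
                   semi_minor = sqrt(r2 * pmax(ev$values[2], 0)),
                   angle_rad = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
                   coverage = 0.95)
  })
  out <- list(scores = st,
              explained_variance = expl[seq_len(k)],
              ellipses = ellipses,
              imputation_iterations = imp$iterations,
              cytokines_used = colnames(m))
  class(out) <- "panel_pca"
  out
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("<panel_pca> ", nrow(x$scores), " samples, ",
      length(x$cytokines_used), " cytokines; PC1 ",
      round(100 * x$explained_variance[1], 1), "%, PC2 ",
      round(100 * x$explained_variance[2], 1), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.panel_pca <- function(x, ...) x$scores

#' @export
glance.panel_pca <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores),
                 n_cytokines = length(x$cytokines_used),
                 pc1_variance = x$explained_variance[1],
                 pc2_variance = x$explained_variance[2],
                 imputation_iterations = x$imputation_iterations)
}

#' Score plot with group prediction ellipses
#'
#' @param object A `panel_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panel_pca <- function(object, ...) {
  ell <- object$ellipses[!is.na(object$ellipses$center_x), ]
  theta <- seq(0, 2 * pi, length.out = 181)
  ring <- purrr::map_dfr(seq_len(nrow(ell)), function(i) {
    e <- ell[i, ]
    x0 <- e$semi_major * cos(theta); y0 <- e$semi_minor * sin(theta)
    tibble::tibble(group = e$group,
                   PC1 = e$center_x + x0 * cos(e$angle_rad) -
                     y0 * sin(e$angle_rad),
                   PC2 = e$center_y + x0 * sin(e$angle_rad) +
                     y0 * cos(e$angle_rad))
  })
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(data = ring, ggplot2::aes(group = .data$group)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2])
    ) +
    ggplot2::theme_minimal()
}

#' Clustered heatmap matrix of cytokine medians
#'
#' Per-cytokine medians by timepoint, min-max scaled within each cytokine to
#' `[0, 1]` (the colour-gradient convention: 0 = lowest median during the
#' study, 1 = highest), plus average-linkage hierarchical clustering
#' (Euclidean) of the serum samples on the scaled panel for patient-level
#' clustering. Clustering is skipped when the matrix is constant.
#'
#' @param panel Validated cytokine panel.
#' @return List with `medians` (cytokines x timepoints), `scaled` (min-max
#'   per cytokine), and `sample_clustering` (an `hclust` or `NULL`).
#' @export
heatmap_matrix <- function(panel) {
  tps <- intersect(timepoint_levels(), unique(as.character(panel$timepoint)))
  med <- sapply(tps, function(tp) {
    apply(panel[panel$timepoint == tp, cytokine_names()], 2,
          stats::median, na.rm = TRUE)
  })
  med <- matrix(med, nrow = length(cytokine_names()),
                dimnames = list(cytokine_names(), tps))
  rng <- apply(med, 1, function(v) diff(range(v, na.rm = TRUE)))
  scaled <- med
  for (i in seq_len(nrow(med))) {
    r <- range(med[i, ], na.rm = TRUE)
    scaled[i, ] <- if (diff(r) == 0) 0.5 else (med[i, ] - r[1]) / diff(r)
  }

  m <- panel_matrix(panel)
  complete <- m[stats::complete.cases(m), , drop = FALSE]
  cl <- NULL
  if (nrow(complete) >= 3 && stats::sd(as.vector(complete)) > 0) {
    z <- scale(complete)
    z[, apply(complete, 2, stats::sd) == 0] <- 0
    cl <- stats::hclust(stats::dist(z), method = "average")
  }
  list(medians = med, scaled = scaled, sample_clustering = cl,
       constant_rows = names(rng)[rng == 0])
}
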