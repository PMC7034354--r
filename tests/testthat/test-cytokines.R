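make_panel <- function(values_by_tp, subjects = NULL) {
  # values_by_tp: named list timepoint -> subjects x cytokine-values matrix
  rows <- purrr::map_dfr(names(values_by_tp), function(tp) {
    m <- values_by_tp[[tp]]
    df <- tibble::as_tibble(m)
    df$subject_id <- subjects %||% sprintf("p%02d", seq_len(nrow(m)))
    df$timepoint <- tp
    df
  })
  for (cy in setdiff(cytokine_names(), names(rows))) rows[[cy]] <- NA_real_
  validate_cytokine_panel(rows)
}

test_that("paired prepregnancy tests: identity gives p=1, uniform drop gives the exact floor", {
  set.seed(101)
  v <- matrix(stats::rlnorm(16, 2, 0.5), 16, 1, dimnames = list(NULL, "IL6"))
  panel <- make_panel(list(pre = v, T1 = v))
  res <- paired_prepregnancy_tests(panel, trimesters = "T1")
  r6 <- res[res$cytokine == "IL6", ]
  expect_equal(r6$p, 1)
  expect_equal(r6$n_pairs, 16)

  # every one of 16 pairs decreases: the minimal attainable two-sided
  # signed-rank p is 2 / 2^16
  panel2 <- make_panel(list(pre = v, T1 = v * 0.5))
  r2 <- paired_prepregnancy_tests(panel2, trimesters = "T1")
  expect_equal(r2$p[r2$cytokine == "IL6"], 2 / 2^16, tolerance = 1e-12)
})

test_that("paired tests use complete pairs only and flag tiny ones", {
  v_pre <- matrix(c(1, 2, 3, NA), 4, 1, dimnames = list(NULL, "IL8"))
  v_t1 <- matrix(c(2, NA, 5, 7), 4, 1, dimnames = list(NULL, "IL8"))
  panel <- make_panel(list(pre = v_pre, T1 = v_t1))
  res <- paired_prepregnancy_tests(panel, trimesters = "T1")
  expect_equal(res$n_pairs[res$cytokine == "IL8"], 2)
  expect_true(all(res$skipped[res$cytokine == "IL4"]))   # all-missing cytokine
})

test_that("planted paired decreases are detected with good power", {
  detected <- vapply(1:60, function(s) {
    set.seed(s)
    pre <- stats::rlnorm(16, 3, 0.3)
    # paired differences ~ N(3, 3): a 1-SD shift in the difference scale
    t1 <- pmax(pre - stats::rnorm(16, 3, 3), 0.01)
    panel <- make_panel(list(pre = cbind(IL6 = pre), T1 = cbind(IL6 = t1)))
    res <- paired_prepregnancy_tests(panel, trimesters = "T1")
    res$p[res$cytokine == "IL6"] < 0.05
  }, logical(1))
  expect_gt(mean(detected), 0.8)
})

test_that("Friedman matches the closed-form rank statistic and gates Dunn", {
  # strictly increasing in every subject: ranks are 1,2,3 everywhere, so
  # chi^2 = 12n/(k(k+1)) * sum((rbar - 2)^2) = 10 * 2 = 20 at n=10, k=3
  base <- matrix(stats::rlnorm(10, 2, 0.3), 10, 1, dimnames = list(NULL, "IL12"))
  panel <- make_panel(list(T1 = base, T2 = base * 2, T3 = base * 4))
  res <- trimester_trend_tests(panel)
  r <- res$friedman[res$friedman$cytokine == "IL12", ]
  expect_equal(r$chi_squared, 20)
  expect_equal(r$df, 2)
  dn <- res$dunn[res$dunn$cytokine == "IL12", ]
  expect_equal(nrow(dn), 3)
  expect_true(all(dn$p_adjusted <= 1))
  # monotone increase: T1-vs-T3 is the extreme comparison
  expect_equal(dn$comparison[which.max(abs(dn$z))], "T1_vs_T3")

  # identical values across trimesters: all ties, p = 1
  panel_tie <- make_panel(list(T1 = base, T2 = base, T3 = base))
  res_tie <- trimester_trend_tests(panel_tie)
  expect_equal(res_tie$friedman$p[res_tie$friedman$cytokine == "IL12"], 1)
})

test_that("incomplete trimester triplets are excluded and tiny designs skipped", {
  base <- matrix(stats::rlnorm(5, 2, 0.3), 5, 1, dimnames = list(NULL, "IL4"))
  t2 <- base; t2[1:3] <- NA
  panel <- make_panel(list(T1 = base, T2 = t2, T3 = base))
  res <- trimester_trend_tests(panel)
  r <- res$friedman[res$friedman$cytokine == "IL4", ]
  expect_equal(r$n_subjects, 2)
  expect_true(r$skipped)
})

test_that("between-group Mann-Whitney hits the exact floor on disjoint supports", {
  g1 <- matrix(stats::runif(10, 0, 1), 10, 1, dimnames = list(NULL, "IL5"))
  g2 <- matrix(stats::runif(10, 10, 11), 10, 1, dimnames = list(NULL, "IL5"))
  panel <- make_panel(list(T1 = rbind(g1, g2)))
  groups <- tibble::tibble(subject_id = sprintf("p%02d", 1:20),
                           group = rep(c("IBD", "control"), each = 10))
  res <- between_group_tests(panel, groups, timepoints = "T1")
  r <- res[res$cytokine == "IL5", ]
  # exact two-sided minimum for U = 0 at n = 10/10
  expect_equal(r$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_false(r$skipped)
  # identical groups give p near 1
  panel_eq <- make_panel(list(T1 = rbind(g1, g1)))
  res_eq <- between_group_tests(panel_eq, groups, timepoints = "T1")
  expect_gte(res_eq$p[res_eq$cytokine == "IL5"], 0.95)
})

test_that("normality screening is logged but never gates the tests", {
  set.seed(111)
  v <- matrix(stats::rlnorm(40, 2, 1), 40, 1, dimnames = list(NULL, "IL17"))
  panel <- make_panel(list(T1 = v))
  ns <- normality_screen(panel)
  expect_true(all(c("W", "p", "normal_at_0.05") %in% names(ns)))
  expect_false(ns$normal_at_0.05[ns$cytokine == "IL17"])   # lognormal data
  # the Mann-Whitney battery still runs regardless of normality
  groups <- tibble::tibble(subject_id = sprintf("p%02d", 1:40),
                           group = rep(c("a", "b"), 20))
  res <- between_group_tests(panel, groups, timepoints = "T1")
  expect_equal(res$test[res$cytokine == "IL17"], "mann_whitney")
})

test_that("PCA on complete data equals plain SVD and imputation is a no-op", {
  set.seed(121)
  m <- matrix(stats::rlnorm(30 * 12, 2, 0.4), 30, 12,
              dimnames = list(NULL, cytokine_names()))
  panel <- make_panel(list(T1 = m))
  g <- rep(c("a", "b"), 15)
  pc <- panel_pca(panel, g)
  sv <- svd(scale(m))
  ref <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  # scores match plain SVD up to per-component sign
  for (k in 1:2) {
    expect_true(max(abs(pc$scores[[paste0("PC", k)]] - ref[, k])) < 1e-8 ||
                max(abs(pc$scores[[paste0("PC", k)]] + ref[, k])) < 1e-8)
  }
  expect_equal(pc$imputation_iterations, 0)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_equal(pc$ellipses$coverage, c(0.95, 0.95))
})

test_that("PCA separates planted groups but overlaps isotropic ones", {
  set.seed(131)
  m <- matrix(stats::rnorm(40 * 12, 10, 1), 40, 12,
              dimnames = list(NULL, cytokine_names()))
  # a coherent multi-cytokine signature: after unit-variance scaling a
  # single shifted column cannot dominate PC1, so the plant spans six
  m[1:20, 1:6] <- m[1:20, 1:6] + 15
  m[sample(length(m), 30)] <- NA          # exercise the imputation
  panel <- make_panel(list(T1 = pmax(m, 0)))
  g <- rep(c("hi", "lo"), each = 20)
  pc <- panel_pca(panel, g)
  sc <- pc$scores
  gap <- abs(mean(sc$PC1[sc$group == "hi"]) - mean(sc$PC1[sc$group == "lo"]))
  spread <- stats::sd(sc$PC1[sc$group == "hi"])
  expect_gt(gap, 2 * spread)             # clear PC1 separation

  m2 <- matrix(stats::rnorm(40 * 12, 10, 1), 40, 12,
               dimnames = list(NULL, cytokine_names()))
  pc2 <- panel_pca(make_panel(list(T1 = pmax(m2, 0))), g)
  ctrs <- pc2$ellipses
  dist_centers <- sqrt(diff(ctrs$center_x)^2 + diff(ctrs$center_y)^2)
  expect_lt(dist_centers, min(ctrs$semi_major))   # ellipses overlap
  p <- autoplot(pc2)
  expect_s3_class(p, "ggplot")
})

test_that("heatmap medians preserve gradient order and clustering matches the oracle", {
  set.seed(141)
  tps <- c("pre", "T1", "T2", "T3")
  mats <- lapply(seq_along(tps), function(i) {
    matrix(stats::rlnorm(8 * 12, 2 - 0.4 * i, 0.05), 8, 12,
           dimnames = list(NULL, cytokine_names()))
  })
  names(mats) <- tps
  hm <- heatmap_matrix(make_panel(mats))
  # monotone decreasing medians -> scaled gradient runs 1 ... 0
  expect_true(all(apply(hm$scaled, 1, function(v) all(diff(v) < 0))))
  expect_equal(unname(hm$scaled[, "pre"]), rep(1, 12))

  m <- matrix(stats::rnorm(7 * 12, 5, 1), 7, 12,
              dimnames = list(NULL, cytokine_names()))
  m <- rbind(m, m[7, , drop = FALSE])     # duplicated sample
  hm2 <- heatmap_matrix(make_panel(list(T1 = pmax(m, 0.1))))
  cl <- hm2$sample_clustering
  expect_equal(min(cl$height), 0)         # identical pair merges at height 0
  expect_equal(sort(cl$height),
               sort(oracle_average_linkage_heights(stats::dist(scale(pmax(m, 0.1))))),
               tolerance = 1e-9)
})
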