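make_relabund <- function(n_samples, n_features, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rgamma(n_samples * n_features, 1), n_samples, n_features,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("f%02d", seq_len(n_features))))
  feature_table(m / rowSums(m), unit = "relabund")
}

test_that("genus merge averages member features and matches a group-by oracle", {
  m <- matrix(c(0.2, 0.4, 0.4,
                0.1, 0.5, 0.4), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  tax <- parse_taxonomy(c("f1", "f2", "f3"),
                        c("k__B;f__F1;g__GenA", "k__B;f__F1;g__GenA",
                          "k__B;f__F2;g__GenB"))
  merged <- merge_to_genus(feature_table(m, "relabund"), tax)
  expect_equal(merged[, "g__GenA"], c(s1 = 0.3, s2 = 0.3))   # mean of pair
  expect_equal(merged[, "g__GenB"], c(s1 = 0.4, s2 = 0.4))   # singleton intact

  # 30-genus random table against an explicit tapply oracle
  ft <- make_relabund(12, 60, seed = 5)
  genera <- sprintf("g__Gen%02d", rep(1:30, each = 2))
  tax2 <- tibble::tibble(feature_id = colnames(ft),
                         lineage = paste0("k__B;f__F;", genera),
                         genus = genera, family = "F")
  merged2 <- merge_to_genus(ft, tax2)
  oracle <- t(apply(unclass(ft), 1, function(v) tapply(v, genera, mean)))
  expect_equal(unclass(merged2)[, colnames(oracle)], oracle)
  expect_error(merge_to_genus(ft, tax2[0, ]), "empty")
})

test_that("pseudo-count log transform maps zeros to -2 and whitens columns", {
  ft <- make_relabund(20, 10, seed = 7)
  x <- unclass(ft); x[3, 2] <- 0
  x <- x / rowSums(x)
  norm <- log_z_transform(x, pseudo_count = 0.01)
  # pre-whitening closed form for a zero abundance
  expect_equal(log10(0 + 0.01), -2)
  recovered <- unclass(norm) * rep(attr(norm, "scale"), each = nrow(norm)) +
    rep(attr(norm, "center"), each = nrow(norm))
  expect_equal(recovered[3, 2], -2, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(norm))), 1e-9)
  expect_lt(max(abs(apply(norm, 2, stats::sd) - 1)), 1e-9)
})

test_that("zero-variance genus columns are dropped with a warning", {
  x <- cbind(flat = rep(0.25, 8),
             ok = seq(0.1, 0.8, length.out = 8))
  rownames(x) <- sprintf("s%d", 1:8)
  expect_warning(norm <- log_z_transform(x), "zero-variance")
  expect_equal(colnames(norm), "ok")
})

test_that("frozen whitening statistics transfer to held-out samples", {
  ft <- make_relabund(15, 6, seed = 9)
  train <- unclass(ft)[1:12, ]; test <- unclass(ft)[13:15, ]
  norm <- log_z_transform(train)
  z_new <- apply_normalization(norm, test)
  manual <- sweep(sweep(log10(test + 0.01), 2, attr(norm, "center")), 2,
                  attr(norm, "scale"), "/")
  expect_equal(z_new, manual)
  # applying to the training data reproduces the fitted scores
  expect_equal(apply_normalization(norm, train), unclass(norm),
               ignore_attr = TRUE)
})

test_that("detrending removes per-timepoint means, planted trends, and is idempotent", {
  subjects <- sprintf("S%02d", 1:10)
  meta <- make_meta(subjects, c("T1", "T2", "T3"))
  set.seed(13)
  z <- matrix(stats::rnorm(30 * 5), 30, 5,
              dimnames = list(meta$sample_id, sprintf("g%d", 1:5)))
  # plant a time trend on every genus
  tp_idx <- match(as.character(meta$timepoint), timepoint_levels())
  z_trend <- z + outer(tp_idx, rep(1.5, 5))
  norm <- pregbiome:::new_normalized(z_trend, center = rep(0, 5),
                                     scale = rep(1, 5), pseudo_count = 0.01,
                                     detrended = FALSE)
  det <- detrend_time(norm, meta)
  for (tp in unique(tp_idx)) {
    expect_lt(max(abs(colMeans(unclass(det)[tp_idx == tp, ]))), 1e-9)
  }
  expect_lt(max(abs(stats::cor(unclass(det), tp_idx))), 1e-9)
  det2 <- detrend_time(det, meta)
  expect_equal(unclass(det2), unclass(det), tolerance = 1e-9)
})

test_that("detrending a timepoint with identical values zeroes it exactly", {
  meta <- make_meta(c("S1", "S2", "S3"), c("T1", "T2"))
  z <- matrix(stats::rnorm(18), 6, 3, dimnames = list(meta$sample_id, c("a", "b", "c")))
  z[meta$timepoint == "T1", ] <- 2.5
  norm <- pregbiome:::new_normalized(z, rep(0, 3), rep(1, 3), 0.01, FALSE)
  det <- detrend_time(norm, meta)
  expect_true(all(unclass(det)[meta$timepoint == "T1", ] == 0))
})
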