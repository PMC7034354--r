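# UC-vs-CD discrimination: leave-one-out cross-validated linear soft-margin
# SVM on per-fold renormalised genus profiles, with a rank-statistic AUC.

#' Area under the ROC curve by rank statistic
#'
#' Midrank (Mann-Whitney) AUC of `scores` for discriminating
#' `labels == positive`; ties get midranks, so the AUC is invariant under
#' strictly monotone transforms of the scores.
#'
#' @param labels Two-class vector.
#' @param scores Numeric decision values, larger meaning more positive.
#' @param positive The label treated as positive (default: second factor
#'   level).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(labels, scores, positive = NULL) {
  g <- as.factor(labels)
  positive <- positive %||% levels(g)[2]
  pos <- g == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_pb("need both classes to compute an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated linear SVM
#'
#' Trains a linear soft-margin SVM (box constraint `C`, default 1) on
#' genus-level abundances, holding out one sample per fold. Normalisation
#' statistics (pseudo-count log10 + z-score) are refit on each training fold
#' and applied frozen to the held-out sample, so no information leaks from
#' the test sample into the transform. The signed decision value of each
#' held-out sample is recorded and the AUC computed by midrank statistic.
#' No kernels and no hyperparameter search: with cohorts this small,
#' anything more flexible overfits.
#'
#' @param table Samples x genera relative abundances (merged genus table); a
#'   `normalized_table` is also accepted, in which case its values are used
#'   as-is per fold without refitting (not recommended).
#' @param labels Two-class vector aligned with the rows; each class needs at
#'   least two members (a singleton class would make its LOOCV fold
#'   degenerate).
#' @param box_constraint Soft-margin cost `C` (default 1).
#' @param pseudo_count Offset for the per-fold log transform (default 0.01).
#' @return A `cv_result` list: `predictions` tibble (`sample_id`,
#'   `true_label`, `decision_value`, `n_support_vectors`), `auc`,
#'   `positive_class`.
#' @export
loocv_linear_svm <- function(table, labels, box_constraint = 1,
                             pseudo_count = 0.01) {
  x <- as.matrix(unclass(table))
  g <- droplevels(as.factor(labels))
  if (nlevels(g) != 2) stop_pb("exactly two classes required")
  if (any(table(g) < 2)) stop_pb("each class needs >= 2 members for LOOCV")
  if (nrow(x) < 4) stop_pb("need at least 4 samples")
  if (any(!is.finite(x))) stop_pb("non-finite feature values")
  refit <- !inherits(table, "normalized_table")
  pos <- levels(g)[2]

  n <- nrow(x)
  dec <- numeric(n)
  nsv <- integer(n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]
    te_x <- x[i, , drop = FALSE]
    if (refit) {
      norm <- log_z_transform(tr_x, pseudo_count = pseudo_count)
      te_x <- apply_normalization(norm, te_x)
      tr_x <- unclass(norm)
    }
    fit <- e1071::svm(tr_x, g[-i], kernel = "linear", cost = box_constraint,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, te_x[, colnames(tr_x), drop = FALSE],
                              decision.values = TRUE), "decision.values")
    # e1071 names the decision column "A/B" with larger values meaning A;
    # flip so that larger always means the positive (second) class
    flip <- if (startsWith(colnames(dv)[1], paste0(pos, "/"))) 1 else -1
    dec[i] <- flip * dv[1, 1]
    nsv[i] <- fit$tot.nSV
  }
  res <- list(
    predictions = tibble::tibble(sample_id = rownames(x) %||%
                                   as.character(seq_len(n)),
                                 true_label = as.character(g),
                                 decision_value = dec,
                                 n_support_vectors = nsv),
    auc = rank_auc(g, dec, positive = pos),
    positive_class = pos
  )
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> LOOCV linear SVM, n = ", nrow(x$predictions),
      ", AUC = ", format(round(x$auc, 3)), " (positive: ", x$positive_class,
      ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n = nrow(x$predictions),
                 positive_class = x$positive_class,
                 mean_support_vectors = mean(x$predictions$n_support_vectors))
}

#' ROC coordinates of a cross-validation result
#'
#' @param cv A `cv_result`.
#' @return Tibble with `threshold`, `fpr`, `tpr`, one row per distinct
#'   decision value plus the endpoints.
#' @export
roc_coordinates <- function(cv) {
  d <- cv$predictions
  pos <- d$true_label == cv$positive_class
  thr <- c(Inf, sort(unique(d$decision_value), decreasing = TRUE), -Inf)
  purrr::map_dfr(thr, function(t) {
    pred <- d$decision_value >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & !pos) / sum(!pos),
                   tpr = sum(pred & pos) / sum(pos))
  })
}

#' ROC curve plot for a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  rc <- roc_coordinates(object)
  ggplot2::ggplot(rc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("LOOCV ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}
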