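# Genus merging, pseudo-count log transform, whitening, time detrending.
#
# Fixed order of operations: merge -> relative abundance -> + pseudo-count ->
# log10 -> whiten (z-score per genus) -> detrend (subtract per-timepoint
# genus means). The whitening statistics are kept on the object so that a
# transform fitted on a training fold can be applied, frozen, to held-out
# samples.

#' Merge features to the genus level
#'
#' The genus value of a sample is the arithmetic mean of the relative
#' abundances of all features assigned to that genus (not their sum, and the
#' merged table is not renormalised). Features without a genus assignment are
#' pooled into `g__unclassified.<family>` buckets.
#'
#' @param table A `feature_table`; counts are converted to relative
#'   abundance first.
#' @param taxonomy Tibble from [read_taxonomy()]/[parse_taxonomy()] covering
#'   every feature in `table`.
#' @return A `feature_table` (samples x genera) of averaged relative
#'   abundances, with attribute `merged_genus_count`.
#' @export
merge_to_genus <- function(table, taxonomy) {
  if (nrow(taxonomy) == 0) stop_pb("empty taxonomy")
  table <- to_relabund(table)
  miss <- setdiff(colnames(table), taxonomy$feature_id)
  if (length(miss)) stop_pb("feature(s) without taxonomy: ",
                            paste(utils::head(miss, 5), collapse = ", "))
  genus <- taxonomy$genus[match(colnames(table), taxonomy$feature_id)]
  groups <- split(seq_len(ncol(table)), genus)
  merged <- vapply(groups, function(idx) {
    rowMeans(unclass(table)[, idx, drop = FALSE])
  }, numeric(nrow(table)))
  if (nrow(table) == 1) merged <- matrix(merged, nrow = 1,
                                         dimnames = list(rownames(table),
                                                         names(groups)))
  # averaged values no longer sum to 1, so bypass the relabund invariant
  out <- structure(merged, unit = "genus_mean_relabund",
                   class = c("feature_table", "matrix", "array"))
  attr(out, "merged_genus_count") <- length(groups)
  out
}

#' Pseudo-count log10 transform and statistical whitening
#'
#' Each value becomes `log10(value + pseudo_count)` (so a zero abundance maps
#' to `log10(0.01) = -2` at the default pseudo-count), then each genus column
#' is z-scored across the samples used for fitting: subtract the column mean
#' and divide by the column SD (sample SD, denominator n-1). Zero-variance
#' columns are dropped with a warning, since their z-score is undefined.
#'
#' @param table Samples x genera matrix (or `feature_table`) of relative
#'   abundances in `[0, 1]`.
#' @param pseudo_count Positive offset added before the log (default 0.01).
#' @return A `normalized_table`: samples x genera z-score matrix with
#'   attributes `center`, `scale` (the frozen whitening statistics),
#'   `pseudo_count` and `detrended = FALSE`.
#' @export
log_z_transform <- function(table, pseudo_count = 0.01) {
  if (pseudo_count <= 0) stop_pb("pseudo_count must be positive")
  x <- unclass(table)
  if (any(x < 0)) stop_pb("abundances must be non-negative")
  lg <- log10(x + pseudo_count)
  ctr <- colMeans(lg)
  scl <- apply(lg, 2, stats::sd)
  flat <- scl < .Machine$double.eps^0.5
  if (any(flat)) {
    warn_pb("dropping ", sum(flat), " zero-variance genus column(s): ",
            paste(utils::head(colnames(lg)[flat], 5), collapse = ", "))
    lg <- lg[, !flat, drop = FALSE]
    ctr <- ctr[!flat]
    scl <- scl[!flat]
  }
  if (ncol(lg) == 0) stop_pb("no genus column with nonzero variance")
  z <- sweep(sweep(lg, 2, ctr), 2, scl, "/")
  new_normalized(z, center = ctr, scale = scl, pseudo_count = pseudo_count,
                 detrended = FALSE)
}

new_normalized <- function(z, center, scale, pseudo_count, detrended) {
  structure(z, center = center, scale = scale, pseudo_count = pseudo_count,
            detrended = detrended,
            class = c("normalized_table", "matrix", "array"))
}

#' @export
print.normalized_table <- function(x, ...) {
  cat("<normalized_table> ", nrow(x), " samples x ", ncol(x), " genera",
      if (isTRUE(attr(x, "detrended"))) ", detrended" else "", "\n", sep = "")
  invisible(x)
}

#' Apply frozen whitening statistics to new samples
#'
#' Used by the leave-one-out classifier: the pseudo-count/log/z transform is
#' fitted on the training fold and applied unchanged to the held-out sample.
#'
#' @param norm A `normalized_table` fitted with [log_z_transform()].
#' @param table New samples x genera relative abundances (same genera).
#' @return Matrix of z-scores for the new samples, using the frozen
#'   column means and SDs.
#' @export
apply_normalization <- function(norm, table) {
  ctr <- attr(norm, "center")
  scl <- attr(norm, "scale")
  x <- unclass(table)[, names(ctr), drop = FALSE]
  lg <- log10(x + attr(norm, "pseudo_count"))
  sweep(sweep(lg, 2, ctr), 2, scl, "/")
}

#' Remove the per-timepoint mean of each genus
#'
#' For each genus and each timepoint, the mean of that genus over the samples
#' collected at that timepoint is subtracted, removing the shared effect of
#' gestational time so that the remaining variation is between-subject. The
#' operation is idempotent. A timepoint observed in a single sample maps that
#' sample to exactly zero (its own mean), which is logged via a message.
#'
#' @param norm A `normalized_table` (samples in rows).
#' @param meta Validated metadata covering every row of `norm`.
#' @return A `normalized_table` with `detrended = TRUE`; every
#'   (genus, timepoint) mean is 0 to numerical precision.
#' @export
detrend_time <- function(norm, meta) {
  meta <- tibble::as_tibble(meta)
  idx <- match(rownames(norm), meta$sample_id)
  if (anyNA(idx)) stop_pb("sample(s) missing from metadata: ",
                          paste(rownames(norm)[is.na(idx)][1], collapse = ", "))
  tp <- as.character(meta$timepoint[idx])
  if (anyNA(tp)) stop_pb("sample(s) with missing timepoint")
  z <- unclass(norm)
  for (t in unique(tp)) {
    rows <- tp == t
    if (sum(rows) == 1) {
      message("timepoint '", t, "' has a single sample; detrending zeroes it")
    }
    z[rows, ] <- sweep(z[rows, , drop = FALSE], 2,
                       colMeans(z[rows, , drop = FALSE]))
  }
  new_normalized(z, center = attr(norm, "center"), scale = attr(norm, "scale"),
                 pseudo_count = attr(norm, "pseudo_count"), detrended = TRUE)
}

#' Full microbiome normalisation chain
#'
#' Convenience wrapper enforcing the fixed order merge -> relative abundance
#' -> pseudo-count log10 -> whiten -> (optionally) detrend.
#'
#' @param table A counts or relative-abundance `feature_table`.
#' @param taxonomy Taxonomy tibble.
#' @param meta Metadata (required when `detrend = TRUE`).
#' @param pseudo_count Offset for the log transform.
#' @param detrend Whether to remove per-timepoint genus means.
#' @return A `normalized_table`.
#' @export
normalize_microbiome <- function(table, taxonomy, meta = NULL,
                                 pseudo_count = 0.01, detrend = FALSE) {
  merged <- merge_to_genus(table, taxonomy)
  norm <- log_z_transform(merged, pseudo_count = pseudo_count)
  if (detrend) {
    if (is.null(meta)) stop_pb("detrending needs sample metadata")
    norm <- detrend_time(norm, meta)
  }
  norm
}
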