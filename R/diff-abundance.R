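# Two-class differential abundance in the LEfSe style: a Kruskal-Wallis
# screen followed by a bootstrap-averaged linear-discriminant effect size on
# the LEfSe per-million abundance scale.

#' LEfSe-style two-class effect-size screen
#'
#' Stage 1 tests every feature with Kruskal-Wallis at `kw_alpha`. Stage 2,
#' for survivors only, computes a one-dimensional Fisher-discriminant effect
#' size: relative abundances are scaled to parts-per-million (the LEfSe
#' convention), and over `n_boot` bootstrap rounds a stratified two-thirds
#' subsample is drawn and the absolute difference of class means along the
#' (unit-norm) discriminant direction recorded; the effect size is the log10
#' of the bootstrap average. Signs are positive when the second factor level
#' of `labels` has the higher mean, so swapping the class labels flips every
#' sign and nothing else.
#'
#' @param table Relative-abundance table (samples x features); counts are
#'   converted internally.
#' @param labels Two-class factor-like vector aligned with rows; each class
#'   needs n >= 3.
#' @param kw_alpha Screening level (default 0.05).
#' @param lda_threshold Absolute log10 effect-size cutoff (default 2).
#' @param n_boot Bootstrap rounds (default 30).
#' @param boot_fraction Fraction subsampled per class per round (default 2/3).
#' @param seed Integer seed for the bootstrap.
#' @return A `lefse_result` tibble: `feature`, `class_with_higher_mean`,
#'   `mean_class1`, `mean_class2` (per-million scale), `kw_p`, `lda_score`
#'   (signed log10), `passed`.
#' @export
lefse_like <- function(table, labels, kw_alpha = 0.05, lda_threshold = 2,
                       n_boot = 30L, boot_fraction = 2 / 3, seed = 1L) {
  g <- droplevels(as.factor(labels))
  if (nlevels(g) != 2) stop_pb("exactly two classes required")
  if (any(table(g) < 3)) stop_pb("each class needs at least 3 samples")
  x <- as.matrix(unclass(table))
  if (inherits(table, "feature_table") && ft_unit(table) == "counts") {
    x <- x / rowSums(x)
  }
  x <- x * 1e6
  if (length(g) != nrow(x)) stop_pb("labels must match the table rows")

  kw_p <- apply(x, 2, function(v) {
    if (length(unique(v)) == 1) return(1)
    stats::kruskal.test(v, g)$p.value
  })
  lev <- levels(g)
  m1 <- colMeans(x[g == lev[1], , drop = FALSE])
  m2 <- colMeans(x[g == lev[2], , drop = FALSE])

  survivors <- which(kw_p < kw_alpha)
  eff <- rep(NA_real_, ncol(x))
  if (length(survivors)) {
    # resample in sorted-label order so swapping the factor levels cannot
    # change the bootstrap draws (label swap must only flip signs)
    lev_sorted <- sort(lev)
    idx_a <- which(g == lev_sorted[1]); idx_b <- which(g == lev_sorted[2])
    ka <- max(2L, ceiling(boot_fraction * length(idx_a)))
    kb <- max(2L, ceiling(boot_fraction * length(idx_b)))
    eff[survivors] <- with_seed(seed, {
      vapply(survivors, function(j) {
        mean(vapply(seq_len(n_boot), function(b) {
          sa <- sample(idx_a, ka); sb <- sample(idx_b, kb)
          # 1-D Fisher direction normalised to unit norm is +/-1, so the
          # projected class difference is the raw mean difference
          abs(mean(x[sb, j]) - mean(x[sa, j]))
        }, numeric(1)))
      }, numeric(1))
    })
  }
  score <- ifelse(is.na(eff), NA_real_,
                  sign(m2 - m1) * log10(pmax(eff, 1)))
  out <- tibble::tibble(
    feature = colnames(x),
    class_with_higher_mean = unname(ifelse(m2 >= m1, lev[2], lev[1])),
    mean_class1 = unname(m1), mean_class2 = unname(m2),
    kw_p = unname(kw_p),
    lda_score = unname(score),
    passed = !is.na(score) & kw_p < kw_alpha & abs(score) >= lda_threshold
  )
  attr(out, "classes") <- lev
  class(out) <- c("lefse_result", class(out))
  out
}

#' @export
glance.lefse_result <- function(x, ...) {
  tibble::tibble(n_features = nrow(x), n_screened = sum(x$kw_p < 1),
                 n_passed = sum(x$passed))
}

#' Write a LEfSe-style result as TSV
#'
#' @param result A `lefse_result`.
#' @param path Output path.
#' @param taxonomy Optional taxonomy tibble; adds a `lineage` column.
#' @return `path`, invisibly.
#' @export
write_lefse_result <- function(result, path, taxonomy = NULL) {
  out <- result
  if (!is.null(taxonomy)) {
    out <- dplyr::left_join(out,
                            dplyr::select(taxonomy, feature = "feature_id",
                                          "lineage"),
                            by = "feature")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
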