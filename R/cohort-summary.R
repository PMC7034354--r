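# Cohort characteristics table: per-group counts/percentages and group
# comparisons, in the style of a clinical Table 1.

#' Summarise per-subject cohort characteristics by group
#'
#' Counts and percentages are computed per group for each categorical
#' attribute; percentages use the number of non-missing records in that group
#' as the denominator (so attributes known for only part of a group, e.g.
#' delivery mode, use the observed denominator) and are rounded half-up to
#' one decimal. Group comparison p-values use Fisher's exact test for
#' categorical attributes and, for continuous attributes, Welch's t-test when
#' both groups pass Shapiro-Wilk normality at 0.05, Mann-Whitney otherwise.
#'
#' @param data Per-subject tibble; one row per subject (or per pregnancy,
#'   if that is the natural denominator — the function never infers it).
#' @param group Name of the grouping column (two or more groups, each
#'   non-empty).
#' @param categorical Character vector of categorical column names.
#' @param continuous Character vector of continuous column names.
#' @return List with `summary` (tibble: group, variable, level, n, denom,
#'   pct) and `tests` (tibble: variable, test, statistic, p).
#' @export
cohort_summary <- function(data, group, categorical = character(),
                           continuous = character()) {
  data <- tibble::as_tibble(data)
  if (!group %in% names(data)) stop_pb("grouping column '", group, "' not found")
  g <- as.factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_pb("need at least two groups")
  if (any(table(g) == 0)) stop_pb("empty group")

  summ <- purrr::map_dfr(categorical, function(v) {
    purrr::map_dfr(levels(g), function(gl) {
      x <- data[[v]][g == gl]
      x <- x[!is.na(x)]
      denom <- length(x)
      lvls <- sort(unique(as.character(data[[v]][!is.na(data[[v]])])))
      purrr::map_dfr(lvls, function(lv) {
        n <- sum(x == lv)
        tibble::tibble(group = gl, variable = v, level = lv,
                       n = n, denom = denom,
                       pct = percent_of(n, denom))
      })
    })
  })

  tests <- dplyr::bind_rows(
    purrr::map_dfr(categorical, function(v) {
      keep <- !is.na(data[[v]])
      tab <- table(as.character(data[[v]][keep]), droplevels(g[keep]))
      if (any(dim(tab) < 2)) {
        return(tibble::tibble(variable = v, test = "fisher_exact",
                              statistic = NA_real_, p = NA_real_))
      }
      ft <- stats::fisher.test(tab, simulate.p.value = prod(dim(tab)) > 10,
                               B = 10000)
      tibble::tibble(variable = v, test = "fisher_exact",
                     statistic = NA_real_, p = ft$p.value)
    }),
    purrr::map_dfr(continuous, function(v) {
      x <- data[[v]]
      keep <- !is.na(x)
      gg <- droplevels(g[keep])
      if (nlevels(gg) != 2) {
        kw <- stats::kruskal.test(x[keep], gg)
        return(tibble::tibble(variable = v, test = "kruskal_wallis",
                              statistic = unname(kw$statistic), p = kw$p.value))
      }
      xs <- split(x[keep], gg)
      normal <- all(vapply(xs, function(z) {
        length(unique(z)) > 2 && length(z) >= 3 && length(z) <= 5000 &&
          stats::shapiro.test(z)$p.value >= 0.05
      }, logical(1)))
      if (normal) {
        tt <- stats::t.test(xs[[1]], xs[[2]])
        tibble::tibble(variable = v, test = "welch_t",
                       statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        wt <- stats::wilcox.test(xs[[1]], xs[[2]], exact = FALSE)
        tibble::tibble(variable = v, test = "mann_whitney",
                       statistic = unname(wt$statistic), p = wt$p.value)
      }
    })
  )
  list(summary = summ, tests = tests)
}

#' Percentage with half-up rounding to one decimal
#'
#' @param n Count.
#' @param denom Denominator (explicit — never inferred from another column).
#' @return `100 * n / denom` rounded half-up to one decimal; 0 when
#'   `denom` is 0 and `n` is 0.
#' @export
percent_of <- function(n, denom) {
  if (any(denom == 0 & n > 0)) stop_pb("nonzero count with zero denominator")
  out <- ifelse(denom == 0, 0, round_half_up(100 * n / denom, 1))
  out
}
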