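# Alpha diversity, rarefaction, UniFrac, PCoA ordination, PERMANOVA.
#
# Faith's PD, both UniFrac variants and PERMANOVA are implemented here from
# their definitions (tests compare them against brute-force oracles and,
# where available, picante/vegan).

# Per-branch bookkeeping shared by Faith's PD and UniFrac: for every edge of
# a rooted tree, its length and the set of leaves below it, as a
# tips x edges 0/1 matrix.
branch_structure <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  nedge <- nrow(tr$edge)
  node_tips <- vector("list", nnode)
  for (i in seq_len(ntip)) node_tips[[i]] <- i
  for (e in seq_len(nedge)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    node_tips[[p]] <- c(node_tips[[p]], node_tips[[ch]])
  }
  desc <- matrix(0, ntip, nedge)
  for (e in seq_len(nedge)) desc[node_tips[[tr$edge[e, 2]]], e] <- 1
  rownames(desc) <- tr$tip.label
  list(desc = desc, lengths = tr$edge.length, tips = tr$tip.label)
}

# Align a samples x features abundance matrix with a tree: keep shared
# features, prune the tree, warn about features with no leaf.
align_tree_table <- function(values, tree) {
  shared <- intersect(colnames(values), tree$tip.label)
  if (length(shared) == 0) stop_pb("no feature shared between table and tree")
  lost <- setdiff(colnames(values), tree$tip.label)
  if (length(lost)) {
    warn_pb(length(lost), " feature(s) absent from the tree were pruned: ",
            paste(utils::head(lost, 5), collapse = ", "))
  }
  tree <- if (length(shared) < length(tree$tip.label)) {
    ape::keep.tip(tree, shared)
  } else tree
  list(values = values[, shared, drop = FALSE], tree = tree)
}

#' Depth-filter and rarefy a count table
#'
#' Samples with fewer total sequences than `depth` are removed; the remaining
#' samples are subsampled without replacement to exactly `depth` reads
#' (seeded, reproducible).
#'
#' @param table A counts `feature_table`.
#' @param depth Minimum and target sequencing depth (default 5928).
#' @param seed Integer seed for the subsampling.
#' @return A counts `feature_table` whose rows all sum to `depth`, with
#'   attribute `dropped_samples`.
#' @export
depth_filter_and_rarefy <- function(table, depth = 5928L, seed = 1L) {
  stopifnot(ft_unit(table) == "counts", depth >= 1)
  tot <- rowSums(table)
  keep <- tot >= depth
  if (!any(keep)) stop_pb("all samples fall below depth ", depth)
  dropped <- rownames(table)[!keep]
  x <- unclass(table)[keep, , drop = FALSE]
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # pre-scaled data); the unit is validated as counts here, so mute it
  rar <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(round(x), sample = depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- feature_table(rar, unit = "counts")
  attr(out, "dropped_samples") <- dropped
  out
}

#' Faith's phylogenetic diversity
#'
#' The total branch length of the minimal subtree connecting the root and
#' every leaf observed (count > 0) in a sample.
#'
#' @param table Counts or relative-abundance `feature_table` (or matrix),
#'   samples in rows.
#' @param tree Rooted `phylo` covering the observed features (others are
#'   pruned with a warning).
#' @return Named numeric vector of PD values, one per sample; a sample with
#'   no observed feature gets 0 with a warning.
#' @export
faith_pd <- function(table, tree) {
  al <- align_tree_table(as.matrix(unclass(table)), tree)
  bs <- branch_structure(al$tree)
  pres <- al$values[, bs$tips, drop = FALSE] > 0
  pd <- apply(pres, 1, function(p) {
    if (!any(p)) return(0)
    sum(bs$lengths[colSums(bs$desc[p, , drop = FALSE]) > 0])
  })
  if (any(rowSums(pres) == 0)) {
    warn_pb("sample(s) with no observed feature have PD 0: ",
            paste(names(pd)[rowSums(pres) == 0], collapse = ", "))
  }
  pd
}

#' Shannon diversity (bits) and Pielou evenness
#'
#' Shannon entropy uses base-2 logarithms (the QIIME 2 convention); Pielou's
#' evenness divides by `log2(observed richness)` so the base cancels. A
#' sample with a single observed feature has Shannon 0 and undefined
#' (`NA`) evenness.
#'
#' @param table Counts or relative-abundance table, samples in rows.
#' @return Tibble with `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
shannon_pielou <- function(table) {
  x <- as.matrix(unclass(table))
  out <- apply(x, 1, function(v) {
    p <- v[v > 0]
    p <- p / sum(p)
    h <- -sum(p * log2(p))
    s <- length(p)
    c(richness = s, shannon = h,
      pielou = if (s > 1) h / log2(s) else NA_real_)
  })
  tibble::as_tibble(t(out), rownames = "sample_id")
}

#' Alpha diversity table
#'
#' @param table Rarefied counts `feature_table`.
#' @param tree Rooted `phylo`.
#' @return Tibble with `sample_id`, `richness`, `shannon`, `pielou`,
#'   `faith_pd`.
#' @export
alpha_diversity <- function(table, tree) {
  sp <- shannon_pielou(table)
  sp$faith_pd <- unname(faith_pd(table, tree)[sp$sample_id])
  sp
}

#' UniFrac distance matrix
#'
#' Unweighted UniFrac between two samples is the fraction of the branch
#' length observed in either sample that is unique to one of them
#' (presence/absence only). Weighted (normalised) UniFrac is
#' `sum(b * |p - q|) / sum(b * (p + q))` over branches, where `p`, `q` are
#' the proportions of each sample's abundance below the branch.
#'
#' @param table Relative-abundance (or counts, converted internally)
#'   `feature_table`, samples in rows; no sample may have zero total.
#' @param tree Shared rooted `phylo`.
#' @param weighted `TRUE` for weighted-normalised, `FALSE` for unweighted.
#' @return A `distance_matrix`: symmetric labelled matrix in `[0, 1]` with
#'   zero diagonal.
#' @export
unifrac <- function(table, tree, weighted = FALSE) {
  vals <- as.matrix(unclass(table))
  if (any(rowSums(vals) == 0)) {
    stop_pb("sample(s) with zero total abundance: ",
            paste(rownames(vals)[rowSums(vals) == 0], collapse = ", "))
  }
  vals <- vals / rowSums(vals)
  al <- align_tree_table(vals, tree)
  bs <- branch_structure(al$tree)
  # samples x edges matrix of below-branch proportions
  prop <- al$values[, bs$tips, drop = FALSE] %*% bs$desc
  n <- nrow(prop)
  bl <- bs$lengths
  d <- matrix(0, n, n, dimnames = list(rownames(prop), rownames(prop)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- prop[i, ]; q <- prop[j, ]
      if (weighted) {
        denom <- sum(bl * (p + q))
        d[i, j] <- d[j, i] <- sum(bl * abs(p - q)) / denom
      } else {
        a <- p > 0; b <- q > 0
        union_len <- sum(bl[a | b])
        d[i, j] <- d[j, i] <- sum(bl[xor(a, b)]) / union_len
      }
    }
  }
  structure(d, class = c("distance_matrix", "matrix", "array"),
            metric = if (weighted) "weighted_unifrac" else "unweighted_unifrac")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", nrow(x), " samples (",
      attr(x, "metric") %||% "unknown metric", ")\n", sep = "")
  invisible(x)
}

#' Write a distance matrix as square labelled TSV
#'
#' @param d A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  readr::write_tsv(tibble::as_tibble(unclass(d), rownames = "sample_id"),
                   path, progress = FALSE)
  invisible(path)
}

#' Principal coordinates of a distance matrix
#'
#' Classical PCoA (metric multidimensional scaling) for ordination plots.
#'
#' @param d A `distance_matrix`.
#' @param k Number of axes (default 2).
#' @return Tibble with `sample_id`, `PCo1`, `PCo2`, ...; attribute
#'   `eig_fraction` holds the fraction of positive eigenvalue mass per axis.
#' @export
pcoa_coordinates <- function(d, k = 2) {
  fit <- stats::cmdscale(stats::as.dist(unclass(d)), k = k, eig = TRUE)
  co <- fit$points
  colnames(co) <- paste0("PCo", seq_len(ncol(co)))
  out <- tibble::as_tibble(co, rownames = "sample_id")
  pos <- fit$eig[fit$eig > 0]
  attr(out, "eig_fraction") <- fit$eig[seq_len(k)] / sum(pos)
  out
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' statistic compares between-group to within-group sums of squared
#' distances, and its null distribution is obtained by permuting group
#' labels. `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d A `distance_matrix` (or symmetric labelled matrix).
#' @param grouping Factor-like vector, aligned with the rows of `d`; at least
#'   two groups with at least two members each.
#' @param n_perm Number of permutations (default 999; must be >= 1).
#' @param seed Integer seed.
#' @return Tibble with `pseudo_F`, `p`, `n_perm`, `n_groups`, `n_samples`.
#' @export
permanova <- function(d, grouping, n_perm = 999L, seed = 1L) {
  if (n_perm < 1) stop_pb("n_perm must be at least 1")
  dm <- as.matrix(unclass(d))
  g <- as.factor(grouping)
  if (length(g) != nrow(dm)) stop_pb("grouping length must match the matrix")
  g <- droplevels(g)
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop_pb("need >= 2 groups with >= 2 samples each")
  }
  d2 <- dm^2
  n <- nrow(dm)
  a <- nlevels(g)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw_of <- function(gg) {
    s <- 0
    for (lv in levels(gg)) {
      idx <- which(gg == lv)
      s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  f_of <- function(gg) {
    ssw <- ssw_of(gg)
    ((sst - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(g)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_of(factor(sample(as.character(g)), levels = levels(g))) >= f_obs
    }, logical(1)))
  })
  tibble::tibble(pseudo_F = f_obs, p = (1 + hits) / (1 + n_perm),
                 n_perm = as.integer(n_perm), n_groups = a,
                 n_samples = n)
}

#' Compare alpha-diversity metrics between groups
#'
#' Mann-Whitney for two groups, Kruskal-Wallis for more, per metric; with an
#' optional stratification (e.g. per trimester) each stratum is tested
#' separately.
#'
#' @param alpha Tibble from [alpha_diversity()] (or any per-sample table).
#' @param grouping Vector aligned with the rows of `alpha`.
#' @param metrics Metric column names to test.
#' @param strata Optional vector aligned with rows; tests run within each
#'   stratum.
#' @return Tibble with `metric`, `stratum`, `test`, `statistic`, `p`,
#'   and per-group sizes in `n`.
#' @export
alpha_compare <- function(alpha, grouping,
                          metrics = c("faith_pd", "shannon", "pielou"),
                          strata = NULL) {
  g <- as.factor(grouping)
  strata <- if (is.null(strata)) rep("all", nrow(alpha)) else as.character(strata)
  purrr::map_dfr(unique(strata), function(st) {
    rows <- strata == st
    gg <- droplevels(g[rows])
    if (nlevels(gg) < 2 || any(table(gg) < 2)) {
      stop_pb("stratum '", st, "': need >= 2 groups of >= 2 samples")
    }
    purrr::map_dfr(metrics, function(m) {
      x <- alpha[[m]][rows]
      ok <- !is.na(x)
      if (nlevels(gg) == 2) {
        xs <- split(x[ok], droplevels(gg[ok]))
        if (length(unique(x[ok])) == 1) {
          # tie-only data carry no ordering information
          return(tibble::tibble(metric = m, stratum = st,
                                test = "mann_whitney",
                                statistic = length(xs[[1]]) *
                                  length(xs[[2]]) / 2,
                                p = 1, n = sum(ok)))
        }
        wt <- suppressWarnings(stats::wilcox.test(xs[[1]], xs[[2]],
                                                  exact = FALSE, correct = TRUE))
        tibble::tibble(metric = m, stratum = st, test = "mann_whitney",
                       statistic = unname(wt$statistic), p = wt$p.value,
                       n = sum(ok))
      } else {
        kw <- stats::kruskal.test(x[ok], droplevels(gg[ok]))
        tibble::tibble(metric = m, stratum = st, test = "kruskal_wallis",
                       statistic = unname(kw$statistic), p = kw$p.value,
                       n = sum(ok))
      }
    })
  })
}
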