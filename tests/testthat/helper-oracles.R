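# Independent brute-force oracles and small fixture builders.
#
# The oracles identify each branch by the child node of its edge and build
# leaf->root path sets from ape::nodepath, a different route than the
# postorder accumulation used by the implementation.

# list of edge-index sets: for each tip, the edges on its root path
oracle_tip_paths <- function(tree) {
  paths <- ape::nodepath(tree)
  lapply(paths, function(p) {
    # every node on the path except the root heads exactly one edge
    match(p[-1], tree$edge[, 2])
  })
}

oracle_faith_pd <- function(tree, present_tips) {
  if (length(present_tips) == 0) return(0)
  paths <- oracle_tip_paths(tree)
  idx <- match(present_tips, tree$tip.label)
  sum(tree$edge.length[unique(unlist(paths[idx]))])
}

oracle_unweighted_unifrac <- function(tree, tips_a, tips_b) {
  paths <- oracle_tip_paths(tree)
  ea <- unique(unlist(paths[match(tips_a, tree$tip.label)]))
  eb <- unique(unlist(paths[match(tips_b, tree$tip.label)]))
  uniq <- c(setdiff(ea, eb), setdiff(eb, ea))
  sum(tree$edge.length[uniq]) / sum(tree$edge.length[union(ea, eb)])
}

# p, q: named relative-abundance vectors over the tips
oracle_weighted_unifrac <- function(tree, p, q) {
  paths <- oracle_tip_paths(tree)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- tree$tip.label[vapply(seq_along(paths),
                                   function(i) e %in% paths[[i]], logical(1))]
    pa <- sum(p[below]); qa <- sum(q[below])
    num <- num + tree$edge.length[e] * abs(pa - qa)
    den <- den + tree$edge.length[e] * (pa + qa)
  }
  num / den
}

random_tree <- function(n_tips, labels = sprintf("t%02d", seq_len(n_tips))) {
  tr <- ape::rtree(n_tips, tip.label = labels)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  tr
}

random_count_table <- function(n_samples, tips) {
  m <- matrix(stats::rpois(n_samples * length(tips), lambda = 3),
              n_samples, length(tips),
              dimnames = list(sprintf("s%02d", seq_len(n_samples)), tips))
  # keep every sample non-empty
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  feature_table(m, unit = "counts")
}

# brute-force average-linkage agglomeration returning merge heights
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# brute-force AUC: fraction of (positive, negative) pairs ranked correctly,
# ties counting one half
oracle_pairwise_auc <- function(labels, scores, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# minimal metadata for a set of subjects x timepoints
make_meta <- function(subjects, timepoints, group = "CD") {
  df <- expand.grid(subject_id = subjects, timepoint = timepoints,
                    stringsAsFactors = FALSE)
  df$sample_id <- paste(df$subject_id, df$timepoint, sep = "_")
  df$group <- group
  validate_metadata(df)
}

# transitions object with fully independent Gaussian blocks: a pure null
# for the dynamic-correlation machinery
make_null_transitions <- function(n_trans, n_genera = 5, n_cyt = 4) {
  g <- sprintf("G%02d", seq_len(n_genera))
  cy <- cytokine_names()[seq_len(n_cyt)]
  rnd <- function(cols) matrix(stats::rnorm(n_trans * length(cols)),
                               n_trans, length(cols),
                               dimnames = list(NULL, cols))
  out <- list(index = tibble::tibble(subject_id = sprintf("S%03d", seq_len(n_trans)),
                                     t_from = "T1", t_to = "T2"),
              bact_from = rnd(g), d_bact = rnd(g),
              cyt_from = rnd(cy), d_cyt = rnd(cy))
  class(out) <- "transitions"
  out
}

# latent analysis-scale cohort whose node series are random walks, so every
# cross-node (and self) level-vs-delta correlation is null until couplings
# are planted
make_walk_cohort <- function(n_subjects, n_genera = 6, n_cyt = 6,
                             timepoints = c("T1", "T2", "T3", "post")) {
  subjects <- sprintf("S%03d", seq_len(n_subjects))
  meta <- make_meta(subjects, timepoints)
  k <- length(timepoints)
  genera <- sprintf("G%02d", seq_len(n_genera))
  bact <- matrix(NA_real_, nrow(meta), n_genera,
                 dimnames = list(meta$sample_id, genera))
  cyts <- cytokine_names()[seq_len(n_cyt)]
  cmat <- matrix(NA_real_, nrow(meta), n_cyt,
                 dimnames = list(meta$sample_id, cyts))
  for (s in subjects) {
    rows <- paste(s, timepoints, sep = "_")
    bact[rows, ] <- apply(matrix(stats::rnorm(k * n_genera), k), 2, cumsum)
    cmat[rows, ] <- 50 + apply(matrix(stats::rnorm(k * n_cyt, sd = 5), k),
                               2, cumsum)
  }
  panel <- tibble::as_tibble(cmat)
  panel$subject_id <- meta$subject_id
  panel$timepoint <- as.character(meta$timepoint)
  for (cyname in setdiff(cytokine_names(), cyts)) panel[[cyname]] <- NA_real_
  panel <- validate_cytokine_panel(panel)
  list(meta = meta, bacteria = bact, panel = panel,
       genera = genera, cytokines = cyts)
}
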