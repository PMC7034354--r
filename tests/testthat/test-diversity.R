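test_that("Faith's PD matches hand computations on the 3-leaf tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tab <- matrix(c(5, 0, 0,
                  1, 1, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("sA", "sAll"), c("A", "B", "C")))
  pd <- faith_pd(tab, tr)
  expect_equal(pd[["sA"]], 2)     # A's branch + shared internal branch
  expect_equal(pd[["sAll"]], 5)   # the whole tree
})

test_that("Faith's PD equals the root-path-union oracle and is monotone", {
  set.seed(21)
  for (rep in 1:15) {
    tr <- random_tree(sample(5:20, 1))
    present <- sample(tr$tip.label, sample(1:length(tr$tip.label), 1))
    tab <- matrix(0, 1, length(tr$tip.label),
                  dimnames = list("s1", tr$tip.label))
    tab[1, present] <- 1
    expect_equal(unname(faith_pd(tab, tr)), oracle_faith_pd(tr, present),
                 tolerance = 1e-12)
    # adding one more observed leaf can only increase PD
    absent <- setdiff(tr$tip.label, present)
    if (length(absent)) {
      tab2 <- tab; tab2[1, sample(absent, 1)] <- 1
      expect_gte(unname(faith_pd(tab2, tr)), unname(faith_pd(tab, tr)))
    }
  }
})

test_that("empty samples get PD 0 with a warning", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  tab <- matrix(0, 1, 3, dimnames = list("s0", c("A", "B", "C")))
  expect_warning(pd <- faith_pd(tab, tr), "no observed")
  expect_equal(unname(pd), 0)
})

test_that("UniFrac satisfies its defining identities", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tab <- matrix(c(1, 1, 0, 0,
                  0, 0, 1, 1,
                  1, 1, 0, 0), 3, 4, byrow = TRUE,
                dimnames = list(c("left", "right", "left2"), LETTERS[1:4]))
  du <- unifrac(feature_table(tab, "counts") |> to_relabund(), tr,
                weighted = FALSE)
  expect_equal(du["left", "left2"], 0)        # identical composition
  expect_equal(du["left", "right"], 1)        # disjoint subtrees under root
  dw <- unifrac(feature_table(tab, "counts") |> to_relabund(), tr,
                weighted = TRUE)
  expect_equal(dw["left", "left2"], 0)
  expect_equal(dw["left", "right"], 1)
})

test_that("both UniFrac variants match brute-force branch enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- random_tree(sample(5:15, 1))
    tab <- random_count_table(4, tr$tip.label)
    rel <- unclass(to_relabund(tab))
    du <- unifrac(tab, tr, weighted = FALSE)
    dw <- unifrac(tab, tr, weighted = TRUE)
    for (i in 1:3) for (j in (i + 1):4) {
      tips_i <- colnames(rel)[rel[i, ] > 0]
      tips_j <- colnames(rel)[rel[j, ] > 0]
      expect_equal(du[i, j], oracle_unweighted_unifrac(tr, tips_i, tips_j),
                   tolerance = 1e-10)
      expect_equal(dw[i, j], oracle_weighted_unifrac(tr, rel[i, ], rel[j, ]),
                   tolerance = 1e-10)
    }
    expect_true(isSymmetric(unclass(du)))
    expect_true(all(du >= 0 & du <= 1) && all(dw >= 0 & dw <= 1))
    expect_true(all(diag(du) == 0) && all(diag(dw) == 0))
  }
})

test_that("faith_pd agrees with picante on a shared instance", {
  skip_if_not_installed("picante")
  set.seed(41)
  tr <- random_tree(12)
  tab <- random_count_table(5, tr$tip.label)
  ours <- faith_pd(tab, tr)
  theirs <- picante::pd(unclass(tab), tr, include.root = TRUE)$PD
  expect_equal(unname(ours), theirs, tolerance = 1e-10)
})

test_that("depth filter removes shallow samples and rarefies to exact depth", {
  set.seed(51)
  m <- matrix(stats::rpois(8 * 20, 40), 8, 20,
              dimnames = list(sprintf("s%d", 1:8), sprintf("f%d", 1:20)))
  m[1, ] <- 0; m[1, 1] <- 100          # shallow sample
  tab <- feature_table(m, "counts")
  rar <- depth_filter_and_rarefy(tab, depth = 500, seed = 3)
  expect_false("s1" %in% rownames(rar))
  expect_equal(attr(rar, "dropped_samples"), "s1")
  expect_true(all(rowSums(rar) == 500))
  # sample at exactly the target depth is retained unchanged
  m2 <- m[-1, ]; m2[1, ] <- 0; m2[1, 1:5] <- 100
  rar2 <- depth_filter_and_rarefy(feature_table(m2, "counts"), depth = 500,
                                  seed = 3)
  expect_equal(unclass(rar2)[1, 1:5], m2[1, 1:5])
  expect_error(depth_filter_and_rarefy(tab, depth = 1e7), "below depth")
})

test_that("rarefaction preserves expected relative abundances", {
  set.seed(61)
  v <- c(a = 4000, b = 1000, c = 500, d = 100)
  tab <- feature_table(matrix(v, 1, 4, dimnames = list("s1", names(v))),
                       "counts")
  draws <- sapply(1:200, function(i) {
    unclass(depth_filter_and_rarefy(tab, depth = 1000, seed = i))[1, ] / 1000
  })
  p <- v / sum(v)
  se <- sqrt(p * (1 - p) / 1000) / sqrt(200)
  expect_true(all(abs(rowMeans(draws) - p) <= 3 * se + 1e-12))
})

test_that("shannon is in bits and a singleton sample has zero diversity", {
  m <- matrix(c(1, 1, 0, 0,
                7, 0, 0, 0,
                1, 1, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("even2", "single", "even4"), letters[1:4]))
  sp <- shannon_pielou(m)
  expect_equal(sp$shannon, c(1, 0, 2))   # log2 convention
  expect_equal(sp$pielou, c(1, NA, 1))
  expect_equal(sp$richness, c(2, 1, 4))
})

test_that("alpha comparisons dispatch by group count and handle ties", {
  alpha <- tibble::tibble(sample_id = sprintf("s%d", 1:12),
                          faith_pd = c(rep(1, 6), rep(1, 6)),
                          shannon = stats::rnorm(12),
                          pielou = stats::runif(12))
  g2 <- rep(c("IBD", "control"), each = 6)
  res <- alpha_compare(alpha, g2)
  expect_equal(unique(res$test), "mann_whitney")
  expect_equal(res$p[res$metric == "faith_pd"], 1)   # all-tie data
  g3 <- rep(c("CD", "UC", "control"), each = 4)
  res3 <- alpha_compare(alpha, g3, metrics = "shannon")
  expect_equal(res3$test, "kruskal_wallis")
  expect_error(alpha_compare(alpha, c("a", rep("b", 11))), ">= 2")
})
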