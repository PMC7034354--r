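test_that("transitions pair consecutive observed timepoints per subject", {
  meta <- validate_metadata(tibble::tibble(
    sample_id = c("A_pre", "A_T1", "A_T3", "B_T2"),
    subject_id = c("A", "A", "A", "B"),
    timepoint = c("pre", "T1", "T3", "T2"),
    group = "CD"))
  bz <- matrix(stats::rnorm(8), 4, 2,
               dimnames = list(meta$sample_id, c("G1", "G2")))
  tr <- build_transitions(bz, NULL, meta)
  expect_equal(nrow(tr$index), 2)          # (pre,T1) and (T1,T3); B has none
  expect_equal(tr$index$t_from, c("pre", "T1"))
  expect_equal(tr$index$t_to, c("T1", "T3"))
  expect_equal(tr$d_bact[1, ], bz["A_T1", ] - bz["A_pre", ])
  # calendar-adjacent mode drops the T1 -> T3 gap
  tr2 <- build_transitions(bz, NULL, meta, consecutive_only = TRUE)
  expect_equal(nrow(tr2$index), 1)
})

test_that("a full five-point series yields four transitions per subject", {
  meta <- make_meta(sprintf("S%d", 1:6), timepoint_levels())
  bz <- matrix(stats::rnorm(30 * 3), 30, 3,
               dimnames = list(meta$sample_id, c("G1", "G2", "G3")))
  tr <- build_transitions(bz, NULL, meta)
  expect_equal(nrow(tr$index), 4 * 6)
  expect_true(all(table(tr$index$subject_id) == 4))
})

test_that("a deterministic coupling yields r = 1 at the minimal p", {
  set.seed(151)
  tr <- make_null_transitions(20)
  tr$d_bact[, "G02"] <- tr$bact_from[, "G01"]   # change == source level
  ed <- dynamic_correlations(tr)
  hit <- ed[ed$source == "G01" & ed$target == "G02" &
              ed$family == "bact_to_dbact", ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_lt(hit$p, 1e-30)
  expect_equal(hit$sign, "+")
})

test_that("edge sign flips when the target is negated; |r| is invariant", {
  set.seed(161)
  tr <- make_null_transitions(15)
  ed1 <- dynamic_correlations(tr)
  tr2 <- tr; tr2$d_cyt <- -tr2$d_cyt
  ed2 <- dynamic_correlations(tr2)
  fam <- ed1$family == "bact_to_dcyt"
  expect_equal(ed1$r[fam], -ed2$r[fam])
  expect_equal(abs(ed1$r), abs(ed2$r))
  expect_equal(ed1$p, ed2$p, tolerance = 1e-12)
})

test_that("directional families are asymmetric by construction", {
  set.seed(171)
  tr <- make_null_transitions(40, n_genera = 3, n_cyt = 2)
  # couple bacteria level -> cytokine change only
  tr$d_cyt[, "IL4"] <- 0.9 * tr$bact_from[, "G01"] +
    stats::rnorm(40, sd = 0.3)
  ed <- dynamic_correlations(tr)
  fwd <- ed[ed$family == "bact_to_dcyt" & ed$source == "G01" &
              ed$target == "IL4", ]
  rev <- ed[ed$family == "cyt_to_dbact" & ed$source == "IL4" &
              ed$target == "G01", ]
  expect_lt(fwd$p, 0.001)
  expect_gt(rev$p, 0.01)
})

test_that("self-pairs exist only in the bacteria -> delta-bacteria family", {
  set.seed(181)
  tr <- make_null_transitions(10)
  ed <- dynamic_correlations(tr)
  self <- ed[ed$source == ed$target, ]
  expect_true(all(self$family == "bact_to_dbact"))
  expect_equal(nrow(self), ncol(tr$bact_from))
})

test_that("scrambling is seeded, bit-identical, and never uses the identity", {
  set.seed(191)
  tr <- make_null_transitions(12)
  n1 <- scramble_null(tr, n_scrambles = 10, seed = 99)
  n2 <- scramble_null(tr, n_scrambles = 10, seed = 99)
  expect_identical(n1, n2)
  expect_error(scramble_null(tr, n_scrambles = 0), "at least 1")
  # with 2 transitions the only non-identity permutation is the swap, so a
  # scramble must change the correlations deterministically
  tr2 <- make_null_transitions(2)
  expect_error(dynamic_correlations(tr2), "at least 3")
})

test_that("null edges pass the 0.01 threshold at about the nominal rate", {
  set.seed(201)
  rates <- replicate(30, {
    tr <- make_null_transitions(40)
    ed <- dynamic_correlations(tr)
    mean(ed$p < 0.01)
  })
  pooled <- mean(rates)
  # 30 reps x 65 tests; generous binomial band around 0.01
  expect_lt(abs(pooled - 0.01), 0.01)
})

test_that("assembly thresholds, deduplicates, and finds planted hubs", {
  ed <- tibble::tibble(source = c("G1", "G2"), target = c("IL6", "G3"),
                       family = c("bact_to_dcyt", "bact_to_dbact"),
                       r = c(0.5, -0.4), n = 30, p = c(0.5, 0.2),
                       sign = c("+", "-"))
  net <- assemble_network(ed, threshold = 0.01)
  expect_equal(nrow(net$edges), 0)                 # nothing passes
  expect_true(is.na(net$hub_bacteria))

  # planted star: five bacteria drive the change of one hub genus
  set.seed(211)
  co <- make_walk_cohort(20, n_genera = 7, n_cyt = 3)
  star <- tibble::tibble(source = sprintf("G%02d", 1:5), target = "G07",
                         family = "bact_to_dbact", beta = 1)
  pl <- plant_dynamic_couplings(co$bacteria, co$panel, co$meta, star,
                                noise_sd = 0.4, seed = 3)
  tr <- build_transitions(pl$bacteria, pl$panel, co$meta)
  net2 <- assemble_network(dynamic_correlations(tr), threshold = 0.01)
  expect_equal(net2$hub_bacteria, "G07")
  deg <- net2$degrees[net2$degrees$family == "bact_to_dbact", ]
  expect_gte(deg$in_degree[deg$node == "G07"], 4)

  # Benjamini-Hochberg mode keeps a comparable (here: subset) edge set
  ed_all <- dynamic_correlations(tr)
  fixed <- assemble_network(ed_all, 0.01, method = "fixed")
  bh <- assemble_network(ed_all, 0.01, method = "BH")
  key <- function(n) paste(n$edges$source, n$edges$target, n$edges$family)
  expect_true(all(key(bh) %in% key(fixed)) || all(key(fixed) %in% key(bh)))
})

test_that("planted couplings are recovered in all three families", {
  set.seed(221)
  co <- make_walk_cohort(20)
  edges <- tibble::tibble(
    source = c("G01", "IL6", "G03"),
    target = c("IL8", "G02", "G04"),
    family = c("bact_to_dcyt", "cyt_to_dbact", "bact_to_dbact"),
    beta = c(8, 0.15, 0.9))
  pl <- plant_dynamic_couplings(co$bacteria, co$panel, co$meta, edges,
                                noise_sd = 0.5, seed = 5)
  tr <- build_transitions(pl$bacteria, pl$panel, co$meta)
  expect_equal(nrow(tr$index), 60)
  net <- assemble_network(dynamic_correlations(tr), 0.01)
  found <- dplyr::semi_join(net$edges, edges,
                            by = c("source", "target", "family"))
  expect_equal(nrow(found), 3)
  expect_true(all(found$sign == "+"))
  # network exports round-trip through igraph and disk
  ig <- as_igraph(net)
  expect_equal(igraph::ecount(ig), nrow(net$edges))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, tsv, gml)
  expect_true(file.exists(gml))
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)),
               nrow(net$edges))
  expect_s3_class(autoplot(net), "ggplot")
})
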