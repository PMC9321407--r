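# Tetra-nucleosome features, group routing, classifier harness, folding
# ratios and their resampling significance.

test_that("features equal a dense-submatrix oracle", {
  map <- toy_map(n_nodes = 15, seed = 81, lam = 4)
  feats <- extract_features(map)
  M <- dense_counts(map)
  expect_equal(nrow(feats), 15 - 3)           # i = 2..n-2 eligible
  expect_equal(attr(feats, "n_skipped"), 3L)
  for (r in seq_len(nrow(feats))) {
    i <- feats$node[r]
    sub <- M[(i - 1):(i + 2), (i - 1):(i + 2)]
    oracle <- sub[upper.tri(sub, diag = TRUE)]
    # row-major upper triangle vs R column-major: reorder
    rm_order <- c(1, 2, 4, 7, 3, 5, 8, 6, 9, 10)
    vec <- unlist(feats[r, sprintf("f%d", 1:10), with = FALSE])
    expect_equal(unname(vec), oracle[rm_order])
    expect_equal(feats$contact_sum[r], sum(oracle))
  }
})

test_that("an all-ones submatrix gives ten 1s with contact sum 10", {
  nodes <- data.table::data.table(chrom = "c",
                                  dyad = c(200L, 400L, 600L, 800L),
                                  node = 1:4)
  pr <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  edges <- data.table::data.table(chrom = "c", node_i = pr[, 1],
                                  node_j = pr[, 2], count = 1L)
  data.table::set(edges, NULL, "dist",
                  abs(nodes$dyad[edges$node_j] - nodes$dyad[edges$node_i]))
  map <- structure(list(nodes = nodes, edges = edges,
                        assignments = data.table::data.table(),
                        self_count = 0L, skipped = 0L),
                   class = "nuc_contact_map")
  feats <- extract_features(map)
  expect_equal(nrow(feats), 1)
  expect_equal(unname(unlist(feats[1, sprintf("f%d", 1:10),
                                   with = FALSE])),
               rep(1, 10))
  expect_equal(feats$contact_sum, 10)
})

test_that("group boundaries are left-inclusive", {
  f <- data.table::data.table(contact_sum = c(150, 199.9, 200, 399, 400,
                                              600, 1e4))
  g <- group_features(f)$group
  expect_equal(g, c(1L, 1L, 2L, 2L, 3L, 4L, 4L))
})

sep_features <- function(n_per_group = 240, seed = 82) {
  # linearly separable toy problem: alpha iff f1 > f2, planted per group
  set.seed(seed)
  gsum <- rep(c(250, 450, 700), each = n_per_group)
  f1 <- stats::runif(3 * n_per_group, 0, gsum / 5)
  f2 <- stats::runif(3 * n_per_group, 0, gsum / 5)
  feats <- data.table::data.table(f1 = f1, f2 = f2)
  for (k in 3:10) data.table::set(feats, NULL, sprintf("f%d", k), gsum / 10)
  data.table::set(feats, NULL, "chrom", "c")
  data.table::set(feats, NULL, "node", seq_len(nrow(feats)))
  data.table::set(feats, NULL, "contact_sum", gsum)
  feats <- group_features(feats)
  labels <- factor(ifelse(f1 > f2, "alpha", "beta"),
                   levels = c("alpha", "beta"))
  list(features = feats, labels = labels)
}

fast_classifiers <- function() {
  default_classifiers()[c("knn", "decision_tree", "naive_bayes")]
}

test_that("the harness reaches F1 = 1 on separable labels and is seeded", {
  d <- sep_features()
  tm <- train_select(d$features, d$labels, classifiers = fast_classifiers(),
                     seed = 7)
  expect_setequal(names(tm$models), c("2", "3", "4"))
  for (g in names(tm$models)) expect_gte(tm$models[[g]]$f1, 0.95)
  tm2 <- train_select(d$features, d$labels,
                      classifiers = fast_classifiers(), seed = 7)
  expect_identical(tm$selected, tm2$selected)
  expect_equal(tm$report$f1, tm2$report$f1)
})

test_that("permuted labels drive the best F1 towards chance", {
  d <- sep_features(n_per_group = 1400, seed = 83)
  set.seed(84)
  perm <- sample(d$labels)
  tm <- train_select(d$features, perm, classifiers = fast_classifiers(),
                     seed = 8)
  # chance-level F1 lies between balanced prediction (0.5) and the
  # degenerate all-positive predictor (2/3); selection takes the max, so
  # bound it rather than centering on 0.5
  for (g in names(tm$models)) {
    expect_gt(tm$models[[g]]$f1, 0.35)
    expect_lt(tm$models[[g]]$f1, 0.72)
  }
})

test_that("group 1 is never predicted and empty input passes through", {
  d <- sep_features()
  tm <- train_select(d$features, d$labels, classifiers = fast_classifiers())
  g1 <- data.table::copy(d$features[1:5, ])
  data.table::set(g1, NULL, "contact_sum", 50)
  g1 <- group_features(g1)
  expect_true(all(predict_motifs(g1, tm) == "unpredicted"))
  empty <- d$features[0, ]
  expect_equal(length(predict_motifs(empty, tm)), 0)
  # predictions are deterministic given fitted models
  p1 <- predict_motifs(d$features, tm)
  expect_identical(p1, predict_motifs(d$features, tm))
})

test_that("single-class groups are skipped with a warning", {
  d <- sep_features()
  lab <- d$labels
  lab[d$features$group == 2] <- "alpha"
  expect_warning(train_select(d$features, lab,
                              classifiers = fast_classifiers()),
                 "single label class")
})

make_labels <- function(n_alpha, n_beta) {
  factor(c(rep("alpha", n_alpha), rep("beta", n_beta)),
         levels = c("alpha", "beta"))
}

test_that("folding ratios reproduce the published regional odds ratios", {
  genome <- make_labels(514, 486)
  cases <- list(weak_boundaries = list(c(692, 308), 2.12),
                stripes = list(c(554, 446), 1.17),
                compartment_A = list(c(546, 454), 1.14),
                compartment_B = list(c(468, 532), 0.83),
                lamina = list(c(376, 624), 0.57))
  for (cs in cases) {
    local <- make_labels(cs[[1]][1], cs[[1]][2])
    expect_equal(round(folding_ratio(local, genome)$ratio, 2), cs[[2]])
  }
  # equal proportions give exactly 1
  expect_equal(folding_ratio(make_labels(257, 243), genome)$ratio, 1)
})

test_that("folding ratio is antisymmetric under label swap and scale-free", {
  local <- make_labels(70, 30)
  genome <- make_labels(510, 490)
  r <- folding_ratio(local, genome)$ratio
  swap <- function(x) factor(ifelse(x == "alpha", "beta", "alpha"),
                             levels = c("alpha", "beta"))
  r_sw <- folding_ratio(swap(local), swap(genome))$ratio
  expect_equal(r * r_sw, 1)
  r10 <- folding_ratio(make_labels(700, 300), make_labels(5100, 4900))$ratio
  expect_equal(r10, r)
  expect_error(folding_ratio(make_labels(10, 0), genome), "positive")
})

test_that("resampling significance separates real from null enrichment", {
  set.seed(85)
  genome <- make_labels(2500, 2500)[sample(5000)]
  # local drawn from the genome itself: p should usually be unremarkable
  p_null <- vapply(1:50, function(s) {
    loc <- genome[sample(5000, 200)]
    ratio_significance(loc, genome, n_resamples = 200, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.9)
  # extreme separation: all-alpha local set
  p_ext <- ratio_significance(make_labels(499, 1), genome,
                              n_resamples = 200, seed = 1)$p_value
  expect_lt(p_ext, 1e-6)
  # reproducible under a fixed seed
  p_a <- ratio_significance(make_labels(120, 80), genome, seed = 42)
  p_b <- ratio_significance(make_labels(120, 80), genome, seed = 42)
  expect_equal(p_a$p_value, p_b$p_value)
  expect_error(ratio_significance(make_labels(5, 5), genome), "20")
})

test_that("synthetic label slope reproduces rising alpha fractions by group", {
  map <- toy_map(n_nodes = 600, seed = 86, lam = 40)
  feats <- extract_features(map)
  expect_gt(length(unique(feats$group)), 1)
  labels <- make_tetra_labels(feats, slope = 0.002, seed = 87)
  tm <- train_select(feats, labels, classifiers = fast_classifiers(),
                     seed = 88)
  pred <- predict_motifs(feats, tm)
  frac <- vapply(sort(unique(feats$group[feats$group > 1])), function(g) {
    mean(pred[feats$group == g] == "alpha")
  }, numeric(1))
  if (length(frac) > 1) {
    expect_gt(frac[length(frac)], frac[1])
  }
})
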