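test_that("entropy and information gain match hand values and brute-force enumeration", {
  expect_equal(entropy(c("A", "A", "A")), 0)
  expect_equal(entropy(c("A", "A", "B", "B")), 1)
  expect_equal(entropy(c("A", "A", "A", "B")), 0.8112781244591328)
  expect_error(entropy(character(0)), "empty")

  expect_equal(information_gain(c("A", "A", "B", "B"), c("A", "A"), c("B", "B")), 1)
  expect_equal(information_gain(c("A", "A", "B", "B"), c("A", "B"), c("A", "B")), 0)
  expect_equal(information_gain(c("A", "A", "A", "B"), c("A", "A"), c("A", "B")),
               0.8112781244591328 - 0.5)
  expect_error(information_gain(c("A", "B"), c("A"), c("C")), "partition")

  # brute-force oracle over random small multisets
  set.seed(11)
  for (rep in 1:25) {
    labs <- sample(LETTERS[1:3], sample(2:12, 1), replace = TRUE)
    expect_equal(entropy(labs), oracle_entropy(labs))
    cut <- sample(seq_len(length(labs) - 1), 1)
    expect_equal(information_gain(labs, labs[1:cut], labs[-(1:cut)]),
                 max(oracle_entropy(labs) -
                       (cut * oracle_entropy(labs[1:cut]) +
                          (length(labs) - cut) * oracle_entropy(labs[-(1:cut)])) /
                       length(labs), 0))
  }
})

test_that("tree growth finds the exhaustive-search split and handles degenerate input", {
  # perfectly separable 1-D, two classes: depth-1 tree, root IG = parent entropy
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1, dimnames = list(NULL, "f1"))
  y <- factor(rep(c("A", "B"), each = 3))
  tr <- build_tree(x, y)
  root <- tr$nodes[[1]]
  expect_false(root$leaf)
  expect_equal(root$ig, entropy(y))
  expect_true(tr$nodes[[root$left]]$leaf && tr$nodes[[root$right]]$leaf)
  expect_identical(unname(predict(tr, x)), rep(c("A", "B"), each = 3))

  # constant features: no valid split, single leaf
  xc <- matrix(5, 6, 2, dimnames = list(NULL, c("f1", "f2")))
  trc <- build_tree(xc, y)
  expect_length(trc$nodes, 1)
  expect_true(trc$nodes[[1]]$leaf)

  # 30-sample 3-class toy set: root split equals brute-force search
  set.seed(21)
  x3 <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y3 <- factor(rep(c("A", "B", "C"), each = 10))
  x3[, 2] <- x3[, 2] + 1.5 * as.integer(y3)
  tr3 <- build_tree(x3, y3)
  oracle <- oracle_best_split(x3, y3)
  expect_identical(tr3$nodes[[1]]$feature, oracle$feature)
  expect_equal(tr3$nodes[[1]]$threshold, oracle$threshold)
  expect_equal(tr3$nodes[[1]]$ig, oracle$ig)
})

test_that("class-balanced accuracy is the macro-average of per-class recalls", {
  expect_equal(weighted_accuracy(diag(3)), 1)
  cm <- rbind(c(47, 12, 6), c(2, 58, 4), c(1, 3, 33))
  expect_equal(weighted_accuracy(cm), mean(c(47 / 65, 58 / 64, 33 / 37)))
  expect_equal(weighted_accuracy(rbind(c(5, 0), c(3, 0))), 0.5)
  expect_error(weighted_accuracy(matrix(0, 2, 2)), "no actual samples")
  # zero rows (classes absent from the held-out set) are ignored
  expect_equal(weighted_accuracy(rbind(c(4, 0), c(0, 0))), 1)
})

test_that("single-tree relative importance equals a first-principles re-evaluation", {
  sp <- synthetic_spec(n_genes = 12, n_samples_per_phase = c(10, 10, 8),
                       n_informative = 3, effect_size = 2.5, seed = 5)
  g <- generate_synthetic(sp)
  params <- mcfs_params(s = 1, t = 1, m = 6, seed = 17)
  r <- mcfs_rank(g$expr, params, keep_trees = TRUE)
  rec <- attr(r, "trees")[[1]]
  oracle <- oracle_tree_ri(g$expr, rec, u = 1, v = 1)
  expect_equal(rec$wacc, oracle$wacc, tolerance = 1e-12)
  ri <- setNames(r$ri, r$feature_id)
  for (f in names(oracle$ri))
    expect_equal(unname(ri[f]), unname(oracle$ri[f]), tolerance = 1e-9, info = f)
  expect_true(all(ri[setdiff(names(ri), names(oracle$ri))] == 0))
})

test_that("relative importance is additive over subset-budget partitions", {
  sp <- synthetic_spec(n_genes = 40, n_samples_per_phase = c(8, 8, 8),
                       n_informative = 4, seed = 2)
  g <- generate_synthetic(sp)
  p_full <- mcfs_params(s = 6, t = 2, m = 10, seed = 9)
  full <- mcfs_rank(g$expr, p_full)
  h1 <- mcfs_rank(g$expr, mcfs_params(s = 3, t = 2, m = 10, seed = 9))
  h2 <- mcfs_rank(g$expr, mcfs_params(s = 3, t = 2, m = 10, seed = 9),
                  subset_offset = 3)
  ri_full <- setNames(full$ri, full$feature_id)
  ri_sum <- setNames(h1$ri, h1$feature_id)[names(ri_full)] +
    setNames(h2$ri, h2$feature_id)[names(ri_full)]
  expect_equal(unname(ri_sum), unname(ri_full), tolerance = 1e-9)
})

test_that("u = v = 0 reduces importance to the raw per-feature gain sum over stored trees", {
  sp <- synthetic_spec(n_genes = 25, n_samples_per_phase = c(8, 8, 6),
                       n_informative = 3, seed = 13)
  g <- generate_synthetic(sp)
  r <- mcfs_rank(g$expr, mcfs_params(s = 4, t = 2, m = 8, u = 0, v = 0, seed = 4),
                 keep_trees = TRUE)
  trees <- attr(r, "trees")
  ig_sum <- setNames(numeric(nrow(r)), sort(r$feature_id))
  for (rec in trees) {
    for (node in rec$tree$nodes) {
      if (!node$leaf) ig_sum[node$feature] <- ig_sum[node$feature] + node$ig
    }
  }
  ri <- setNames(r$ri, r$feature_id)[names(ig_sum)]
  expect_equal(unname(ri), unname(ig_sum), tolerance = 1e-9)
  expect_true(all(r$ri >= 0))
})

test_that("features never drawn into a subset score exactly zero", {
  sp <- synthetic_spec(n_genes = 60, n_samples_per_phase = c(6, 6, 6),
                       n_informative = 0, seed = 3)
  g <- generate_synthetic(sp)
  r <- mcfs_rank(g$expr, mcfs_params(s = 2, t = 1, m = 5, seed = 8),
                 keep_trees = TRUE)
  drawn <- unique(unlist(lapply(attr(r, "trees"), `[[`, "features")))
  ri <- setNames(r$ri, r$feature_id)
  expect_true(all(ri[setdiff(names(ri), drawn)] == 0))
})

test_that("under a label-free null no feature's importance dominates", {
  # pure-noise features, random labels: RI spread stays flat. The bound is an
  # ensemble property, so the cohort must be large enough for per-tree gain
  # sums to concentrate; 30 samples per phase suffices.
  sp <- synthetic_spec(n_genes = 50, n_samples_per_phase = c(30, 30, 30),
                       n_informative = 0, seed = 19)
  g <- generate_synthetic(sp)
  r <- mcfs_rank(g$expr, mcfs_params(s = 100, t = 5, m = 10, seed = 19))
  expect_true(max(r$ri) <= 3 * median(r$ri))
})

test_that("stronger planted effects never worsen the expected rank of informative genes", {
  mean_rank <- function(effect) {
    ranks <- vapply(1:20, function(sd) {
      g <- generate_synthetic(synthetic_spec(
        n_genes = 60, n_samples_per_phase = c(8, 8, 8),
        n_informative = 3, effect_size = effect, seed = 100 + sd))
      r <- mcfs_rank(g$expr, mcfs_params(s = 15, t = 2, m = 12, seed = 100 + sd))
      mean(match(g$truth$gene, r$feature_id))
    }, numeric(1))
    mean(ranks)
  }
  weak <- mean_rank(0.5)
  strong <- mean_rank(2.5)
  expect_lt(strong, weak)
})

test_that("ranking files round-trip and the order is descending with stable ties", {
  sp <- synthetic_spec(n_genes = 30, n_samples_per_phase = c(6, 6, 6),
                       n_informative = 2, seed = 23)
  g <- generate_synthetic(sp)
  r <- mcfs_rank(g$expr, mcfs_params(s = 3, t = 1, m = 6, seed = 2))
  expect_true(all(diff(r$ri) <= 0))
  zero <- r$feature_id[r$ri == 0]
  expect_identical(zero, sort(zero))  # ties broken by ascending feature id
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(r, path)
  r2 <- read_ranking(path)
  expect_equal(r2$ri, r$ri)
  expect_identical(r2$feature_id, r$feature_id)
})
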