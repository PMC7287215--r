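test_that("LOOCV is perfect on well-separated classes and its confusion sums to n", {
  em <- make_blob_expr(n_per_class = 10, sep = 4, seed = 1)
  res <- loocv_evaluate(em)
  expect_equal(res$accuracy, 1)
  expect_equal(unname(diag(res$confusion)), rep(10L, 3))
  expect_equal(sum(res$confusion), 30)
  expect_equal(overall_accuracy(res$confusion), res$accuracy)
})

test_that("LOOCV on permuted labels sits at chance for three balanced classes", {
  # leave-one-out is slightly pessimistic under the null (the held-out class
  # is underrepresented in its training fold), so the cohort must be large
  # enough for that bias to stay inside the binomial band: 30 per class.
  set.seed(33)
  n <- 90
  vals <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(paste0("f", 1:20), sprintf("s%02d", 1:n)))
  em <- expr_matrix(vals, sample(rep(c("D0", "D30", "Y1"), each = 30)))
  res <- loocv_evaluate(em)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(res$accuracy - 1 / 3), 3 * se)
})

test_that("1-NN LOOCV reproduces a hand-executed fold-by-fold trace", {
  # feature values 0,1,5,4,8,9; nearest neighbours under LOOCV:
  # 0->1(A) ok, 1->0(A) ok, 5->4(B) wrong, 4->5(A) wrong, 8->9(B) ok, 9->8(B) ok
  vals <- matrix(c(0, 1, 5, 4, 8, 9), 1, 6,
                 dimnames = list("f1", paste0("s", 1:6)))
  em <- expr_matrix(vals, c("A", "A", "A", "B", "B", "B"))
  res <- loocv_evaluate(em, classifier = knn_classifier(1))
  expect_equal(res$accuracy, 4 / 6)
  expect_equal(unname(res$confusion),
               rbind(c(2L, 1L), c(1L, 2L)))
})

test_that("overall accuracy is trace over total", {
  cm <- rbind(c(47, 12, 6), c(2, 58, 4), c(1, 3, 33))
  expect_equal(overall_accuracy(cm), 138 / 166)
  expect_equal(overall_accuracy(diag(4)), 1)
  expect_equal(overall_accuracy(rbind(c(0, 3), c(2, 0))), 0)
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
})

test_that("the plateau rule picks the smallest near-maximal feature count", {
  pts <- data.frame(n_features = c(1, 2, 3), accuracy = c(0.5, 0.9, 0.9))
  expect_equal(select_optimal(pts, epsilon = 0), 2)
  flat <- data.frame(n_features = c(5, 10, 20), accuracy = rep(0.7, 3))
  expect_equal(select_optimal(flat), 5)
  paperlike <- data.frame(n_features = c(10, 50, 134, 500),
                          accuracy = c(0.80, 0.829, 0.831, 0.832))
  expect_equal(select_optimal(paperlike, epsilon = 0.005), 50)
})

test_that("incremental selection walks nested prefixes and finds planted signal", {
  sp <- synthetic_spec(n_genes = 80, n_samples_per_phase = c(12, 12, 12),
                       n_informative = 4, effect_size = 3, seed = 6)
  g <- generate_synthetic(sp)
  r <- mcfs_rank(g$expr, mcfs_params(s = 40, t = 3, m = 12, seed = 6))
  curve <- ifs_run(r, g$expr, grid_max = 12)
  expect_identical(curve$points$n_features, curve$grid)
  expect_true(all(diff(curve$grid) > 0))
  expect_true(curve$selected_n %in% curve$grid)
  # selected features are exactly the top-n prefix of the ranking
  expect_identical(curve$selected_features, r$feature_id[seq_len(curve$selected_n)])
  expect_equal(sum(curve$confusion), ncol(g$expr$values))
  expect_equal(overall_accuracy(curve$confusion), curve$accuracy)
  # signal carried by the top-ranked planted genes: plateau reached by <= 2k
  expect_lte(curve$selected_n, 8)
  expect_gt(curve$accuracy, 0.9)

  # single-point grid
  one <- ifs_run(r, g$expr, grid = 3)
  expect_equal(one$selected_n, 3)
  expect_equal(nrow(one$points), 1)
})

test_that("IFS results are reproducible and invariant to sample column order", {
  sp <- synthetic_spec(n_genes = 40, n_samples_per_phase = c(8, 8, 8),
                       n_informative = 3, seed = 14)
  g <- generate_synthetic(sp)
  r <- mcfs_rank(g$expr, mcfs_params(s = 10, t = 2, m = 10, seed = 14))
  c1 <- ifs_run(r, g$expr, grid_max = 6)
  c2 <- ifs_run(r, g$expr, grid_max = 6)
  expect_identical(c1$points, c2$points)
  # shuffle sample columns: LOOCV sorts by sample id, so nothing changes
  perm <- sample(ncol(g$expr$values))
  shuffled <- expr_matrix(g$expr$values[, perm], g$expr$labels[perm])
  c3 <- ifs_run(r, shuffled, grid_max = 6)
  expect_equal(c3$points$accuracy, c1$points$accuracy)
  expect_identical(c3$confusion, c1$confusion)
})

test_that("curve, signature and confusion files are written faithfully", {
  em <- make_blob_expr(n_per_class = 5, sep = 5, seed = 2)
  ranking <- data.frame(rank = 1:2, feature_id = c("f1", "f2"), ri = c(2, 1))
  class(ranking) <- c("feature_ranking", "data.frame")
  curve <- ifs_run(ranking, em, grid_max = 2)
  dir <- withr::local_tempdir()
  write_ifs_curve(curve, file.path(dir, "curve.tsv"))
  write_signature(curve, file.path(dir, "sig.tsv"))
  write_confusion(curve, file.path(dir, "conf.tsv"))
  pts <- read.delim(file.path(dir, "curve.tsv"))
  expect_equal(pts$accuracy, curve$points$accuracy)
  sig <- read.delim(file.path(dir, "sig.tsv"))
  expect_identical(sig$feature_id, curve$selected_features)
  conf <- read.delim(file.path(dir, "conf.tsv"))
  expect_equal(as.matrix(conf[, -1]), unname(curve$confusion),
               ignore_attr = TRUE)
})
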