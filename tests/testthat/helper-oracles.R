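# Independent, deliberately naive reference implementations used as oracles.

# Entropy by direct summation over the distinct labels.
oracle_entropy <- function(labels) {
  n <- length(labels)
  h <- 0
  for (lev in unique(labels)) {
    p <- sum(labels == lev) / n
    h <- h - p * log(p, base = 2)
  }
  h
}

# Upper-tail hypergeometric probability by summing the pmf term by term.
oracle_hyper_sum <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i) / choose(N, n))
}

# Upper-tail hypergeometric probability by enumerating every n-subset of the
# universe and counting how many overlap the K-set by >= k. Exact but O(C(N,n)).
oracle_hyper_enum <- function(k, K, n, N) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  draws <- utils::combn(universe, n)
  mean(apply(draws, 2, function(d) sum(d %in% inset) >= k))
}

# Exhaustive best split: every (feature, midpoint-threshold) pair scored with
# information_gain on the actual label partitions.
oracle_best_split <- function(x, y) {
  best <- list(ig = -Inf)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (thr in (v[-length(v)] + v[-1]) / 2) {
      left <- y[x[, j] <= thr]
      right <- y[x[, j] > thr]
      ig <- information_gain(y, left, right)
      if (ig > best$ig + 1e-12)
        best <- list(feature = colnames(x)[j], threshold = thr, ig = ig)
    }
  }
  best
}

# Naive average-linkage agglomeration on a distance matrix: returns merge
# heights in order, for comparison with hclust.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      h <- mean(d[active[[a]], active[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    heights <- c(heights, best[1])
    merged <- c(active[[best[2]]], active[[best[3]]])
    active <- active[-c(best[2], best[3])]
    active[[length(active) + 1]] <- merged
  }
  heights
}

# Rand index between two flat partitions given as label vectors.
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / choose(n, 2)
}

# Re-evaluate the relative-importance sum of one stored tree from first
# principles: walk the tree on its recorded training fold, recompute every
# node's information gain from the actual label partition, recompute the
# held-out class-balanced accuracy, and assemble each feature's contribution.
oracle_tree_ri <- function(expr, tree_rec, u = 1, v = 1) {
  tree <- tree_rec$tree
  xt <- t(expr$values)[, tree_rec$features, drop = FALSE]
  train <- xt[tree_rec$train_idx, , drop = FALSE]
  ytr <- expr$labels[tree_rec$train_idx]
  n_train <- nrow(train)

  # recompute held-out class-balanced accuracy
  test <- xt[tree_rec$test_idx, , drop = FALSE]
  yte <- as.character(expr$labels[tree_rec$test_idx])
  pred <- predict(tree, test)
  recalls <- vapply(unique(yte),
                    function(cl) mean(pred[yte == cl] == cl), numeric(1))
  wacc <- mean(recalls)

  ri <- numeric(0)
  walk <- function(node_id, idx) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) return(invisible())
    go_left <- train[idx, node$feature] <= node$threshold
    ig <- information_gain(ytr[idx], ytr[idx][go_left], ytr[idx][!go_left])
    contrib <- wacc^u * ig * (length(idx) / n_train)^v
    ri[node$feature] <<- if (node$feature %in% names(ri))
      ri[node$feature] + contrib else contrib
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(1, seq_len(n_train))
  list(ri = ri, wacc = wacc)
}

# Small balanced three-phase dataset for classifier tests.
make_blob_expr <- function(n_per_class = 10, n_features = 2, sep = 4, seed = 1) {
  set.seed(seed)
  classes <- c("D0", "D30", "Y1")
  n <- n_per_class * 3
  vals <- matrix(rnorm(n_features * n), n_features, n)
  for (k in 1:3) {
    cols <- ((k - 1) * n_per_class + 1):(k * n_per_class)
    vals[, cols] <- vals[, cols] + (k - 1) * sep
  }
  dimnames(vals) <- list(paste0("f", seq_len(n_features)),
                         sprintf("s%02d", seq_len(n)))
  expr_matrix(vals, rep(classes, each = n_per_class))
}
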