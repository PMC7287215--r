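#' Shannon entropy of a label multiset
#'
#' @param labels Non-empty vector (or factor) of class labels.
#' @return Entropy in bits: `-sum(p_c * log2(p_c))` over observed classes;
#'   0 for a pure set, `log2(c)` for a uniform set over `c` classes.
#' @examples
#' entropy(c("A", "A", "B", "B"))  # 1
#' entropy(c("A", "A", "A"))       # 0
#' @export
entropy <- function(labels) {
  if (length(labels) == 0) stop("entropy of an empty label set is undefined")
  p <- as.vector(table(labels))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

#' Information gain of a binary split
#'
#' Reduction in label entropy achieved by splitting `parent_labels` into the
#' two child multisets, which must exactly partition the parent.
#'
#' @param parent_labels,left_labels,right_labels Label vectors; `left` and
#'   `right` together must equal `parent` as multisets.
#' @return Non-negative information gain in bits.
#' @export
information_gain <- function(parent_labels, left_labels, right_labels) {
  combined <- c(as.character(left_labels), as.character(right_labels))
  if (!identical(sort(combined), sort(as.character(parent_labels))))
    stop("left and right children must partition the parent label multiset")
  n <- length(parent_labels)
  h <- entropy(parent_labels) -
    (length(left_labels) * entropy(left_labels) +
       length(right_labels) * entropy(right_labels)) / n
  max(h, 0)
}

## Row-wise entropy of a matrix of class counts; 0*log0 treated as 0.
.count_entropy <- function(counts) {
  tot <- rowSums(counts)
  s <- rowSums(counts * log2(pmax(counts, 1)))
  ifelse(tot > 0, log2(tot) - s / tot, 0)
}

## Best threshold for one feature: candidate thresholds are midpoints between
## consecutive distinct sorted values; returns the IG-maximizing one.
.best_split_feature <- function(v, y_int, n_class, h_parent) {
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]
  ys <- y_int[ord]
  cuts <- which(vs[-n] < vs[-1])
  if (length(cuts) == 0) return(NULL)
  onehot <- matrix(0L, n, n_class)
  onehot[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(onehot, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  left <- cum[cuts, , drop = FALSE]
  right <- rep(cum[n, ], each = length(cuts)) - left
  dim(right) <- dim(left)
  nl <- cuts
  nr <- n - cuts
  ig <- h_parent - (nl * .count_entropy(left) + nr * .count_entropy(right)) / n
  best <- which.max(ig)
  list(threshold = (vs[cuts[best]] + vs[cuts[best] + 1]) / 2,
       ig = max(ig[best], 0))
}

#' Grow an information-gain decision tree
#'
#' Binary CART-style tree: each internal node stores the (feature, threshold)
#' split maximizing information gain over candidate thresholds placed at
#' midpoints between consecutive distinct sorted values. Growth stops at pure
#' nodes, nodes smaller than `min_samples_split`, `max_depth`, or when no
#' split has positive gain. Ties between equally good splits are broken by
#' feature column order, then by the smaller threshold, so trees are
#' deterministic given the input.
#'
#' @param x Numeric matrix, samples x features, with feature column names.
#' @param y Factor of class labels, one per row of `x`.
#' @param min_samples_split Minimum node size eligible for splitting (default 2).
#' @param max_depth Maximum tree depth (default `Inf`; root depth 0).
#' @return An object of class `ig_tree`: a list with `nodes` (list of node
#'   records carrying `feature`, `threshold`, `ig`, `n_node`, child ids, or a
#'   leaf `class`) and `n_train` (the sample count of the root).
#' @export
build_tree <- function(x, y, min_samples_split = 2, max_depth = Inf) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- factor(y)
  n_class <- nlevels(y)
  y_int <- as.integer(y)
  nodes <- list()
  new_id <- function() length(nodes) + 1L

  grow <- function(idx, depth) {
    id <- new_id()
    nodes[[id]] <<- list()  # reserve slot so child ids come out preorder
    yl <- y_int[idx]
    n <- length(idx)
    majority <- levels(y)[which.max(tabulate(yl, n_class))]
    pure <- length(unique(yl)) == 1L
    if (pure || n < min_samples_split || depth >= max_depth) {
      nodes[[id]] <<- list(id = id, leaf = TRUE, class = majority, n_node = n)
      return(id)
    }
    h_parent <- .count_entropy(matrix(tabulate(yl, n_class), nrow = 1))
    best <- NULL
    best_j <- NA_integer_
    for (j in seq_len(ncol(x))) {
      cand <- .best_split_feature(x[idx, j], yl, n_class, h_parent)
      if (!is.null(cand) && (is.null(best) || cand$ig > best$ig + 1e-12)) {
        best <- cand
        best_j <- j
      }
    }
    if (is.null(best) || best$ig <= 1e-12) {
      nodes[[id]] <<- list(id = id, leaf = TRUE, class = majority, n_node = n)
      return(id)
    }
    go_left <- x[idx, best_j] <= best$threshold
    left_id <- grow(idx[go_left], depth + 1)
    right_id <- grow(idx[!go_left], depth + 1)
    nodes[[id]] <<- list(id = id, leaf = FALSE,
                         feature = colnames(x)[best_j],
                         threshold = best$threshold, ig = best$ig,
                         n_node = n, left = left_id, right = right_id,
                         class = majority)
    id
  }
  grow(seq_along(y_int), 0)
  structure(list(nodes = nodes, n_train = length(y_int), classes = levels(y)),
            class = "ig_tree")
}

#' Predict class labels with an information-gain tree
#'
#' @param object An `ig_tree` from [build_tree()].
#' @param newdata Numeric matrix, samples x features, with the feature
#'   columns the tree was grown on (matched by name).
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.ig_tree <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  apply(newdata, 1, function(row) {
    node <- object$nodes[[1]]
    while (!node$leaf) {
      node <- if (row[node$feature] <= node$threshold)
        object$nodes[[node$left]] else object$nodes[[node$right]]
    }
    node$class
  })
}

#' Class-balanced (macro-averaged) accuracy from a confusion matrix
#'
#' Mean of per-class recalls over classes that have at least one actual
#' sample — the tree-accuracy weight used when aggregating relative
#' importance, and the class-balanced companion to [overall_accuracy()].
#'
#' @param confusion Square count matrix, rows = actual classes, columns =
#'   predicted classes.
#' @return Macro-averaged recall in `[0, 1]`.
#' @examples
#' cm <- rbind(c(47, 12, 6), c(2, 58, 4), c(1, 3, 33))
#' weighted_accuracy(cm)  # mean(47/65, 58/64, 33/37)
#' @export
weighted_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  rs <- rowSums(confusion)
  if (all(rs == 0)) stop("confusion matrix has no actual samples")
  mean(diag(confusion)[rs > 0] / rs[rs > 0])
}

#' Parameters for Monte Carlo feature selection
#'
#' @param s Number of random feature subsets (default 100).
#' @param t Trees grown per subset (default 5), so `s * t` trees in total.
#' @param m Features drawn per subset, without replacement. Default `NULL`
#'   resolves, once the matrix is known, to
#'   `max(ceiling(0.05 * d), ceiling(sqrt(d)))` for `d` features (capped at
#'   `d`).
#' @param u Exponent on each tree's class-balanced held-out accuracy
#'   (default 1).
#' @param v Exponent on the node-size fraction `n_node / n_tree` (default 1).
#' @param train_fraction Fraction of samples, stratified by phase, used to
#'   grow each tree; the remainder scores the tree's accuracy (default 2/3).
#' @param seed Integer seed governing the single random stream (subset draws
#'   and train/test splits), making runs exactly reproducible.
#' @param min_samples_split,max_depth Tree growth controls, see
#'   [build_tree()].
#' @return A list of class `mcfs_params`.
#' @export
mcfs_params <- function(s = 100, t = 5, m = NULL, u = 1, v = 1,
                        train_fraction = 2 / 3, seed = 1,
                        min_samples_split = 2, max_depth = Inf) {
  stopifnot(s >= 1, t >= 1, u >= 0, v >= 0,
            train_fraction > 0, train_fraction < 1)
  if (!is.null(m)) stopifnot(m >= 1)
  structure(list(s = as.integer(s), t = as.integer(t), m = m, u = u, v = v,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 min_samples_split = min_samples_split, max_depth = max_depth),
            class = "mcfs_params")
}

## Deterministic per-subset seed below 2^31, so subset streams are
## independent of how the s-budget is partitioned across calls.
.derive_seed <- function(seed, idx) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(idx) * 104729
  as.integer(x %% 2147483647)  # exact: x stays far below 2^53
}

## Stratified train/test split: per phase, round(train_fraction * n_c)
## training samples, clamped to [1, n_c - 1] so both folds see every phase
## where possible.
.stratified_split <- function(y, train_fraction) {
  train <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, if (length(idx) == 1) idx else sample(idx, n_tr))
  }
  sort(train)
}

#' Rank features by Monte Carlo feature selection
#'
#' Grows `s * t` information-gain decision trees: `s` feature subsets of size
#' `m` are drawn uniformly without replacement, and `t` trees are grown per
#' subset, each on an independent stratified train/test split of the samples.
#' Each feature's relative importance (RI) accumulates, over every tree node
#' that splits on it,
#'
#' \deqn{RI_g = \sum_{\tau=1}^{s t} (wAcc_\tau)^u \sum_{n_g(\tau)}
#'   IG(n_g(\tau)) \left(\frac{n_{node}}{n_\tau}\right)^v}
#'
#' where `IG` is the node's information gain, `n_node / n_tau` the fraction
#' of the tree's training samples reaching the node, and `wAcc` the tree's
#' class-balanced accuracy on its held-out samples (computed over the phases
#' present in the held-out set). Features never drawn into any subset get RI
#' exactly 0.
#'
#' RI is additive over trees: because every subset's random stream is derived
#' from `(seed, subset index)`, a budget of `s` subsets can be accumulated
#' incrementally — `mcfs_rank(..., s = s1)` plus
#' `mcfs_rank(..., s = s2, subset_offset = s1)` sums to the single
#' `s = s1 + s2` run.
#'
#' @param x An [expr_matrix()] with at least two phases.
#' @param params An [mcfs_params()] object.
#' @param keep_trees If `TRUE`, attach the grown trees (with their feature
#'   subsets, fold indices and held-out accuracies) as attribute `"trees"`
#'   for auditing.
#' @param subset_offset Index offset for the subset stream (default 0); see
#'   Details on additivity.
#' @return A `feature_ranking`: data frame with columns `rank`, `feature_id`,
#'   `ri`, sorted by descending RI with ties broken by ascending feature id.
#' @export
mcfs_rank <- function(x, params = mcfs_params(), keep_trees = FALSE,
                      subset_offset = 0) {
  stopifnot(inherits(x, "expr_matrix"), inherits(params, "mcfs_params"))
  d <- nrow(x$values)
  m <- params$m
  if (is.null(m)) m <- min(d, max(ceiling(0.05 * d), ceiling(sqrt(d))))
  if (m > d) stop("m (features per subset) exceeds the number of features")
  y <- x$labels
  if (nlevels(y) < 2) stop("feature ranking needs >= 2 phases")
  feats_all <- feature_ids(x)
  ri <- stats::setNames(numeric(d), feats_all)
  trees <- if (keep_trees) vector("list", params$s * params$t) else NULL

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  xt <- t(x$values)  # samples x features
  tree_no <- 0L
  for (i in seq_len(params$s)) {
    set.seed(.derive_seed(params$seed, subset_offset + i))
    feat_idx <- sample(d, m)
    for (j in seq_len(params$t)) {
      tree_no <- tree_no + 1L
      train <- .stratified_split(y, params$train_fraction)
      test <- setdiff(seq_along(y), train)
      tree <- build_tree(xt[train, feat_idx, drop = FALSE], y[train],
                         min_samples_split = params$min_samples_split,
                         max_depth = params$max_depth)
      pred <- predict(tree, xt[test, feat_idx, drop = FALSE])
      conf <- table(factor(y[test], levels = levels(y)),
                    factor(pred, levels = levels(y)))
      wacc <- weighted_accuracy(conf)
      for (node in tree$nodes) {
        if (!node$leaf) {
          ri[node$feature] <- ri[node$feature] +
            wacc^params$u * node$ig * (node$n_node / tree$n_train)^params$v
        }
      }
      if (keep_trees) {
        trees[[tree_no]] <- list(tree = tree,
                                 features = feats_all[feat_idx],
                                 train_idx = sample_ids(x)[train],
                                 test_idx = sample_ids(x)[test],
                                 wacc = wacc)
      }
    }
  }
  ord <- order(-ri, feats_all)
  out <- data.frame(rank = seq_len(d), feature_id = feats_all[ord],
                    ri = unname(ri[ord]), stringsAsFactors = FALSE)
  class(out) <- c("feature_ranking", "data.frame")
  if (keep_trees) attr(out, "trees") <- trees
  out
}

#' Write / read a feature ranking as TSV
#'
#' Columns `rank`, `feature_id`, `ri`.
#'
#' @param ranking A `feature_ranking` from [mcfs_rank()].
#' @param path File path.
#' @return `write_ranking` returns `ranking` invisibly; `read_ranking`
#'   returns a `feature_ranking`.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  df$ri <- format(df$ri, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ranking)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character", "numeric"))
  class(df) <- c("feature_ranking", "data.frame")
  df
}
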