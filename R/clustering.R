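#' Agglomerative clustering of genes or samples
#'
#' Standard expression-heatmap clustering: by default rows are z-scored per
#' gene, items are compared by correlation distance (1 - Pearson r) and
#' merged with average linkage, and the tree is cut into `k` flat clusters.
#' Cluster indices are canonicalized by first appearance in item order, so
#' memberships are invariant to permuting the input items.
#'
#' @param x An [expr_matrix()].
#' @param axis `"rows"` to cluster genes, `"columns"` to cluster samples.
#' @param metric `"correlation"` (1 - Pearson r, the default) or
#'   `"euclidean"`.
#' @param linkage_method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @param k Number of flat clusters to cut.
#' @param standardize_rows Z-score each gene across samples before
#'   clustering (default TRUE); constant genes become all-zero rows.
#' @return An object of class `cluster_assignment`: list with `item_ids`,
#'   `cluster` (named integer vector, clusters numbered 1..k by first
#'   appearance), `order` (dendrogram leaf order) and `hclust` (the merge
#'   history).
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "columns"),
                                 metric = c("correlation", "euclidean"),
                                 linkage_method = "average", k,
                                 standardize_rows = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  vals <- x$values
  if (standardize_rows) vals <- .zscore_rows(vals)
  items <- if (axis == "rows") vals else t(vals)
  if (k > nrow(items)) stop("k exceeds the number of items on this axis")
  d <- if (metric == "correlation") {
    co <- suppressWarnings(stats::cor(t(items)))
    co[!is.finite(co)] <- 0  # constant items: treat as uncorrelated
    stats::as.dist(1 - co)
  } else {
    stats::dist(items)
  }
  hc <- stats::hclust(d, method = linkage_method)
  raw <- stats::cutree(hc, k = k)
  # renumber clusters by first appearance so labels don't depend on input order
  first <- unique(raw)
  cluster <- stats::setNames(match(raw, first), rownames(items))
  structure(list(item_ids = rownames(items), cluster = cluster,
                 order = hc$order, hclust = hc),
            class = "cluster_assignment")
}

.zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Associate each gene with the phase where it is most expressed
#'
#' Labels every gene with the phase whose mean expression is highest, and
#' summarizes the trend of the per-phase means along the phase order
#' (`increasing` / `decreasing` for strictly monotone profiles, otherwise
#' `other`). Ties in the phase means are broken deterministically by phase
#' order and flagged.
#'
#' @param x An [expr_matrix()] with >= 2 phases.
#' @param genes Feature ids to summarize (default: all).
#' @return Data frame with one row per gene: `gene`, `phase` (the argmax
#'   phase), `tie` (logical), `trend`, and one `mean_<phase>` column per
#'   phase (boxplot-ready per-phase means).
#' @export
phase_association <- function(x, genes = feature_ids(x)) {
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(genes, feature_ids(x))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  phases <- levels(x$labels)
  if (length(phases) < 2) stop("phase association needs >= 2 phases")
  sub <- x$values[genes, , drop = FALSE]
  means <- vapply(phases,
                  function(p) rowMeans(sub[, x$labels == p, drop = FALSE]),
                  numeric(length(genes)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  best <- apply(means, 1, which.max)  # first max = tie-break by phase order
  tie <- apply(means, 1, function(r) sum(r == max(r)) > 1)
  trend <- apply(means, 1, function(r) {
    if (all(diff(r) > 0)) "increasing"
    else if (all(diff(r) < 0)) "decreasing"
    else "other"
  })
  out <- data.frame(gene = genes, phase = phases[best], tie = tie,
                    trend = trend, stringsAsFactors = FALSE)
  colnames(means) <- paste0("mean_", phases)
  cbind(out, as.data.frame(means, row.names = NULL))
}

#' Heatmap-ready clustering report for a gene signature
#'
#' Clusters the signature genes and the samples of an expression matrix,
#' associates each gene cluster with its high-expression phase, and returns
#' the z-scored matrix in dendrogram order — everything needed to draw the
#' standard signature heatmap, as data.
#'
#' @param x An [expr_matrix()].
#' @param genes Signature feature ids.
#' @param k_genes Number of gene clusters (default: number of phases).
#' @param k_samples Number of sample clusters (default: number of phases).
#' @param ... Passed to [hierarchical_cluster()] (metric, linkage, ...).
#' @return List with `gene_clusters` (data frame `gene`, `cluster`,
#'   `associated_phase`, plus phase-mean columns), `sample_clusters` (data
#'   frame `sample_id`, `phase`, `cluster`), `matrix` (z-scored signature
#'   matrix in dendrogram order), and the two `cluster_assignment` objects.
#' @export
cluster_report <- function(x, genes, k_genes = nlevels(x$labels),
                           k_samples = nlevels(x$labels), ...) {
  sub <- subset_features(x, genes)
  gc <- hierarchical_cluster(sub, axis = "rows", k = k_genes, ...)
  sc <- hierarchical_cluster(sub, axis = "columns", k = k_samples, ...)
  assoc <- phase_association(x, genes)
  gene_clusters <- cbind(data.frame(gene = genes,
                                    cluster = unname(gc$cluster[genes])),
                         associated_phase = assoc$phase,
                         assoc[, grep("^mean_", colnames(assoc)), drop = FALSE])
  sample_clusters <- data.frame(sample_id = sample_ids(sub),
                                phase = as.character(sub$labels),
                                cluster = unname(sc$cluster[sample_ids(sub)]))
  z <- .zscore_rows(sub$values)[gc$order, sc$order, drop = FALSE]
  list(gene_clusters = gene_clusters, sample_clusters = sample_clusters,
       matrix = z, gene_assignment = gc, sample_assignment = sc)
}

#' Write a clustering report to TSV files
#'
#' Writes `clusters_genes.tsv`, `clusters_samples.tsv` and
#' `heatmap_matrix.tsv` (dendrogram order) into a directory.
#'
#' @param report A list from [cluster_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_cluster_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clusters_genes.tsv", "clusters_samples.tsv",
                            "heatmap_matrix.tsv"))
  utils::write.table(report$gene_clusters, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$sample_clusters, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hm <- data.frame(gene = rownames(report$matrix), report$matrix,
                   check.names = FALSE)
  utils::write.table(hm, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
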