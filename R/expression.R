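#' Construct an expression matrix with sample phase labels
#'
#' The central data container of the package: a features x samples matrix of
#' log-scale expression values together with one categorical phase label per
#' sample. All downstream steps (feature ranking, incremental selection,
#' clustering, enrichment universes) consume this object.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature ids, column names sample ids; both must be unique
#'   and all values finite.
#' @param labels Phase label per sample: either a named vector/factor (names =
#'   sample ids) or an unnamed vector in column order of `values`. Every label
#'   level must contain at least two samples, as required by the stratified
#'   train/test splits and leave-one-out folds used downstream.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `labels` (a named factor in column order).
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(x, c("D0", "D0", "D30", "D30"))
#' dim(em)
#' @export
expr_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must have row names (feature ids) and column names (sample ids)")
  dup <- fid[duplicated(fid)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 fid[bad[1]], sid[bad[2]]))
  }
  if (is.null(names(labels))) {
    if (length(labels) != ncol(values))
      stop("unnamed `labels` must have one entry per sample")
    names(labels) <- sid
  }
  missing <- setdiff(sid, names(labels))
  if (length(missing))
    stop("sample(s) missing from labels: ", paste(missing, collapse = ", "))
  lab_chr <- as.character(labels[sid])
  lev <- if (is.factor(labels)) intersect(levels(labels), unique(lab_chr))
         else unique(lab_chr)
  labels <- factor(lab_chr, levels = lev)
  names(labels) <- sid
  if (anyNA(labels)) stop("labels contain missing values")
  small <- names(which(table(labels) < 2))
  if (length(small))
    stop("every phase needs >= 2 samples; offending phase(s): ",
         paste(small, collapse = ", "))
  structure(list(values = values, labels = labels), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples\n", nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat("phases:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Feature and sample accessors
#'
#' @param x An `expr_matrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Restrict an expression matrix to a feature subset
#'
#' @param x An `expr_matrix`.
#' @param features Feature ids to keep, in the order given.
#' @return An `expr_matrix` with only those rows.
#' @export
subset_features <- function(x, features) {
  missing <- setdiff(features, feature_ids(x))
  if (length(missing))
    stop("feature(s) not in matrix: ", paste(missing, collapse = ", "))
  expr_matrix(x$values[features, , drop = FALSE], x$labels)
}

#' Read an expression matrix and its sample labels from TSV files
#'
#' Expression file: tab-separated, header row of sample ids, first column
#' feature ids. Labels file: two tab-separated columns `sample_id` and
#' `phase`, with header. Row and column order are preserved from the files.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Path to the labels TSV.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, labels_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expression file needs a feature-id column plus >= 1 sample")
  fid <- raw[[1]]
  sid <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric value '%s' at row %d (feature '%s'), column '%s'",
                 vals[bad[1, 1], bad[1, 2]], bad[1, 1], fid[bad[1, 1]], sid[bad[1, 2]]))
  }
  dimnames(num) <- list(fid, sid)
  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  if (!all(c("sample_id", "phase") %in% colnames(lab)))
    stop("labels file must have columns 'sample_id' and 'phase'")
  labels <- stats::setNames(lab$phase, lab$sample_id)
  expr_matrix(num, labels)
}

#' Write an expression matrix and its labels to TSV files
#'
#' Inverse of [read_expression()]; read -> write -> read round-trips are
#' value-identical (values are written with full precision).
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the expression TSV.
#' @param labels_path Output path for the labels TSV.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, labels_path) {
  df <- data.frame(feature_id = feature_ids(x),
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = sample_ids(x), phase = as.character(x$labels))
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a probe-to-gene map from TSV
#'
#' @param path Two-column TSV `probe_id<TAB>gene_id`, header required. Many
#'   probes may map to one gene; each probe maps to exactly one gene.
#' @return Named character vector: names are probe ids, values gene ids.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("probe_id", "gene_id") %in% colnames(df)))
    stop("probe map must have columns 'probe_id' and 'gene_id'")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop("probe(s) mapped more than once: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(df$gene_id))) stop("empty gene_id in probe map")
  stats::setNames(df$gene_id, df$probe_id)
}

#' Collapse probe-level rows to gene-level rows by averaging
#'
#' Probes mapping to the same gene are averaged (arithmetic mean on the
#' stored log scale) per sample. Output gene order is the order of first
#' appearance among the input probes.
#'
#' @param x An `expr_matrix` whose features are probe ids.
#' @param map Named character vector probe id -> gene id
#'   (see [read_probe_map()]). Every feature of `x` must appear in it.
#' @return An `expr_matrix` with one row per distinct gene.
#' @export
collapse_probes <- function(x, map) {
  probes <- feature_ids(x)
  missing <- setdiff(probes, names(map))
  if (length(missing))
    stop("probe(s) absent from map: ", paste(missing, collapse = ", "))
  genes <- as.character(map[probes])
  order_first <- unique(genes)
  sums <- rowsum(x$values, group = genes, reorder = FALSE)
  counts <- as.vector(table(factor(genes, levels = rownames(sums))))
  means <- sums / counts
  means <- means[order_first, , drop = FALSE]
  expr_matrix(means, x$labels)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) to the same expression distribution: each
#' value is replaced by the mean, across samples, of the values at its rank
#' (the per-rank reference), and tied values within a sample receive the mean
#' of the reference values at their tied ranks. After normalization the
#' sorted value vector of every column is identical, and the operation is
#' idempotent.
#'
#' @param x An `expr_matrix` with at least two samples.
#' @return The normalized `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x$values) < 2)
    stop("quantile normalization needs >= 2 samples")
  norm <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(norm) <- dimnames(x$values)
  expr_matrix(norm, x$labels)
}

#' Preprocess a probe-level matrix the standard way
#'
#' Convenience wrapper for the two preprocessing steps applied to the array
#' data this pipeline targets: collapse probes to genes, then
#' quantile-normalize. The order is configurable because either convention
#' appears in practice.
#'
#' @param x Probe-level `expr_matrix`.
#' @param map Probe -> gene map.
#' @param order `"collapse_then_normalize"` (default) or
#'   `"normalize_then_collapse"`.
#' @return Gene-level, quantile-normalized `expr_matrix`.
#' @export
preprocess <- function(x, map,
                       order = c("collapse_then_normalize",
                                 "normalize_then_collapse")) {
  order <- match.arg(order)
  if (order == "collapse_then_normalize")
    quantile_normalize(collapse_probes(x, map))
  else
    collapse_probes(quantile_normalize(x), map)
}
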