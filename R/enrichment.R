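#' Read a gene-set collection from a GMT file
#'
#' Standard GMT layout: one set per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate member ids
#' within a set are collapsed; empty sets are rejected.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   gene-id vectors) and `names` (term_id -> description).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- ids
  empty <- ids[lengths(sets) == 0]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "))
  descr <- stats::setNames(vapply(parts, function(p) if (length(p) >= 2) p[2] else "",
                                  character(1)), ids)
  structure(list(sets = sets, names = descr), class = "gene_set_collection")
}

#' Build a gene-set collection in code
#'
#' @param sets Named list of member gene-id vectors.
#' @param names Optional named vector of term descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  if (is.null(base::names(sets)) || anyDuplicated(base::names(sets)))
    stop("`sets` must be a uniquely named list")
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) stop("empty gene set")
  if (is.null(names))
    names <- stats::setNames(base::names(sets), base::names(sets))
  structure(list(sets = sets, names = names), class = "gene_set_collection")
}

#' Upper-tail hypergeometric probability for set overlap
#'
#' Probability of drawing at least `k` members of a `K`-gene term when `n`
#' genes are drawn without replacement from an `N`-gene universe:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, evaluated through the
#' log-space-stable distribution function.
#'
#' @param k Observed overlap count.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail (inclusive) p-value in `(0, 1]`.
#' @examples
#' hypergeom_pvalue(2, 2, 2, 4)  # 1/6
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric over-representation test of a query gene set
#'
#' Tests every term of a collection for over-representation of the query
#' genes. The background universe is, by default, all genes of the
#' expression matrix the query came from (`universe_mode = "matrix"`, pass
#' `expr`) — conditioning on the measured genes; alternatives are the union
#' of the collection's members (`"collection"`) or an explicit id vector
#' (`"explicit"`). Query and term members are intersected with the universe
#' before counting. P-values are Benjamini-Hochberg adjusted across all
#' terms of the collection; terms with zero overlap are reported only when
#' `include_zero = TRUE`.
#'
#' @param query Character vector of query gene ids (e.g. the selected
#'   signature).
#' @param collection A `gene_set_collection`.
#' @param expr The [expr_matrix()] supplying the universe in `"matrix"` mode.
#' @param universe_mode `"matrix"` (default), `"collection"` or
#'   `"explicit"`.
#' @param universe Universe gene ids for `"explicit"` mode.
#' @param include_zero Report terms with zero overlap (default FALSE).
#' @return Data frame sorted by ascending `p_value` then `term_id`, with
#'   columns `term_id`, `term_name`, `k` (overlap), `K` (term size in
#'   universe), `n` (query size in universe), `N` (universe size),
#'   `p_value`, `q_value`.
#' @export
enrich <- function(query, collection, expr = NULL,
                   universe_mode = c("matrix", "collection", "explicit"),
                   universe = NULL, include_zero = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe_mode <- match.arg(universe_mode)
  universe <- switch(universe_mode,
    matrix = {
      if (is.null(expr)) stop("universe_mode 'matrix' requires `expr`")
      feature_ids(expr)
    },
    collection = unique(unlist(collection$sets, use.names = FALSE)),
    explicit = {
      if (is.null(universe)) stop("universe_mode 'explicit' requires `universe`")
      universe
    })
  universe <- unique(universe)
  query <- unique(query)
  eff_query <- intersect(query, universe)
  if (length(eff_query) == 0)
    stop(length(query), " query gene(s), all outside the universe")
  N <- length(universe)
  n <- length(eff_query)
  rows <- lapply(names(collection$sets), function(tid) {
    members <- intersect(collection$sets[[tid]], universe)
    K <- length(members)
    k <- length(intersect(eff_query, members))
    data.frame(term_id = tid,
               term_name = unname(collection$names[tid]),
               k = k, K = K, n = n, N = N,
               p_value = if (K == 0) 1 else hypergeom_pvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  if (!include_zero) res <- res[res$k >= 1, , drop = FALSE]
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results as TSV
#'
#' @param results Data frame from [enrich()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results)
}
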