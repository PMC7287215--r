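#' Run the full phase-signature discovery pipeline
#'
#' Convenience wrapper chaining the core stages on a preprocessed
#' (gene-level, normalized) expression matrix: Monte Carlo feature-selection
#' ranking, incremental feature selection with LOOCV-scored classifiers, and
#' the clustering report for the selected signature.
#'
#' @param x An [expr_matrix()].
#' @param params [mcfs_params()] for the ranking stage.
#' @param grid_max,step,epsilon Incremental-selection grid controls, see
#'   [ifs_run()].
#' @param classifier Classifier spec (default [svm_classifier()]).
#' @param cluster Also compute the [cluster_report()] for the selected
#'   signature (default TRUE).
#' @return List with `ranking` (feature ranking), `curve` (`ifs_curve`),
#'   `signature` (selected feature ids) and, if requested, `clusters`.
#' @export
phase_signature_pipeline <- function(x, params = mcfs_params(),
                                     grid_max = NULL, step = 1,
                                     epsilon = 0.005,
                                     classifier = svm_classifier(),
                                     cluster = TRUE) {
  ranking <- mcfs_rank(x, params)
  curve <- ifs_run(ranking, x, grid_max = grid_max, step = step,
                   classifier = classifier, epsilon = epsilon)
  out <- list(ranking = ranking, curve = curve,
              signature = curve$selected_features)
  if (cluster) out$clusters <- cluster_report(x, curve$selected_features)
  out
}
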