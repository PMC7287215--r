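#' Specification of a synthetic three-phase expression dataset
#'
#' Describes a quantile-normalized-like log-expression matrix for a cohort
#' sampled at three ordered disease phases (acute event D0, 30 days D30, one
#' year Y1 — the design of the blood-transcriptome study this pipeline
#' targets, with its 65/64/37 samples per phase as the default). A small set
#' of informative genes carries phase-dependent mean shifts on top of a
#' large background of i.i.d. Gaussian noise genes; the shift patterns
#' mirror the expression programs such studies report: monotone increase or
#' decrease across phases, or high expression in a single phase.
#'
#' @param n_genes Total number of genes (default 500, a desk-scale stand-in
#'   for genome-wide matrices).
#' @param n_samples_per_phase Integer vector of per-phase sample counts, one
#'   per phase, named or in `phases` order (default `c(65, 64, 37)`); every
#'   phase needs >= 2.
#' @param n_informative Number of planted informative genes (default 10).
#' @param effect_size Mean shift of informative genes in units of `noise_sd`
#'   (default 2).
#' @param patterns Character vector, one of `"monotone_up"`,
#'   `"monotone_down"`, `"high_D0"`, `"high_D30"`, `"high_Y1"` per
#'   informative gene; default cycles through all five.
#' @param noise_sd Per-gene noise standard deviation (default 1, the unit of
#'   `effect_size`).
#' @param baseline_mean Background log-expression level (default 8, typical
#'   of log2 microarray intensities).
#' @param noise `"gaussian"` (default) or `"t"` for heavier tails
#'   (Student t, `df` degrees of freedom, scaled to `noise_sd`).
#' @param df Degrees of freedom for `noise = "t"` (default 5).
#' @param block_cor Equicorrelation within each pattern's informative-gene
#'   block, emulating co-expression (default 0 = independent genes).
#' @param phases Phase labels in order (default `c("D0", "D30", "Y1")`).
#' @param seed Integer seed; generation is bit-reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 500,
                           n_samples_per_phase = c(65, 64, 37),
                           n_informative = 10, effect_size = 2,
                           patterns = NULL, noise_sd = 1, baseline_mean = 8,
                           noise = c("gaussian", "t"), df = 5,
                           block_cor = 0, phases = c("D0", "D30", "Y1"),
                           seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_genes >= 1, n_informative >= 0, n_informative <= n_genes,
            effect_size >= 0, noise_sd > 0, block_cor >= 0, block_cor < 1,
            length(n_samples_per_phase) == length(phases),
            all(n_samples_per_phase >= 2))
  allowed <- c("monotone_up", "monotone_down",
               paste0("high_", phases))
  if (is.null(patterns))
    patterns <- rep_len(allowed, n_informative)
  if (length(patterns) != n_informative)
    stop("`patterns` must have one entry per informative gene")
  bad <- setdiff(patterns, allowed)
  if (length(bad))
    stop("unknown pattern(s): ", paste(unique(bad), collapse = ", "))
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_phase = as.integer(n_samples_per_phase),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, patterns = patterns,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 noise = noise, df = df, block_cor = block_cor,
                 phases = phases, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Per-phase mean offsets (in noise-sd units already multiplied out) for one
## pattern, delta = effect_size * noise_sd.
.pattern_offsets <- function(pattern, phases, delta) {
  p <- length(phases)
  if (pattern == "monotone_up") return(seq(0, delta, length.out = p))
  if (pattern == "monotone_down") return(seq(delta, 0, length.out = p))
  target <- sub("^high_", "", pattern)
  ifelse(phases == target, delta, 0)
}

#' Generate a synthetic three-phase expression dataset
#'
#' Background genes are i.i.d. `Normal(baseline_mean, noise_sd)` per value;
#' informative genes add phase-dependent mean offsets: `monotone_up` =
#' `(0, delta/2, delta)` across the three phases, `monotone_down` the
#' reverse, `high_<phase>` = `delta` in that phase only, with
#' `delta = effect_size * noise_sd`. Informative genes are placed at random
#' positions; the returned truth table identifies them. Generation is
#' bit-reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `expr` (an [expr_matrix()], genes named `g0001`...,
#'   samples `s001`... labelled by phase) and `truth` (data frame `gene`,
#'   `pattern` for the informative genes, in gene order).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  n_samples <- sum(spec$n_samples_per_phase)
  phase_of <- factor(rep(spec$phases, spec$n_samples_per_phase),
                     levels = spec$phases)
  gene_ids <- sprintf("g%0*d", max(4, nchar(spec$n_genes)), seq_len(spec$n_genes))
  sample_ids <- sprintf("s%0*d", max(3, nchar(n_samples)), seq_len(n_samples))

  draw <- function(n) {
    if (spec$noise == "gaussian") stats::rnorm(n, 0, spec$noise_sd)
    else stats::rt(n, spec$df) * spec$noise_sd / sqrt(spec$df / (spec$df - 2))
  }
  vals <- matrix(draw(spec$n_genes * n_samples), spec$n_genes, n_samples,
                 dimnames = list(gene_ids, sample_ids)) + spec$baseline_mean

  info_idx <- sort(sample(spec$n_genes, spec$n_informative))
  delta <- spec$effect_size * spec$noise_sd
  if (spec$block_cor > 0 && spec$n_informative > 0) {
    # shared latent factor per pattern block -> equicorrelated residuals
    rho <- spec$block_cor
    for (pat in unique(spec$patterns)) {
      rows <- info_idx[spec$patterns == pat]
      factor_s <- draw(n_samples)
      vals[rows, ] <- spec$baseline_mean +
        sqrt(rho) * rep(factor_s, each = length(rows)) +
        sqrt(1 - rho) * (vals[rows, , drop = FALSE] - spec$baseline_mean)
    }
  }
  for (i in seq_along(info_idx)) {
    off <- .pattern_offsets(spec$patterns[i], spec$phases, delta)
    vals[info_idx[i], ] <- vals[info_idx[i], ] + off[as.integer(phase_of)]
  }
  truth <- data.frame(gene = gene_ids[info_idx],
                      pattern = spec$patterns[seq_along(info_idx)],
                      stringsAsFactors = FALSE)
  list(expr = expr_matrix(vals, stats::setNames(as.character(phase_of), sample_ids)),
       truth = truth)
}

#' Write the planted-gene truth table as TSV
#'
#' @param truth Data frame with columns `gene`, `pattern` from
#'   [generate_synthetic()].
#' @param path Output file path.
#' @return The input, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(truth)
}
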