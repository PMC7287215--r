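#!/usr/bin/env Rscript
# Step 2 — preprocess: quantile-normalize across samples.
#
# The simulated matrix is already gene-level, so the probe-collapse step is
# demonstrated on the bundled miniature probe-level example instead; the
# cohort matrix is quantile-normalized so every sample shares one expression
# distribution, as is standard for array intensities before ranking.

library(phasesig)

# probe-collapse demonstration on the bundled example files
probe_expr <- read_expression(
  system.file("extdata", "example_probes.tsv", package = "phasesig"),
  system.file("extdata", "example_labels.tsv", package = "phasesig"))
map <- read_probe_map(
  system.file("extdata", "example_probe_map.tsv", package = "phasesig"))
collapsed <- collapse_probes(probe_expr, map)
cat(sprintf("probe-collapse demo: %d probes -> %d genes\n",
            nrow(probe_expr$values), nrow(collapsed$values)))

# cohort preprocessing
expr <- read_expression("results/data/expr.tsv", "results/data/labels.tsv")
norm <- quantile_normalize(expr)
stopifnot(identical(unname(sort(norm$values[, 1])),
                    unname(sort(norm$values[, 2]))))
write_expression(norm, "results/data/expr_norm.tsv",
                 "results/data/labels.tsv")
cat("quantile-normalized matrix written to results/data/expr_norm.tsv\n")
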