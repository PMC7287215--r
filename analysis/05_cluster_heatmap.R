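#!/usr/bin/env Rscript
# Step 5 — cluster the signature and export heatmap-ready data.
#
# Hierarchically clusters the signature genes (correlation distance, average
# linkage, rows z-scored) and the samples, cuts three gene clusters, and
# labels each with the phase where it is most expressed. The z-scored matrix
# is written in dendrogram order; a rendered heatmap is produced only if
# pheatmap is available.

library(phasesig)

expr <- read_expression("results/data/expr_norm.tsv", "results/data/labels.tsv")
signature <- read.delim("results/signature.tsv",
                        colClasses = "character")$feature_id

report <- cluster_report(expr, signature, k_genes = 3, k_samples = 3)
write_cluster_report(report, "results/clusters")

cat("gene clusters and their associated phases:\n")
print(table(cluster = report$gene_clusters$cluster,
            phase = report$gene_clusters$associated_phase))
cat("\nsample clusters by phase (rows = phase):\n")
print(table(phase = report$sample_clusters$phase,
            cluster = report$sample_clusters$cluster))

if (requireNamespace("pheatmap", quietly = TRUE)) {
  ann <- data.frame(phase = report$sample_clusters$phase,
                    row.names = report$sample_clusters$sample_id)
  pheatmap::pheatmap(report$matrix, cluster_rows = FALSE, cluster_cols = FALSE,
                     annotation_col = ann, show_colnames = FALSE,
                     filename = "results/heatmap.png", width = 9, height = 6)
  cat("rendered results/heatmap.png\n")
}
cat("wrote results/clusters/*.tsv\n")
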