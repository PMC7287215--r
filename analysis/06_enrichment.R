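#!/usr/bin/env Rscript
# Step 6 — hypergeometric over-representation of the signature.
#
# With no curated annotation shipped (GO/KEGG collections are
# version-dependent downloads), a synthetic GMT collection is built whose
# first term is the planted gene set and the rest are random draws; the
# signature should light up the planted term and nothing else. Substitute
# any real GMT file to test a biological collection.

library(phasesig)

seed <- 20260923 %% 2147483647
expr <- read_expression("results/data/expr_norm.tsv", "results/data/labels.tsv")
truth <- read.delim("results/data/truth.tsv", colClasses = "character")
signature <- read.delim("results/signature.tsv",
                        colClasses = "character")$feature_id

set.seed(seed)
background <- setdiff(feature_ids(expr), truth$gene)
sets <- c(list(planted = truth$gene),
          setNames(lapply(1:9, function(i) sample(background, 25)),
                   sprintf("random%02d", 1:9)))
gmt_path <- "results/example_sets.gmt"
writeLines(vapply(names(sets), function(id) {
  paste(c(id, paste(id, "synthetic term"), sets[[id]]), collapse = "\t")
}, character(1)), gmt_path)

coll <- read_gmt(gmt_path)
res <- enrich(signature, coll, expr = expr)
write_enrichment(res, "results/enrichment.tsv")

cat("over-representation of the selected signature (universe = matrix genes):\n")
print(res, row.names = FALSE)
cat("wrote results/enrichment.tsv and results/example_sets.gmt\n")
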