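#!/usr/bin/env Rscript
# Stage 2: map scored binding clusters onto the miR promoters and build
# the per-promoter binding summary table (median and range of cluster
# scores), then classify promoters as bound single-gene, bound
# cluster-gene, or unbound.

suppressPackageStartupMessages(library(mirtf))

dir <- "results/data"
promoters <- read_promoters(file.path(dir, "promoters.tsv"))
clusters <- read_clusters(file.path(dir, "clusters.tsv"))
cat(sprintf("Read %d promoters and %d binding clusters\n",
            nrow(promoters), nrow(clusters)))

hits <- intersect_binding(promoters, clusters)
summaries <- summarize_binding(promoters, hits, clusters)
write_binding_table(summaries, "results/binding_table.tsv")

counts <- classify_promoters(summaries)
jsonlite::write_json(counts, "results/binding_counts.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "Bound promoters: %d single-gene + %d cluster-gene; %d unbound\n",
  counts$bound_single, counts$bound_cluster, counts$unbound))
top <- summaries[order(-summaries$median_score), ][1:5, ]
cat("Highest-scoring promoters (median (range)):\n")
for (i in seq_len(5)) {
  cat(sprintf("  %-28s %s (%s-%s)\n", top$genes[i], top$median_score[i],
              top$min_score[i], top$max_score[i]))
}
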