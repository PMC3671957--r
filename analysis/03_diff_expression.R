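#!/usr/bin/env Rscript
# Stage 3: quantile-normalize the knockdown-vs-control intensity matrix,
# call differentially expressed miR genes by Welch's unequal-variance
# t-test at p <= 0.05 (probes collapsed to genes by median), and order
# genes and samples by correlation-distance hierarchical clustering for
# heat-map display.

suppressPackageStartupMessages(library(mirtf))

dir <- "results/data"
em <- read_expression(file.path(dir, "expression.tsv"),
                      file.path(dir, "design.tsv"))
print(em)

em_n <- quantile_normalize(em)
de <- call_de(em_n, alpha = 0.05)
write.table(de, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
counts <- list(down = sum(de$direction == "down_in_kd"),
               up = sum(de$direction == "up_in_kd"),
               ns = sum(de$direction == "ns"))
jsonlite::write_json(counts, "results/de_counts.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf(
  "Significant at p <= 0.05: %d down + %d up in the knockdown (%d ns)\n",
  counts$down, counts$up, counts$ns))
cat(sprintf("Knockdown lowers the affected miRs' levels %d:%d\n",
            counts$down, counts$up))

sig <- de$gene_id[de$direction != "ns"]
em_sig <- em_n
keep <- em_sig$gene_ids %in% sig
em_sig$values <- em_sig$values[keep, , drop = FALSE]
em_sig$probe_ids <- em_sig$probe_ids[keep]
em_sig$gene_ids <- em_sig$gene_ids[keep]
gene_ord <- cluster_order(em_sig, axis = "genes")
sample_ord <- cluster_order(em_sig, axis = "samples")
jsonlite::write_json(
  list(gene_leaf_order = gene_ord$leaf_order,
       gene_labels = gene_ord$labels,
       sample_leaf_order = sample_ord$leaf_order,
       sample_labels = sample_ord$labels),
  "results/clustering.json", digits = NA)
cat("Sample leaf order:",
    paste(sample_ord$labels[sample_ord$leaf_order], collapse = " "), "\n")

# comparative-Ct sanity check of the knockdown itself: a ddCt of 3
# against the reference gene is an 8-fold reduction
fc <- qpcr_relative_expression(ct_target_a = 28, ct_ref_a = 20,
                               ct_target_b = 25, ct_ref_b = 20)
cat(sprintf("Comparative-Ct example: ddCt 3 -> fold change %.3f (8-fold down)\n",
            fc))
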