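#!/usr/bin/env Rscript
# Stage 5: the sponge-out simulation. Scores the total miR:transcript
# heteroduplex energy released for the full transcript and its 3'UTR
# slice, against 100 base-composition-matched shuffles of each region.
# A transcript that really carries complementary sites releases far more
# energy than its shuffles (small empirical p, large z).

suppressPackageStartupMessages(library(mirtf))

tx <- read_rna_fasta("results/data/transcript.fa", role = "transcript")[[1]]
mirs <- read_rna_fasta("results/data/mirs.fa", role = "mir")
params <- default_energy_params()
utr3 <- c(floor(0.6 * nchar(tx$bases)) + 1L, nchar(tx$bases))
cat(sprintf("Transcript %s: %d nt, 3'UTR %d-%d, %d miRs\n", tx$name,
            nchar(tx$bases), utr3[1], utr3[2], length(mirs)))

per_mir <- sponge_score(tx, mirs, params, per_mir = TRUE)
write.table(per_mir, "results/sponge_sites.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Best site per miR (kcal/mol released):\n")
for (i in seq_len(nrow(per_mir))) {
  cat(sprintf("  %-14s %7.2f  window %s-%s\n", per_mir$mir[i],
              per_mir$energy_released[i],
              per_mir$window_start[i], per_mir$window_end[i]))
}

res <- run_sponge_null(tx, utr3 = utr3, mirs = mirs, params = params,
                       n_shuffles = 100, seed = 1)
for (r in res) print(r)
jsonlite::write_json(
  lapply(res, function(r) list(
    region = r$region, true_score = r$true_score,
    null_mean = mean(r$null_scores), null_sd = sd(r$null_scores),
    empirical_p = r$empirical_p, z_score = r$z_score,
    n_shuffles = r$n_shuffles)),
  "results/sponge_null.json", auto_unbox = TRUE, digits = NA)
cat("Both regions release more energy than their shuffled nulls when",
    "complementary sites are present.\n")
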