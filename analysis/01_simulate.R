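#!/usr/bin/env Rscript
# Simulate a Virotrap-style screen under the study design: 12 baits x
# {untreated, TNF} x 3 replicates plus 15 control experiments, a shared
# contaminant background, and planted bait-specific interactors
# (constitutive / TNF-induced / TNF-lost, with deliberate one-hit wonders).
# Writes the count matrix, metadata, ground truth and a partial-knowledge
# reference set under results/data/.

suppressPackageStartupMessages(library(baitprey))

seed <- 2026
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
d <- simulate_dataset(cfg)
ref <- simulate_reference_set(d$truth, coverage = cfg$reference_coverage,
                              extra_pairs = 20, seed = seed)

write_counts_wide(d$matrix, file.path(out, "spectral_counts.tsv"),
                  file.path(out, "experiment_overview.tsv"))
write_ground_truth(d$truth, file.path(out, "ground_truth.tsv"))
write_reference_tsv(ref, file.path(out, "reference_pairs.tsv"))

message(sprintf(
  "simulated %d proteins x %d experiments (%d planted pairs, %d background contaminants)",
  nrow(d$matrix$counts), ncol(d$matrix$counts), nrow(d$truth$planted),
  length(d$truth$background)))
message(sprintf("reference set: %d unordered pairs (coverage %.0f%% + 20 decoys)",
                length(ref$keys), 100 * cfg$reference_coverage))
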