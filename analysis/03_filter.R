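#!/usr/bin/env Rscript
# The stringent filter cascade on the simulated screen: pre-filter census,
# control-based background removal, replicate summation with weak/strong
# classes, one-hit-wonder removal.  Writes the surviving candidate table.

suppressPackageStartupMessages(library(baitprey))

m <- read_counts_wide("results/data/spectral_counts.tsv",
                      "results/data/experiment_overview.tsv")
pre <- census(m)
message(sprintf("pre-filter: %d proteins, %d bait-prey interactions",
                pre$n_proteins, pre$n_interactions))

res <- filter_cascade(m)
post <- census(res$post_control)
message(sprintf("after control filter: %d proteins (%d removed as background)",
                post$n_proteins, length(res$removed_background)))
surviving <- unique(paste(res$candidates$bait, res$candidates$prey))
message(sprintf("after replicate summation + one-hit removal: %d pairs (%d candidate rows)",
                length(surviving), nrow(res$candidates)))
print(table(res$candidates$condition, res$candidates$strength))

write_candidates(res$candidates, "results/candidates.tsv")
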