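#!/usr/bin/env Rscript
# Demonstrate why the search is iterated: a far-diverged homolog that a
# seed-only profile cannot see becomes significant once a mid-diverged
# homolog has been folded into the alignment (taxa enrichment).

library(orthotrace)
dir.create("results", showWarnings = FALSE)

rows <- list()
for (s in 1:10) {
  b <- simulate_bridge_family(seed = 500 + s)
  targets <- list(taxonA = c(mid = b$mid), taxonB = c(far = b$far))
  single <- iterative_search(b$seed_msa, targets, max_iter = 1,
                             seed = 500 + s, family = "bridge")
  full <- iterative_search(b$seed_msa, targets, max_iter = 10,
                           seed = 500 + s, family = "bridge")
  far_iter <- if ("taxonB:far" %in% full$hits$target)
    full$hits$iteration[full$hits$target == "taxonB:far"] else NA
  rows[[s]] <- data.frame(
    replicate = s,
    single_pass_hits = nrow(single$hits),
    converged_hits = nrow(full$hits),
    iterations = length(full$iteration_hits),
    far_recovered_at = far_iter)
}
tab <- do.call(rbind, rows)
write_tsv(tab, "results/iterative_search_bridge.tsv")

message("single-pass vs converged hit counts over 10 bridge replicates:")
print(tab, row.names = FALSE)
message(sprintf("far homolog recovered at iteration >= 2 in %d/10 replicates",
                sum(!is.na(tab$far_recovered_at) & tab$far_recovered_at >= 2)))
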