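#!/usr/bin/env Rscript
# Map family losses onto the species tree by Dollo parsimony, compare
# inferred loss branches with the simulator's true loss events,
# summarize complexes, and draw the presence/absence heat grid.

library(orthotrace)
dir.create("results", showWarnings = FALSE)

tree <- ape::read.tree("results/run/species_tree.nwk")
calls <- read_tsv("results/run/calls.tsv")
pm <- build_matrix(calls)
events <- reconstruct_all(tree, pm)
write_tsv(events, "results/loss_events.tsv")

# complexes: group the simulated families into two arbitrary "machines"
fams <- pm$families
complexes <- data.frame(
  complex = rep(c("machineA", "machineB"), c(6, length(fams) - 6)),
  family = fams)
status <- complex_status(pm, complexes)
write_tsv(status, "results/complex_status.tsv")

tab <- branch_loss_summary(tree, events, complexes)
write_tsv(data.frame(branch = rownames(tab), tab, check.names = FALSE),
          "results/branch_loss_summary.tsv")

# per-taxon completeness against the simulated family set
found <- colSums(pm$state != "absent")
comp <- data.frame(taxon = pm$taxa, n_found = found,
                   n_max = length(fams),
                   percent = busco_percentage(found, length(fams)))
write_tsv(comp, "results/completeness.tsv")

grDevices::png("results/presence_matrix.png", 900, 700, res = 120)
plot_presence_matrix(pm, main = "presence / absence across taxa")
grDevices::dev.off()

message(sprintf("%d loss events across %d branches; totals conserved: %s",
                sum(events$type == "loss"), sum(rowSums(tab) > 0),
                identical(sum(tab), sum(events$type == "loss"))))
message("complex status counts:")
print(table(status$complex, status$status))
message("per-taxon completeness (%):")
print(comp, row.names = FALSE)
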