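#!/usr/bin/env Rscript
# Genome QC: heterozygous-site calling under the explicit two-read /
# 10x rule, allele-balance ploidy verdicts for the simulated haploid
# and diploid pileups, and k-mer assembly completeness for the
# dropout-0.1 assembly of taxon t1.

library(orthotrace)
dir.create("results", showWarnings = FALSE)

for (kind in c("haploid", "diploid")) {
  pile <- read_tsv(sprintf("results/pileup_%s.tsv", kind))
  hc <- call_het_sites(pile, min_cov = 10, min_alt_reads = 2)
  rep_ <- infer_ploidy(hc)
  jsonlite::write_json(unclass(rep_),
                       sprintf("results/ploidy_%s.json", kind),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  grDevices::png(sprintf("results/allele_balance_%s.png", kind),
                 700, 500, res = 110)
  plot_allele_balance(rep_)
  grDevices::dev.off()
  message(sprintf(
    "%s pileup: %d/%d sites heterozygous (fraction %.2e) -> verdict %s",
    kind, rep_$het_count, rep_$considered, rep_$het_fraction,
    rep_$verdict))
}

asm <- read_tsv("results/t1_assembly_kmers.tsv")$kmer
reads <- read_tsv("results/t1_read_kmers.tsv")
kc <- kmer_completeness(asm, reads, solid_min = 4)
jsonlite::write_json(unclass(kc), "results/kmer_completeness.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf(
  "k-mer completeness of the dropout-0.1 assembly: %.2f%% (%d/%d solid k-mers)",
  kc$percent, kc$found, kc$solid))
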