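#!/usr/bin/env Rscript
# Generate the synthetic study bundle: a rooted species tree with a
# long-branch clade, protein families evolving with Dollo losses,
# genome/proteome pairs with deliberate annotation failures, and the
# pileups / k-mer sets used by the QC stage. Everything downstream
# reads from results/run/.

library(orthotrace)

cfg <- list(
  seed = 20260101,
  outdir = "results/run",
  simulate = list(n_taxa = 8, n_families = 12, root_len = 120,
                  sub_rate = 0.3, loss_rate = 0.15,
                  long_clade_fraction = 0.25, long_multiplier = 2,
                  intergenic_len = 150, hide_fraction = 0.2)
)
dir.create("results", showWarnings = FALSE)

bundle <- run_pipeline(cfg)

message("wrote synthetic bundle + screen outputs under results/run/")
message(sprintf("grid: %d families x %d taxa; %d genes hidden from proteomes",
                length(bundle$matrix$families), length(bundle$matrix$taxa),
                sum(bundle$truth_registry$hidden)))

# QC inputs for 05: haploid and diploid pileups, k-mer sets
pile_hap <- simulate_pileup(1, 50000, 30, error_rate = 0.005,
                            seed = 20260102)
pile_dip <- simulate_pileup(2, 50000, 30, error_rate = 0.005,
                            het_density = 0.01, seed = 20260103)
write_tsv(pile_hap, "results/pileup_haploid.tsv")
write_tsv(pile_dip, "results/pileup_diploid.tsv")

genome1 <- read_fasta("results/run/t1_genome.fasta")
ks <- sample_kmer_sets(genome1, k = 17, read_cov = 30, dropout = 0.1,
                       seed = 20260104)
write_tsv(data.frame(kmer = ks$assembly_kmers),
          "results/t1_assembly_kmers.tsv")
write_tsv(ks$read_kmers, "results/t1_read_kmers.tsv")
message("wrote pileups and k-mer tables under results/")
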