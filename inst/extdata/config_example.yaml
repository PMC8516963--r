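# Example configuration for run_pipeline(). Any omitted field falls
# back to default_config(); seeds are mandatory and explicit.
seed: 20260101
outdir: results/run
simulate:
  enabled: true
  n_taxa: 8
  n_families: 12
  root_len: 120
  sub_rate: 0.3
  loss_rate: 0.15
  long_clade_fraction: 0.25
  long_multiplier: 2
  intergenic_len: 150
  hide_fraction: 0.2
search:
  inclusion_E: 1.0e-5
  domain_E: 1.0e-3
  n_decoys: 200
  max_iter: 10
  min_seg_len: 30
ploidy:
  enabled: false
  min_cov: 10
  min_alt_reads: 2
  het_frac_threshold: 5.0e-3
kmer:
  enabled: false
  solid_min: 4
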