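# Bundled toy study: a small end-to-end run of the full pipeline.
seed: 42
simulation:
  n_contigs: 2
  contig_length: 60000
  n_genes: 8
  n_known_pirnas: 40
  n_decoy_sncrnas: 10
  n_planted_loci: 20
  n_samples_per_stage: {CN: 6, LGDN: 3, HGDN: 3, eHCC: 3, pHCC: 6}
  nb_mean: 30
  nb_dispersion: 0.3
  planted_fc: 4
  frac_differential: 0.2
  low_expression_frac: 0.5
  u1_prob: 0.8
thresholds:
  fc: 1.5
  fdr: 0.05
  score: 0.5
  merge_distance: 0
  max_placements: 30
  rpm_filter: 1
  high_rpm: 5000
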