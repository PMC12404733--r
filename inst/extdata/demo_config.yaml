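seed: 7
reference:
  mode: simulate
  n_per_family: 2
simulation:
  n_replicates: {control: 2, case: 2}
  reads_per_replicate: 4000
  dispersion: 0.05
  theta_case:
    Ala-AGC-1: 0.43
    Ala-AGC-2: 0.25
    Val-AAC-1: 0.6
    Val-AAC-2: 0.8
    Ile-AAT-1: 0.7
    Leu-AAG-1: 0.85
    Thr-AGT-1: 0.75
  coupling: {slope: 1, sd: 0.15}
  mis_rate: 0.08
  trunc_prob: 0.05
  error_rate: 0.001
assign: {max_mismatch: 3, mod_site_free: true}
quantify: {min_coverage: 20}
differential: {sig: 0.05, shrink: 0.5}
coupling: {B: 2000}
enrichment:
  enabled: true
  n_background: 600
  n_target: 60
  multiplier: 1.6
  gene_length: 120
  B: 2000
  families: Ala-AGC
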