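# Demonstration run configuration for ecstress::run_full_pipeline().
# Every field is optional; omitted fields take the package defaults.
seed: 42
synthetic:
  n_genes: 60
  n_cryptic_targets: 8
  n_cryptic_nontargets: 8
  depth: 1000000
  n_libraries: 2
  planted_mean: 60
  ct_sd: 0.2
  efficiency: 1.0
thresholds:
  min_exclusive_reads: 20
  ptc_min_distance_nt: 50
  sharpness_min: 0.9
mirna:
  n_hairpins: 20
  n_family: 6
  family: let-7-like
  n_reads: 20000
  fall_1h: 0.5
  recovery_6h: 1.0
qpcr:
  control_conc_fM: 100
  fall_1h: 0.2
  recovery_6h: 1.0
targets:
  n_mrnas: 2000
  n_targets: 100
  family_shift: 0.5
  sigma: 0.3
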