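# Desk-scale demonstration run: simulate a paired two-platform cohort,
# harmonize, train both imputation directions and emit the tier table.
out_dir: demo_out
seed: 7
split_fraction: 0.75
simulate:
  n_samples: 100
  n_proteins: 60
model:
  max_iter: 60
stages:
  consensus: true
  replication: true
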