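# All-synthetic demonstration run: every stage consumes data generated by
# the synthetic stage, so the pipeline runs without any external files.
seed: 1
outdir: atdkit-demo
stages:
  synthetic: true
  structure: true
  family: true
  trna: true
  kinetics: true
thresholds:
  prune_cutoff: 3.5
  contact_cutoff: 3.5
  score_min: 50
  enrich_threshold: 10
  depletion_threshold: 0.5
  max_mismatch: 1
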