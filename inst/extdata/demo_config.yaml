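# Demonstration run: planted-effect cohort (36 cases / 31 controls,
# five elemental pathways), full pipeline.
seed: 1
output_dir: attractr_demo_run
cohort:
  preset: demo
  seed: 1
rqa:
  target_recurrence_rate: 0.10
  lmin: 3
  theiler_window: 1
prediction:
  train_fraction: 0.6
  n_boot: 2000
  top_k: 5
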