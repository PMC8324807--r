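# Example pamscreen run configuration (see ?run_config for every key).
# A 2-round stochastic screen of the full 256-member PAM library with
# 40 active PAMs, sequenced at 50,000 reads per library.
outdir: pamscreen_run
seed: 1
n_active: 40
edit_prob: 0.1
rounds: 2
unedited_survival: 0.02
background_escape: 1.0e-6
bottleneck_size: 100000
mode: stochastic
n_reads: 50000
error_model:
  substitution_rate: 0.001
  n_rate: 0.0005
  adapter_rate: 0.0
cleaning:
  max_n_frac: 0.1
  min_mean_q: 20
functional_threshold: 0.01
enriched_threshold: 1.0
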