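# Example run configuration for the command-line interface.
# `simulate` uses n_cases/n_controls/seed; `score` and `validate` use the
# cohort path and model columns.  Paths are relative to the working directory.
n_cases: 150
n_controls: 250
seed: 11
cohort: out/synthetic_cohort.csv
models:
  - score_brisk5
  - score_brisklt
scheme: 5year
out_dir: out
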