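# Example run configuration for run_full_analysis() / the CLI wrapper.
# Exactly one of `input` or `simulate` may be present.
simulate:
  n_pairs: 18
  apply_dropout: true
analysis:
  rater: gambler          # gambler-rated TLFB-G is the primary series
  contrast_weeks: [12, 25, 38]
  ppc_n_rep: 200
  mcmc:
    chains: 4
    adapt: 500
    burn: 500
    iter: 1000
out_dir: out
seed: 2026
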