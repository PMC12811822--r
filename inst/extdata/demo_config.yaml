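# Demonstration configuration: a reduced-size end-to-end run of every
# stage (synthetic data -> TPC fit, permutation tests, co-expression
# network, regulatory windows). Sizes are kept small so the full run
# completes in about a minute; analysis defaults are larger (see the
# package documentation).
seed: 5
thermal:
  n_individuals_per_group: 8
tpc:
  n_chains: 2
  n_warmup: 250
  n_sampling: 250
perm:
  m: 2000
expression:
  n_genes: 1200
  n_samples_per_group: 8
coexpr:
  top_n: 600
  n_boot: 20
genome:
  n_genes: 40
  n_peaks: 150
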