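# Demonstration configuration: a reduced synthetic world that runs the
# full pipeline in well under ten minutes on one CPU.
seed: 1
nperm: 499
nsim: 500
k_categories: 5
ne_convention: table
mu: 5.47e-5
sim:
  n_pops: 21
  n_ind_per_pop: 30
  n_loci: 9
  n_clusters: 4
  generations: 150
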