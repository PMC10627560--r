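# Demonstration configuration mirroring a full cetacean analysis:
# 87-taxon mitochondrial + nuclear alignment, root age fixed at 44 Ma,
# extant sampling 0.98, turnover death-rate parametrisation, all other
# ClaDS parameters estimated. The alignment and starting tree are NOT
# bundled; point `alignment` and `tree` at local files. At realistic
# chain lengths (hundreds of millions of iterations) this is a
# multi-day single-core run; the settings below are a template, not a
# benchmark, and the demo carries no pass/fail semantics.
death_mode: turnover
rho: 0.98
lambda0: 0.1
alpha_lambda: 1.0
sigma_lambda: 0.1
epsilon: 0.5
estimate:
  - lambda0
  - alpha_lambda
  - sigma_lambda
  - epsilon
tree: cetacea_start.nwk        # user-supplied, root age 44
alignment: cetacea_87taxa.fasta  # user-supplied, 87 x 16175
fixed_tree: false
fixed_root: true
clock_rate: 0.01
estimate_clock: false
n_iter: 1000000
sample_every: 1000
tree_every: 1000
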