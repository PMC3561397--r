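# Scaled-down torus sweep usable with the CLI:
#   Rscript inst/cli/fashion.R sweep --config inst/extdata/example-sweep.yaml --out results.csv
kind: sweep
network_family: torus
rows: 11
cols: 11
r_grid: [0.0, 0.5, 1.0]
p_grid: [0.2, 0.5, 0.8]
replicates: 3
max_steps: 200
master_seed: 1
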