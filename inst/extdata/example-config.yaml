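# Scaled-down grid run: 4 x 4 cells, one replicate, small cohorts.
fractions: {from: 0.05, to: 0.20, by: 0.05}
folds: {from: 1.25, to: 2.0, by: 0.25}
replicates: 1
scenario: A
model: 1
seed: 1
n_gxe_ancestral: 5000
n_gxe_modern: 5000
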