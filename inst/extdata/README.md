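# Example data

`ttctf_synthetic.csv` (+ `.json` sidecar) is a fully synthetic dataset of 38
"samples" with the layout of a multi-sample creativity-test meta-analysis:
five subscores, a two-factor structure, and a `west` grouping dummy with
deliberate loading non-invariance on the fourth subscore and nonzero latent
mean differences. It is generated from the model, not derived from any real
data, and exists for examples and smoke tests. `ttctf_model.yaml` is the
matching model configuration for the command-line interface.
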