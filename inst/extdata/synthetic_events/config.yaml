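input_mode: events
input: manifest.tsv
out_dir: out
seed: 1.0
bootstrap_b: 200.0
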