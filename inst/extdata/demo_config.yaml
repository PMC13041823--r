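# Demo analysis configuration (see analysis_config() for all fields).
de_fdr: 0.10
de_lfc: 1
mediation_fdr: 0.05
adjacency_floor: 0.10
scale_free_cut: 0.85
powers_transcript: [3, 4, 5]
powers_gene: [14, 15, 16]
grid: demo
n_sims: 1000
bootstrap_B: 1000
bootstrap_n: 100
seed: 1
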