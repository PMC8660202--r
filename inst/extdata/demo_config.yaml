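# Two-tissue synthetic demo: rectal-like (16 case / 13 control) and
# bronchial-like (19 case / 9 control) cohorts over a shared 1000-gene
# universe, one scored interaction table with a planted hub, and one
# annotation set with a planted enriched term.
mode: simulate
seed: 11
tissue_a: rectal
tissue_b: bronchial
n_genes: 1000
n_case_a: 16
n_control_a: 13
n_case_b: 19
n_control_b: 9
n_planted_deg: 50
n_shared_planted: 10
effect_lfc: 2.0
noise_sd: 0.5
net_n_nodes: 200
net_m_attach: 2
planted_hub_extra_links: 30
n_terms: 50
planted_term_overlap: 30
lfc_cut: 0.5
fdr_cut: 0.05
min_confidence: 0.4
shell1_max: 20
shell2_max: 5
saturation_shell1: 50
fdr_cut_deg: 0.05
fdr_cut_hbs: 0.001
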