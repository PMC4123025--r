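# Demo configuration for run_pipeline(): a small three-city campaign,
# coarse-mass models per city, no grid export. Finishes in a few minutes.
seed: 2026
n_sites: 25
repeat_fraction: 0.3333333
outcomes: mass
scopes: city
max_vars: 8
max_params: 6
log_transform: false
drop_outliers_3sd: false
grid: false
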