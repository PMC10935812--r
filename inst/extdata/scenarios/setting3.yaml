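label: setting3
alpha: [4.5, -0.2, -0.2]
delta: [-1.0, 0.0, 2.0]
shape_p: 6
missing_link: logit
followup_c: 50
score_beta: [8, 2]
score_z_dependent: false
unequivocal_threshold: 0.8
error_base: 1.8
'n': 1000
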