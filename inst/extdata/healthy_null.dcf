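eta: 7.27e-5
iota: 0.015
beta: 0.025
kappa_diff: 4.5e-5
L_y: 0.5
L_z: 0.04
p_bar: 6000
model_name: null
dt: 0.25
T: 730
seed: 1
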