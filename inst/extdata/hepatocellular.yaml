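# Hepatocellular carcinoma scenario: MS engine, dissemination proportional
# to volume, m calibrated against the numerical colony-size reference so
# that the visible-colony count (>= 4.6e+07 cells) at day 1110 matches.
scenario: hepatocellular
type: cascade
engine: MS
b: 7.3e+10
mu: 0.00286
d_i: 0.6666666666666666
m: calibrate
alpha_d: 1
T_env: 1
c_frac: 1.0e-4
grid_dt: 1
horizon: 1400
max_order: 1
variant: primary_like
seed: 1
eval_times: [1110, 1310]
visibility_threshold: 4.6e+07
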