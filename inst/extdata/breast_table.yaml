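# Breast-cancer registry summary grid (probability and mean time of first
# metastasis formation), normalized to 1.1% visible metastases at pT1.
scenario: breast
type: breast_table
engine: MS
grid_dt: 2
n_courses: 2000
seed: 1
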