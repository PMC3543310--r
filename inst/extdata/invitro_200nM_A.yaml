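# Reference in vitro experiment: 200 nM androstenedione added to
# 600,000 granulosa cells in 2 ml, 48 h, inter-study factor 0.685
# (the calibrated value of the baseline study).  Add fsh_ng_ml: 20
# for the FSH-induced variant.
cells_per_ml: 300000
volume_ml: 2
medium_nM:
  A: 200
fsh_ng_ml: 0
sigma_L: 0.685
duration_min: 2880
snapshot_min: 2880
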