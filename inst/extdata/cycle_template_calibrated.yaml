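# Estrous-cycle forcing template (4-day cycle, minutes).
# Cycle time 0 = metestrus onset; stage onsets: metestrus 0,
# diestrus 1440, proestrus 2880, estrus 4320.
#
# Input waveforms are smooth unit-peak bumps with an optional
# post-ovulatory dip; they are calibration constructs, constrained only
# by the ovarian concentration/flux profiles they produce.  This
# bundled template was tuned so that the baseline in vivo flux analysis
# reproduces the reference A->E1 rates at the three sampled stages
# (6.09 / 6.17 / 5.10 e-9 pmoles/min/cell).
period_min: 5760
Q_base:            # baseline input rates (pg/min FSH, pmoles/min steroids)
  FSH: 330
  A: 1.2
  T: 3
Q_scale:           # magnitudes of the cyclic component
  FSH: 1450
  A: 18
  T: 13
shapes:
  FSH:
    peak_min: 4300      # late-proestrus surge
    width_min: 200
  A:
    peak_min: 4300
    width_min: 181
    dip_peak_min: 5784  # broad post-ovulatory androgen decline
    dip_width_min: 1793
    dip_depth: 0.0375
  T:
    peak_min: 4300
    width_min: 181
geometry:           # constant compartment geometry within the 0.05-ml
  N_GCs: 1.306e7    # diestrus ovary; granulosa and "other" cells share
  N_others: 1.306e7 # the non-extracellular volume
  V_ext: 0.042959
  V_others: 0.0035206
stage_times:        # representative sampling times within the cycle
  metestrus: 720
  diestrus: 2160
  proestrus: 3600
  estrus: 5500
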