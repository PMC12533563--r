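# Prostate cancer test panel. Operating points from Vickers et al. (2013),
# Clin Chem 59(1) (biopsy cohort with elevated PSA; 26% tested positive).
# Testing losses are expressed directly as ratios to the treatment benefit:
# the benefit of a true-positive biopsy/treatment pathway is taken as ten
# times the utility loss of a TRUS examination, so lDx/b = 0.1 for TRUS and
# 0.01 for each blood marker.
name: prostate
description: >
  Free-to-total PSA (FT, 20% cutoff), human kallikrein 2 (hK2, 0.075 ng/mL
  cutoff) and transrectal ultrasound (TRUS, 50 cm^3 cutoff) for prostate
  cancer detection.
rho_default: 0.26
tests:
- name: FT
  sensitivity: 0.91
  specificity: 0.40
  loss_over_b: 0.01
  source: Vickers et al. (2013), free-to-total PSA, cutoff 20%
- name: hK2
  sensitivity: 0.51
  specificity: 0.78
  loss_over_b: 0.01
  source: Vickers et al. (2013), human kallikrein 2, cutoff 0.075 ng/mL
- name: TRUS
  sensitivity: 0.84
  specificity: 0.34
  loss_over_b: 0.1
  source: Vickers et al. (2013), transrectal ultrasound, cutoff 50 cm^3
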