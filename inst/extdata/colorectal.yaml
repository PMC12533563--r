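# Colorectal cancer screening panel. Test accuracies and costs after
# Pickhardt et al. (2003) and Ladabaum & Mannalithara (2016). Colonoscopy
# carries a perforation risk of 0.04% with 7.5% mortality; at 15 years of
# residual life expectancy this values the expected harm at 6e-4 QALY.
# Treatment: willingness to pay USD 100000/QALY, 1.5 QALY gain, USD 75000
# cost, hence benefit b = 100000 * 1.5 - 75000 = USD 75000.
name: colorectal
description: >
  Fecal immunochemical test (FIT), multitarget stool DNA (MT) and
  colonoscopy (COL) for colorectal cancer screening.
frame:
  lambda: 100000
  qaly_gain: 1.5
  treatment_cost: 75000
tests:
- name: FIT
  sensitivity: 0.733
  specificity: 0.964
  cost: 19
  source: Ladabaum & Mannalithara (2016), fecal immunochemical test
- name: MT
  sensitivity: 0.933
  specificity: 0.898
  cost: 649
  source: Ladabaum & Mannalithara (2016), multitarget stool DNA
- name: COL
  sensitivity: 0.887
  specificity: 0.796
  cost: 1400
  harm: 0.0006
  source: Pickhardt et al. (2003); perforation harm 6e-4 QALY
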