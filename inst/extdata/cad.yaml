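# Stable coronary artery disease (CAD) panel. Test accuracies and costs
# after Min et al. (2017): treatment loss l = USD 55000 for patients at 20%
# pre-test probability, benefit b = USD 105000. Threshold reproductions use
# the calibrated benefit-loss ratio b/l = 1.9 (rho = 1/2.9), chosen so that
# the ETT test threshold matches the 15% lower bound of the ESC 2013
# guidelines; the CCTA test-treatment threshold then falls at 87%.
name: cad
description: >
  Exercise treadmill testing (ETT), stress echocardiography (SE),
  myocardial perfusion scintigraphy (MPS) and coronary computed tomographic
  angiography (CCTA) for stable coronary artery disease.
frame:
  benefit: 105000
  loss: 55000
benefit_loss_ratio: 1.9
tests:
- name: ETT
  sensitivity: 0.68
  specificity: 0.77
  cost: 100
  source: Min et al. (2017), exercise treadmill testing
- name: SE
  sensitivity: 0.867
  specificity: 0.807
  cost: 340
  source: Min et al. (2017), stress echocardiography
- name: MPS
  sensitivity: 0.806
  specificity: 0.747
  cost: 819
  source: Min et al. (2017), myocardial perfusion scintigraphy
- name: CCTA
  sensitivity: 0.937
  specificity: 0.847
  cost: 394
  source: Min et al. (2017), coronary CT angiography
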