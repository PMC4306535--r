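# Default analysis configuration. Thresholds are in physical units
# (ADC in mm^2/s, Tmax in seconds).
thresholds:
  faWm: 0.15          # white-matter mask: FA strictly greater than this
  adcCore: 6.0e-4     # infarct core: ADC strictly below this (mm^2/s)
  tmaxRoiK: 2.0       # automatic perfusion ROI: contralateral mean + k*SD
deconvolution:
  thresholdFrac: 0.10 # singular values below this fraction of the largest are dropped
  interpolateTmax: false
statistics:
  splitUnit: person
  minGroupSize: 2
  nPermutations: 10000
  alpha: 0.05
segmentation:
  coreWithinRoi: true # restrict the ADC-defined core to the perfusion ROI
split:
  changepoint: 5.4    # s
  faLow: 0.390
  faHigh: 0.423
  faSubgroupSD: 0.014
  tmaxRange: [2.0, 9.0]
association:
  rhoTmaxFaHypoperfused: 0.561
seed: 1
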