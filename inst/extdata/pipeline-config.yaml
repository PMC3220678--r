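# Example pipeline configuration.
# d: cytoplasm dilation distance in pixels (6..20)
# e: nuclear erosion distance in pixels (2..6)
# alpha: prediction-band tail probability (0.005 = 99.5% band)
d: 8
e: 3
alpha: 0.005
maxShift: 20
minAreaFraction: 0.5
logSigma: 3
seed: 1
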