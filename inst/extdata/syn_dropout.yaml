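# Visual-dropout robustness: 62 frames, 12 blanked.
nFrames: 62
trajectory: circular
laps: 1
radius: 20
standoff: 50
frameSize: [368, 378]
focal: 500
seed: 1
nu: 1
sigmaV: 1
nPoints: 40
blank: [7, 11, 12, 23, 24, 37, 38, 42, 43, 45, 51, 54]
W: 5
chiE: 3
kClusters: 3
subsetLen: 5
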