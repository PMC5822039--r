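# Drift-comparison experiment: 150-frame circular sweep (4 laps),
# sigma_v = 1 px correspondence noise, nu = 1 EMT noise (1 deg / 1 mm).
nFrames: 150
trajectory: circular
laps: 4
radius: 20
standoff: 50
frameSize: [368, 378]
focal: 500
seed: 1
nu: 1
sigmaV: 1
nPoints: 40
W: 5
chiE: 3
kClusters: 3
subsetLen: 5
sigmaEmtRotDeg: 1
sigmaEmtTransMm: 1
sigmaPRotDeg: 0.5
sigmaPTransMm: 0.5
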