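# EMT-noise sweep: 17-frame short-arc subset, seven noise multipliers.
nFrames: 17
trajectory: circular
laps: 0.05
radius: 20
standoff: 50
frameSize: [368, 378]
focal: 500
seed: 1
sigmaV: 1
nPoints: 40
nuValues: [0.125, 0.25, 0.5, 1, 2, 3, 4]
W: 5
chiE: 3
kClusters: 3
subsetLen: 5
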