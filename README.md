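# fetomosaic

Drift-free sequential mosaicking of a planar scene by probabilistic fusion
of **visual point correspondences** with **electromagnetic-tracker (EMT)
pose measurements** — the setting of fetoscopic imaging of the placenta,
where a surgeon needs a map of the vascular territory but the scope sees
only a few square centimetres at a time.

Chaining pairwise homographies estimated from feature matches (the classical
mosaicking recipe) accumulates error without bound and breaks outright on a
frame with no usable visual content. Raw EMT poses are globally consistent
but jittery. `fetomosaic` fuses the two: it estimates all camera poses
`x_k = [r_k' t_k']'` (rotation vector + translation) and the scene plane
`π = n/d` by minimizing

    C_v + C_EMT + C_p

where

* `C_v` — visual term: for each matched pair of frames `(m, l)`, squared
  pixel distance between matched points and their propagation through the
  plane-induced pairwise homography `H_l H_m^{-1}`, with
  `H_k = K (R_k − t_k π') K^{-1}`, weighted by `σ_v²` and a per-pair count
  normalization;
* `C_EMT` — tracker term: `Σ_k (z_k − x_k)' Σ_EMT^{-1} (z_k − x_k)` for the
  per-frame EMT measurements `z_k`;
* `C_p` — constant-velocity motion prior:
  `Σ_k (x_k − μ_p(x_{k−1}, x_{k−2}))' Σ_p^{-1} (…)` with
  `μ_p` decomposed from `T_{k−1} T_{k−2}^{-1} T_{k−1}`.

The batch solver (`solveBAVisEMT()`) is bundle adjustment augmented with
the EMT and prior terms. The sequential estimator (`runSequential()`,
"LBAVis+EMT") is a sliding-window local bundle adjustment: only the newest
`χe` cameras and the plane are re-estimated per iteration (window size
`W = χe + χg`), fixed cameras enter as constants, and spatially distributed
**anchor** frames — selected by K-means over projected image footprints —
contribute wide-baseline visual constraints on the plane. Frames with no
visual data ride through on the EMT and prior terms alone.

Also included: a pairwise-chaining baseline (`pairvisChain()`), an EMT-only
composition baseline (`emtOnlyComposition()`), reprojection-grid drift
metrics (`frameError()`, `mosaicError()`), feathered mosaic rendering
(`warpBlend()`), a Harris/RANSAC correspondence front end
(`detectAndMatch()`), a full synthetic-scene simulator (`simulateScene()`),
three scripted experiments (`runDriftExperiment()`, `runNoiseSweep()`,
`runDropoutExperiment()`), and a small CLI (`inst/cli/fetomosaic.R`,
subcommands `simulate | match | bundle | mosaic | evaluate | compare`, with
ready-made configs under `inst/extdata/`).

See the methods vignette (`vignettes/fused-mosaicking-methods.Rmd`) for the
model, its assumptions, the design decisions and the known limitations.

## Worked example

Simulate a noisy 60-frame circular sweep (EMT noise 1°/1 mm, matching noise
1 px), run the sequential estimator, and score both it and the raw-tracker
baseline against the ground truth:

```r
library(fetomosaic)

cfg <- sceneConfig(nFrames = 60, laps = 1, seed = 1)
sim <- simulateScene(cfg, nu = 1, sigmaV = 1)
sim
#> SyntheticSequence: 60 frames (368x378 px), 0 rendered, 0 blanked
#> CorrespondenceCollection: 59 pairs, 2360 matches total

fit <- runSequential(emtMeasurements(sim), sim@correspondences,
                     sim@intrinsics, sim@frameSize, lbaConfig(),
                     corrProvider = syntheticCorrProvider(sim, seed = 1))
fit
#> LBAVis+EMT result: 60 poses over 20 iterations (0 failed windows)
#>   plane: az -87.0 deg, el -88.8 deg, d 40.13 mm
#>   compose-at-fix vs recompose-at-end divergence: 0.035

errorReport(fit$homographies, sim@groundTruth@homographies, sim@frameSize)
#> ErrorReport: 60 frames, e_M = 10.86 px (max e_j = 14.17 px)

errorReport(emtOnlyComposition(emtMeasurements(sim), truePlane(sim),
                               sim@intrinsics),
            sim@groundTruth@homographies, sim@frameSize)
#> ErrorReport: 60 frames, e_M = 17.07 px (max e_j = 43.61 px)
```

`e_M` is the mean, over frames, of the per-frame error `e_j`: the average
displacement of a 100×100 pixel grid between its mosaic-space projections
under the estimated and true homographies. The fused estimate (10.9 px,
bounded over time) beats the jittery EMT-only composition (17.1 px, spikes
to 44 px) even though the latter is given the true plane; the estimated
plane (40 mm against a 50 mm truth) reflects how weakly a single short
sweep constrains depth — it tightens as laps accumulate and anchors gain
baseline. On the same data the pairwise chain's error *grows* with frame
index; `runDriftExperiment()` quantifies that contrast with a slope test.

## File formats

CSV throughout: poses/EMT as `frame, rx, ry, rz, tx, ty, tz` (radians, mm);
homographies as `frame, h11..h33` (row-major); correspondences as
`m, l, xA, yA, xB, yB`. Intrinsics and planes are small JSON objects;
run configs and manifests are YAML; frames are PNG. `writeSequence()` /
`loadSequence()` round-trip a full simulated acquisition directory.

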