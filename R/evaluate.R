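## Drift metrics and the scripted experiment protocols: drift comparison,
## EMT-noise sweep and visual-dropout robustness.

#' Reprojection-grid error of one homography against ground truth
#'
#' Mean, over a regular `nGrid` x `nGrid` lattice of points spanning the
#' frame (corners included), of the Euclidean distance between the points'
#' mosaic-space projections under the estimated and ground-truth inverse
#' homographies. Invariant to the arbitrary scale of either homography.
#'
#' @param H,Hgt Estimated and ground-truth mosaic-to-frame homographies.
#' @param frameSize Integer `c(w, h)`.
#' @param nGrid Lattice points per side (default 100, i.e. 100^2 points).
#' @return Scalar error `e_j` in pixels.
#' @export
frameError <- function(H, Hgt, frameSize, nGrid = 100L) {
  xs <- seq(0, frameSize[1] - 1, length.out = nGrid)
  ys <- seq(0, frameSize[2] - 1, length.out = nGrid)
  grid <- cbind(rep(xs, each = nGrid), rep(ys, nGrid))
  a <- applyHomography(solve(H), grid)
  b <- applyHomography(solve(Hgt), grid)
  mean(sqrt(rowSums((a - b)^2)))
}

#' Aggregate mosaic error
#'
#' Arithmetic mean of per-frame errors `e_j`.
#'
#' @param errors Non-empty numeric vector of per-frame errors.
#' @return Scalar `e_M` (pixels).
#' @export
mosaicError <- function(errors) {
  if (length(errors) == 0) stop("invalid-argument: no frame errors")
  mean(errors)
}

#' Error report for a collection of homographies
#'
#' @param homographies,gtHomographies Lists of estimated / ground-truth
#'   mosaic-to-frame homographies (same length).
#' @param frameSize Integer `c(w, h)`.
#' @param nGrid Lattice points per side.
#' @return An [ErrorReport-class].
#' @export
errorReport <- function(homographies, gtHomographies, frameSize,
                        nGrid = 100L) {
  stopifnot(length(homographies) == length(gtHomographies))
  ej <- vapply(seq_along(homographies), function(j)
    frameError(homographies[[j]], gtHomographies[[j]], frameSize, nGrid),
    numeric(1))
  new("ErrorReport", perFrame = ej, eM = mosaicError(ej),
      nGrid = as.integer(nGrid), frameSize = as.integer(frameSize))
}

#' EMT-only mosaic composition
#'
#' Composes per-frame homographies directly from the raw EMT measurements and
#' a known plane — the jittery baseline whose error scales with the tracker
#' noise, against which the fused estimator is compared.
#'
#' @param Z N x 6 matrix of EMT measurements.
#' @param plane Plane 3-vector (typically the ground truth).
#' @param K Intrinsics.
#' @return List of homographies.
#' @export
emtOnlyComposition <- function(Z, plane, K) {
  composeMosaicHomographies(Z, plane, K)
}

## OLS slope of e_j against frame index with a one-sided (slope > 0) p-value.
driftSlope <- function(ej) {
  frame <- seq_along(ej)
  fit <- summary(lm(ej ~ frame))
  slope <- fit$coefficients["frame", "Estimate"]
  tval <- fit$coefficients["frame", "t value"]
  pOneSided <- stats::pt(tval, df = fit$df[2], lower.tail = FALSE)
  c(slope = slope, p = pOneSided)
}

#' Drift-comparison experiment
#'
#' Simulates one noisy sequence and contrasts the drifting pairwise baseline
#' (PairVis) with the sequential fused estimator (LBAVis+EMT) — and, for
#' short sequences, the batch solvers — using per-frame reprojection errors.
#' The characteristic signature: the PairVis error grows with frame index
#' (positive OLS slope), while the fused estimator's error stays bounded.
#'
#' @param config A [sceneConfig()].
#' @param nu EMT noise multiplier of the simulated data.
#' @param sigmaV Correspondence noise (px).
#' @param nPoints Correspondences per pair.
#' @param lba An [lbaConfig()].
#' @param visual,emt,motion Noise models used by the estimators (note: the
#'   EMT model is the conservative default level, not re-tuned to `nu`).
#' @param runBatch Logical; also run batch BAVis+EMT (defaults to sequences
#'   of at most 40 frames).
#' @param nGrid Metric lattice points per side.
#' @return List: `reports` (named [ErrorReport-class]s), `pairvis`
#'   (slope/p-value), `lbaBounded` (max `e_j` over the last third at most
#'   twice the max over the first third), `sequence`, `lbaResult`.
#' @export
runDriftExperiment <- function(config = sceneConfig(), nu = 1, sigmaV = 1,
                               nPoints = 40, lba = lbaConfig(),
                               visual = visualNoiseModel(),
                               emt = emtNoiseModel(), motion = motionModel(),
                               runBatch = config$nFrames <= 40,
                               nGrid = 100L) {
  sim <- simulateScene(config, nu = nu, sigmaV = sigmaV, nPoints = nPoints)
  n <- length(sim)
  gtH <- sim@groundTruth@homographies
  provider <- syntheticCorrProvider(sim, nPoints = nPoints, sigmaV = sigmaV,
                                    seed = config$seed + 104729L)
  reports <- list()
  pairvisH <- pairvisChain(sim@correspondences, n)
  reports$PairVis <- errorReport(pairvisH, gtH, sim@frameSize, nGrid)
  fit <- runSequential(sim@emt, sim@correspondences, sim@intrinsics,
                       sim@frameSize, lba, visual, emt, motion,
                       corrProvider = provider)
  reports$LBAVisEMT <- errorReport(fit$homographies, gtH, sim@frameSize,
                                   nGrid)
  if (runBatch) {
    ba <- solveBAVisEMT(sim@correspondences, sim@emt, sim@intrinsics,
                        planeInit = lba$planeInit, visual = visual,
                        emt = emt, motion = motion)
    reports$BAVisEMT <- errorReport(ba$homographies, gtH, sim@frameSize,
                                    nGrid)
  }
  ejLba <- frameErrors(reports$LBAVisEMT)
  third <- max(1L, n %/% 3L)
  list(reports = reports,
       pairvis = driftSlope(frameErrors(reports$PairVis)),
       lbaBounded = max(utils::tail(ejLba, third)) <=
         2 * max(utils::head(ejLba, third)),
       lbaTailHeadRatio = max(utils::tail(ejLba, third)) /
         max(utils::head(ejLba, third)),
       sequence = sim, lbaResult = fit)
}

#' EMT-noise sweep experiment
#'
#' For each noise multiplier `nu`, regenerates the EMT measurements of a
#' short sequence (fresh seed per cell, shared trajectory and
#' correspondences), then compares the fused sequential estimate against the
#' EMT-only composition with the ground-truth plane. The EMT-only error grows
#' roughly linearly with `nu`; fusion suppresses the jitter.
#'
#' @param nuValues Noise multipliers (>= 0).
#' @param config A [sceneConfig()]; the default matches the 17-frame
#'   pairwise-quality setting.
#' @param sigmaV,nPoints Correspondence noise and count.
#' @param lba An [lbaConfig()].
#' @param visual,emt,motion Noise models held fixed across the sweep.
#' @param nGrid Metric lattice points per side.
#' @return `data.frame(nu, eMFusion, eMEmtOnly)`.
#' @export
runNoiseSweep <- function(nuValues = c(0.125, 0.25, 0.5, 1, 2, 3, 4),
                          config = sceneConfig(nFrames = 17, laps = 0.05),
                          sigmaV = 1, nPoints = 40, lba = lbaConfig(),
                          visual = visualNoiseModel(), emt = emtNoiseModel(),
                          motion = motionModel(), nGrid = 100L) {
  stopifnot(all(nuValues >= 0))
  sim0 <- simulateScene(config, nu = 0, sigmaV = sigmaV, nPoints = nPoints)
  gtH <- sim0@groundTruth@homographies
  provider <- syntheticCorrProvider(sim0, nPoints = nPoints, sigmaV = sigmaV,
                                    seed = config$seed + 104729L)
  rows <- lapply(seq_along(nuValues), function(i) {
    nu <- nuValues[i]
    Z <- simulateEMT(truePoses(sim0), nu = nu,
                     seed = config$seed + 7919L + i)
    fit <- runSequential(Z, sim0@correspondences, sim0@intrinsics,
                         sim0@frameSize, lba, visual, emt, motion,
                         corrProvider = provider)
    eFus <- errorReport(fit$homographies, gtH, sim0@frameSize, nGrid)@eM
    eEmt <- errorReport(emtOnlyComposition(Z, truePlane(sim0),
                                           sim0@intrinsics),
                        gtH, sim0@frameSize, nGrid)@eM
    data.frame(nu = nu, eMFusion = eFus, eMEmtOnly = eEmt)
  })
  do.call(rbind, rows)
}

#' Visual-dropout robustness experiment
#'
#' Blanks a set of frames of a simulated sequence (no correspondences touch
#' them; the EMT measurements remain), runs the sequential estimator on both
#' the blanked and intact versions at identical seeds, and attempts the
#' pairwise baseline on the blanked input (which must fail with a broken
#' chain).
#'
#' @param config A [sceneConfig()]; default 62 frames.
#' @param blank Frame indices to blank; the default is the 12-frame dropout
#'   pattern used in the robustness study.
#' @param nu,sigmaV,nPoints Simulation noise settings.
#' @param lba An [lbaConfig()].
#' @param visual,emt,motion Noise models.
#' @param nGrid Metric lattice points per side.
#' @return List: `eMDropout`, `eMClean`, `ratio`, `posesEstimated`,
#'   `pairvisError` (the broken-chain condition message), `fit`, `sequence`.
#' @export
runDropoutExperiment <- function(config = sceneConfig(nFrames = 62, laps = 1),
                                 blank = c(7, 11, 12, 23, 24, 37, 38, 42, 43,
                                           45, 51, 54),
                                 nu = 1, sigmaV = 1, nPoints = 40,
                                 lba = lbaConfig(),
                                 visual = visualNoiseModel(),
                                 emt = emtNoiseModel(),
                                 motion = motionModel(), nGrid = 100L) {
  simClean <- simulateScene(config, nu = nu, sigmaV = sigmaV,
                            nPoints = nPoints)
  simDrop <- blankFrames(simClean, blank)
  gtH <- simClean@groundTruth@homographies
  provClean <- syntheticCorrProvider(simClean, nPoints, sigmaV,
                                     seed = config$seed + 104729L)
  provDrop <- syntheticCorrProvider(simDrop, nPoints, sigmaV,
                                    seed = config$seed + 104729L)
  fitClean <- runSequential(simClean@emt, simClean@correspondences,
                            simClean@intrinsics, simClean@frameSize, lba,
                            visual, emt, motion, corrProvider = provClean)
  fitDrop <- runSequential(simDrop@emt, simDrop@correspondences,
                           simDrop@intrinsics, simDrop@frameSize, lba,
                           visual, emt, motion, corrProvider = provDrop)
  eClean <- errorReport(fitClean$homographies, gtH, simClean@frameSize,
                        nGrid)@eM
  eDrop <- errorReport(fitDrop$homographies, gtH, simDrop@frameSize,
                       nGrid)@eM
  pairvisError <- tryCatch({
    pairvisChain(simDrop@correspondences, length(simDrop))
    NULL
  }, error = function(e) conditionMessage(e))
  list(eMDropout = eDrop, eMClean = eClean, ratio = eDrop / eClean,
       posesEstimated = sum(!is.na(fitDrop$poses[, 1])),
       pairvisError = pairvisError, fit = fitDrop, sequence = simDrop)
}
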