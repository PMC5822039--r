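test_that("predictPose implements constant-velocity composition in SE(3)", {
  set.seed(31)
  x <- randomPose()
  expect_equal(predictPose(x, x), x, tolerance = 1e-10)
  # linear extrapolation of pure translations
  expect_equal(predictPose(c(0, 0, 0, 1, 0, 0), rep(0, 6)),
               c(0, 0, 0, 2, 0, 0), tolerance = 1e-12)
  for (i in 1:20) {
    a <- randomPose(); b <- randomPose()
    Tbar <- poseMatrix(a) %*% solve(poseMatrix(b)) %*% poseMatrix(a)
    expect_lt(maxAbs(poseMatrix(predictPose(a, b)) - Tbar), 1e-10)
  }
})

test_that("visual residuals match the scalar projection oracle and define C_v", {
  K <- testIntrinsics()
  set.seed(32)
  xm <- randomPose(rmax = 0.2, tmax = 5)
  xl <- randomPose(rmax = 0.2, tmax = 5)
  plane <- randomPlane()
  pA <- c(80, 60)
  H <- pairwiseHomography(xl, xm, plane, K)
  pB <- applyHomography(H, pA) + c(0.7, -0.4)
  corr <- correspondenceCollection(list(correspondenceSet(1, 2, rbind(pA),
                                                          rbind(pB))))
  st <- problemState(rbind(xm, xl), plane)
  r <- visualResiduals(st, corr, visualNoiseModel(sigmaV = 2,
                                                  normalization = "none"), K)
  expect_equal(r, (pB - applyHomography(H, pA)) / 2, tolerance = 1e-9)
})

test_that("per-pair-count normalization makes a pair's cost invariant to duplicating its points", {
  K <- testIntrinsics()
  set.seed(33)
  sim <- tinyScene(nFrames = 4, sigmaV = 1, nPoints = 20)
  st <- problemState(truePoses(sim), truePlane(sim))
  s <- corrSet(sim@correspondences, 2, 3)
  dup <- correspondenceSet(2, 3, rbind(s@pointsA, s@pointsA),
                           rbind(s@pointsB, s@pointsB))
  vm <- visualNoiseModel(normalization = "per-pair-count")
  c1 <- sum(visualResiduals(st, correspondenceCollection(list(s)), vm, K2 <- sim@intrinsics)^2)
  c2 <- sum(visualResiduals(st, correspondenceCollection(list(dup)), vm, K2)^2)
  expect_equal(c1, c2, tolerance = 1e-12)
  # without normalization the duplicated pair costs twice as much
  vn <- visualNoiseModel(normalization = "none")
  expect_equal(2 * sum(visualResiduals(st, correspondenceCollection(list(s)),
                                       vn, K2)^2),
               sum(visualResiduals(st, correspondenceCollection(list(dup)),
                                   vn, K2)^2), tolerance = 1e-12)
})

test_that("EMT residuals equal the diagonal quadratic form of the measurement error", {
  set.seed(34)
  poses <- t(replicate(5, randomPose()))
  Z <- poses
  st <- problemState(poses, randomPlane())
  expect_identical(emtResiduals(st, Z, emtNoiseModel()), rep(0, 30))
  # identity covariance, single frame offset by (0,0,0,3,4,0): squared norm 25
  em1 <- list(var = rep(1, 6))
  Z2 <- poses; Z2[2, ] <- Z2[2, ] + c(0, 0, 0, 3, 4, 0)
  expect_equal(sum(emtResiduals(st, Z2, em1, targets = 2)^2), 25)
  # random case against dense matrix algebra
  em <- emtNoiseModel(sigmaRotDeg = c(0.5, 1, 2), sigmaTransMm = c(1, 2, 3))
  Z3 <- poses + matrix(rnorm(30, 0, 0.1), 5, 6)
  quad <- sum(vapply(1:5, function(k)
    t(Z3[k, ] - poses[k, ]) %*% diag(1 / em$var) %*% (Z3[k, ] - poses[k, ]),
    numeric(1)))
  expect_equal(sum(emtResiduals(st, Z3, em)^2), quad, tolerance = 1e-10)
})

test_that("motion-prior residuals follow the second-order Markov model", {
  set.seed(35)
  # exactly constant-velocity trajectory: zero residuals (also covered by the
  # trajectory tests); two frames: empty block
  st2 <- problemState(rbind(randomPose(), randomPose()), randomPlane())
  expect_length(motionPriorResiduals(st2, motionModel()), 0)
  # three random poses against an independent evaluation
  poses <- t(replicate(3, randomPose(rmax = 0.3)))
  mm <- motionModel(sigmaRotDeg = 2, sigmaTransMm = 0.7)
  st <- problemState(poses, randomPlane())
  r <- motionPriorResiduals(st, mm)
  Tbar <- poseMatrix(poses[2, ]) %*% solve(poseMatrix(poses[1, ])) %*%
    poseMatrix(poses[2, ])
  mu <- c(logSO3(Tbar[1:3, 1:3]), Tbar[1:3, 4])
  expect_equal(sum(r^2),
               sum((poses[3, ] - mu)^2 / mm$var), tolerance = 1e-10)
})

test_that("the stacked residual blocks reproduce the total cost by independent summation", {
  # -2 log posterior (up to constants) = C_v + C_EMT + C_p
  K <- testIntrinsics()
  set.seed(36)
  sim <- tinyScene(nFrames = 6, nu = 1, sigmaV = 1, nPoints = 15)
  poses <- truePoses(sim) + matrix(rnorm(36, 0, 0.01), 6, 6)
  st <- problemState(poses, truePlane(sim) * 1.02)
  vm <- visualNoiseModel(); em <- emtNoiseModel(); mm <- motionModel()
  Z <- emtMeasurements(sim)
  total <- sum(visualResiduals(st, sim@correspondences, vm,
                               sim@intrinsics)^2) +
    sum(emtResiduals(st, Z, em)^2) +
    sum(motionPriorResiduals(st, mm)^2)
  # independent: accumulate the three cost terms pair-by-pair / frame-by-frame
  cv <- 0
  for (s in sim@correspondences@sets) {
    H <- sim@intrinsics %*%
      (expSO3(st$poses[s@pair[2], 1:3]) - st$poses[s@pair[2], 4:6] %o% st$plane) %*%
      solve(expSO3(st$poses[s@pair[1], 1:3]) - st$poses[s@pair[1], 4:6] %o% st$plane) %*%
      solve(sim@intrinsics)
    mu <- applyHomography(H, s@pointsA)
    cv <- cv + sum((s@pointsB - mu)^2) / (vm$sigmaV^2 * length(s))
  }
  ce <- sum(t(Z - st$poses)^2 / em$var)
  cp <- 0
  for (k in 3:6) {
    mu <- predictPose(st$poses[k - 1, ], st$poses[k - 2, ])
    cp <- cp + sum((st$poses[k, ] - mu)^2 / mm$var)
  }
  expect_equal(total, cv + ce + cp, tolerance = 1e-8)
})

test_that("DLT homography estimation is exact on minimal and redundant clean data", {
  set.seed(37)
  H <- matrix(c(0.9, 0.05, 1e-4, -0.04, 1.05, -2e-4, 3, -2, 1), 3, 3)
  A4 <- rbind(c(0, 0), c(100, 10), c(15, 90), c(110, 105))
  B4 <- applyHomography(H, A4)
  Hhat <- estimatePairwiseHomography(correspondenceSet(1, 2, A4, B4))
  Hc <- canonicalizeHomography(H)
  expect_lt(min(maxAbs(Hhat - Hc), maxAbs(Hhat + Hc)), 1e-8)
  A <- cbind(runif(100, 0, 200), runif(100, 0, 200))
  B <- applyHomography(H, A)
  Hh2 <- estimatePairwiseHomography(correspondenceSet(1, 2, A, B))
  expect_lt(mean(sqrt(rowSums((applyHomography(Hh2, A) - B)^2))), 1e-8)
  expect_error(estimatePairwiseHomography(
    correspondenceSet(1, 2, A4[1:3, ], B4[1:3, ])), "insufficient-data")
  collinear <- cbind(1:6, 2 * (1:6))
  expect_error(estimatePairwiseHomography(
    correspondenceSet(1, 2, collinear, collinear)), "insufficient-data")
})

test_that("PairVis recovers noise-free chains exactly and breaks on missing pairs", {
  sim <- tinyScene(nFrames = 12, sigmaV = 0, nPoints = 25)
  Hs <- pairvisChain(sim@correspondences, 12)
  rep <- errorReport(Hs, sim@groundTruth@homographies, sim@frameSize, 40L)
  expect_lt(mosaicErrorValue(rep), 1e-6)
  # a chain over N frames consumes exactly N-1 adjacent sets
  expect_equal(length(sim@correspondences), 11)
  blanked <- blankFrames(sim, 5)
  expect_error(pairvisChain(blanked@correspondences, 12),
               "broken-chain.*frames 4 and 5")
})

test_that("solveBundle recovers ground truth from noise-free data and descends from any init", {
  sim <- tinyScene(nFrames = 10, sigmaV = 0, nPoints = 30)
  Z <- emtMeasurements(sim)                # nu = 0: exact
  fit <- solveBAVisEMT(sim@correspondences, Z, sim@intrinsics,
                       planeInit = c(0, 0, -1 / 30))
  expect_true(fit$report@converged)
  expect_lt(fit$report@finalCost, 1e-12)
  expect_lt(maxAbs(fit$state$poses[, 4:6] - truePoses(sim)[, 4:6]), 1e-6)
  expect_lt(maxAbs(fit$state$plane - truePlane(sim)) / maxAbs(truePlane(sim)),
            1e-8)
  expect_lte(fit$report@finalCost, fit$report@initialCost)
})

test_that("a plane-only solve recovers the plane with poses held fixed", {
  sim <- tinyScene(nFrames = 8, sigmaV = 0, nPoints = 25)
  st <- problemState(truePoses(sim), truePlane(sim) * 1.6,
                     freeMask = rep(FALSE, 8), planeFree = TRUE)
  out <- solveBundle(st, sim@correspondences, Z = emtMeasurements(sim),
                     K = sim@intrinsics, emtTargets = integer(0),
                     priorTargets = integer(0))
  expect_lt(maxAbs(out$state$plane - truePlane(sim)) / maxAbs(truePlane(sim)),
            1e-8)
  expect_identical(out$state$poses, truePoses(sim))  # fixed means fixed
  expect_lt(out$report@finalCost, out$report@initialCost)
})

test_that("vision-only bundle adjustment is gauge-invariant to the plane-scale initialization", {
  sim <- tinyScene(nFrames = 8, sigmaV = 0, nPoints = 30)
  P <- truePoses(sim)
  for (d0 in c(30, 80)) {
    init <- P + matrix(rnorm(48, 0, 0.002), 8, 6) * rep(c(1, 1, 1, 5, 5, 5),
                                                        each = 8)
    init[1, ] <- 0                     # gauge: pose 1 clamped to identity
    fit <- solveBAVis(sim@correspondences, init, sim@intrinsics,
                      planeInit = c(0, 0, -1 / d0))
    rep <- errorReport(fit$homographies, sim@groundTruth@homographies,
                       sim@frameSize, 30L)
    expect_lt(mosaicErrorValue(rep), 1e-4)
    # the recovered plane keeps the clamped distance
    expect_equal(1 / sqrt(sum(fit$state$plane^2)), d0, tolerance = 1e-6)
  }
})

test_that("fusion beats either source alone on a noisy sequence", {
  sim <- tinyScene(nFrames = 30, laps = 1, nu = 1, sigmaV = 1, nPoints = 40,
                   seed = 77)
  Z <- emtMeasurements(sim)
  gtH <- sim@groundTruth@homographies
  fit <- solveBAVisEMT(sim@correspondences, Z, sim@intrinsics,
                       planeInit = c(0, 0, -1 / 30))
  eFus <- mosaicErrorValue(errorReport(fit$homographies, gtH, sim@frameSize,
                                       40L))
  eEmt <- mosaicErrorValue(errorReport(
    emtOnlyComposition(Z, truePlane(sim), sim@intrinsics), gtH,
    sim@frameSize, 40L))
  expect_lte(eFus, eEmt)
  # translation RMSE of the fused estimate at most the EMT noise std (1 mm)
  rmse <- sqrt(mean((fit$state$poses[, 4:6] - truePoses(sim)[, 4:6])^2))
  expect_lte(rmse, 1)
})
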