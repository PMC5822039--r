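## The probabilistic core: residual blocks for the visual, EMT and
## constant-velocity motion-prior terms, pairwise DLT homography estimation,
## the PairVis chaining baseline, and the damped Gauss-Newton
## (Levenberg-Marquardt) bundle solvers with and without EMT fusion.
##
## The model minimizes  C_v + C_EMT + C_p  over camera poses X and plane pi:
##   C_v   = sum over pairs, points of |p_B - mu_v(x_l, x_m, pi, p_A)|^2 / (sigma_v^2 c)
##   C_EMT = sum_k (z_k - x_k)' Sigma_EMT^-1 (z_k - x_k)
##   C_p   = sum_{k>=3} (x_k - mu_p(x_{k-1}, x_{k-2}))' Sigma_p^-1 (...)
## with mu_v the projection through the plane-induced pairwise homography and
## mu_p the constant-velocity prediction. c is the per-pair normalization
## ("pragmatic correction factor") that stops large correspondence counts from
## overwhelming the EMT term.

#' Noise models for the three cost terms
#'
#' `visualNoiseModel` describes the matching noise: standard deviation
#' `sigmaV` in pixels plus the normalization policy for the correspondence
#' count (the correction factor that keeps a pair's total weight bounded
#' regardless of how many matches it contributes). `emtNoiseModel` and
#' `motionModel` hold the diagonal covariances of the EMT measurement noise
#' and of the constant-velocity motion prior, entered as per-axis standard
#' deviations in degrees / mm and stored as variances in rad^2 / mm^2.
#'
#' @param sigmaV Visual noise std (px, > 0).
#' @param normalization `"per-pair-count"` (default: each pair's squared cost
#'   is divided by its own correspondence count), `"global-count"` (divided by
#'   the mean count over pairs) or `"none"`.
#' @return A list with class tag, consumed by the residual functions.
#' @export
visualNoiseModel <- function(sigmaV = 1,
                             normalization = c("per-pair-count", "none",
                                               "global-count")) {
  stopifnot(sigmaV > 0)
  list(sigmaV = sigmaV, normalization = match.arg(normalization))
}

#' @rdname visualNoiseModel
#' @param sigmaRotDeg,sigmaTransMm Per-axis standard deviations (deg, mm),
#'   scalars or 3-vectors.
#' @export
emtNoiseModel <- function(sigmaRotDeg = 1, sigmaTransMm = 1) {
  v <- c(rep(sigmaRotDeg, length.out = 3) * pi / 180,
         rep(sigmaTransMm, length.out = 3))^2
  stopifnot(all(v > 0))
  list(var = v)
}

#' @rdname visualNoiseModel
#' @export
motionModel <- function(sigmaRotDeg = 0.5, sigmaTransMm = 0.5) {
  v <- c(rep(sigmaRotDeg, length.out = 3) * pi / 180,
         rep(sigmaTransMm, length.out = 3))^2
  stopifnot(all(v > 0))
  list(var = v)
}

#' Optimization state: poses, plane and the free/fixed partition
#'
#' @param poses N x 6 pose matrix (current values; fixed rows are constants).
#' @param plane Plane 3-vector.
#' @param freeMask Logical N-vector: which poses are optimized.
#' @param planeFree Logical: is the plane optimized.
#' @return A list of class `"problemState"`.
#' @export
problemState <- function(poses, plane, freeMask = rep(TRUE, nrow(poses)),
                         planeFree = TRUE) {
  stopifnot(ncol(poses) == 6, length(plane) == 3,
            length(freeMask) == nrow(poses))
  if (!any(freeMask) && !planeFree)
    stop("invalid-argument: nothing to estimate")
  structure(list(poses = poses, plane = plane, freeMask = freeMask,
                 planeFree = planeFree), class = "problemState")
}

#' Constant-velocity pose prediction
#'
#' Predicts pose k from the two previous poses by composing the last pose
#' with the last pairwise velocity:
#' `T_pred = T_{k-1} T_{k-2}^-1 T_{k-1}`, decomposed back to a 6-vector.
#'
#' @param xkm1,xkm2 Pose 6-vectors at times k-1 and k-2.
#' @return Predicted pose 6-vector (canonical rotation-vector branch).
#' @export
predictPose <- function(xkm1, xkm2) {
  poseCompose(poseCompose(xkm1, poseInverse(xkm2)), xkm1)
}

## Pick the rotation-vector branch of r (canonical, |r| <= pi) closest to
## ref: candidates r and r -/+ 2*pi*axis. Needed when a trajectory's
## accumulated z-rotation crosses the +/-pi boundary between frames.
nearestLogBranch <- function(r, ref) {
  th <- sqrt(sum(r * r))
  if (th < 1e-12) return(r)
  ax <- r / th
  cand <- rbind(r, ax * (th - 2 * pi), ax * (th + 2 * pi))
  d <- rowSums((cand - matrix(ref, 3, 3, byrow = TRUE))^2)
  cand[which.min(d), ]
}

## Plain-list view of a correspondence collection with per-set weights under
## the given visual model; hot path of the solver.
flattenCorrs <- function(corrs, model) {
  sets <- if (is(corrs, "CorrespondenceCollection")) corrs@sets else corrs
  sets <- Filter(function(s) length(s) > 0, sets)
  if (length(sets) == 0) return(list())
  counts <- vapply(sets, length, integer(1))
  cfac <- switch(model$normalization,
                 "none" = rep(1, length(sets)),
                 "per-pair-count" = counts,
                 "global-count" = rep(mean(counts), length(sets)))
  lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    list(m = s@pair[1], l = s@pair[2], A = s@pointsA, B = s@pointsB,
         w = 1 / (model$sigmaV * sqrt(cfac[i])))
  })
}

## Normalized (metric) part of the plane-induced homography, R - t pi'.
normalizedH <- function(x, plane) expSO3(x[1:3]) - x[4:6] %o% plane

#' Weighted visual residuals
#'
#' One weighted 2-vector per correspondence:
#' `w * (p_B - mu_v(x_l, x_m, pi, p_A))` in pixel coordinates, where `mu_v`
#' propagates `p_A` through the plane-induced pairwise homography
#' `K (R_l - t_l pi')(R_m - t_m pi')^-1 K^-1` and
#' `w = 1 / (sigma_v sqrt(c))` with `c` the normalization factor. The sum of
#' squares is the visual cost `C_v`.
#'
#' @param state A [problemState()].
#' @param corrs A [CorrespondenceCollection-class] (or list of sets).
#' @param model A [visualNoiseModel()].
#' @param K Intrinsics matrix.
#' @return Numeric residual vector.
#' @export
visualResiduals <- function(state, corrs, model, K) {
  flat <- flattenCorrs(corrs, model)
  visualResidualsFlat(state$poses, state$plane, flat, K)
}

visualResidualsFlat <- function(poses, plane, flat, K) {
  if (length(flat) == 0) return(numeric(0))
  Kinv <- solve(K)
  out <- vector("list", length(flat))
  for (i in seq_along(flat)) {
    f <- flat[[i]]
    Hm <- normalizedH(poses[f$m, ], plane)
    Hl <- normalizedH(poses[f$l, ], plane)
    H <- K %*% Hl %*% solve(Hm) %*% Kinv
    P <- cbind(f$A, 1) %*% t(H)
    if (any(abs(P[, 3]) <= 1e-12) || any(!is.finite(P)))
      stop(sprintf("degenerate-geometry: pair %d->%d", f$m, f$l))
    out[[i]] <- f$w * as.vector(f$B - P[, 1:2] / P[, 3])
  }
  unlist(out, use.names = FALSE)
}

#' Weighted EMT residuals
#'
#' Per targeted frame, the 6-vector `(z_k - x_k)` scaled per axis by
#' `Sigma_EMT^-1/2`; rotation difference taken directly on rotation-vector
#' components. The sum of squares is `C_EMT`.
#'
#' @inheritParams visualResiduals
#' @param Z N x 6 matrix of EMT measurements.
#' @param model An [emtNoiseModel()].
#' @param targets Frame indices carrying an EMT term (default: all).
#' @return Numeric residual vector (6 entries per target).
#' @export
emtResiduals <- function(state, Z, model, targets = seq_len(nrow(Z))) {
  if (length(targets) == 0) return(numeric(0))
  d <- Z[targets, , drop = FALSE] - state$poses[targets, , drop = FALSE]
  as.vector(t(d) / sqrt(model$var))
}

#' Weighted motion-prior residuals
#'
#' Per targeted frame `k >= 3`, the 6-vector
#' `Sigma_p^-1/2 (x_k - mu_p(x_{k-1}, x_{k-2}))`. In windowed problems the
#' targets are the estimated frames only, so the first two terms reach back
#' into the fixed cameras (the window-boundary terms). The rotation branch of
#' the prediction is chosen nearest to `x_k`'s rotation vector, keeping the
#' residual continuous when the accumulated rotation crosses the `pi`
#' boundary. The sum of squares is `C_p`.
#'
#' @inheritParams visualResiduals
#' @param model A [motionModel()].
#' @param targets Frame indices receiving a prior term (default `3:N`; indices
#'   below 3 are dropped).
#' @return Numeric residual vector (6 entries per target).
#' @export
motionPriorResiduals <- function(state, model,
                                 targets = seq_len(nrow(state$poses))) {
  poses <- state$poses
  targets <- targets[targets >= 3]
  if (length(targets) == 0) return(numeric(0))
  w <- 1 / sqrt(model$var)
  out <- matrix(0, 6, length(targets))
  for (i in seq_along(targets)) {
    k <- targets[i]
    mu <- predictPose(poses[k - 1, ], poses[k - 2, ])
    mu[1:3] <- nearestLogBranch(mu[1:3], poses[k, 1:3])
    out[, i] <- (poses[k, ] - mu) * w
  }
  as.vector(out)
}

#' Estimate a homography from point correspondences
#'
#' Normalized (Hartley-preconditioned) direct linear transform, refined by
#' Levenberg-Marquardt on the symmetric transfer error.
#'
#' @param corr A [CorrespondenceSet-class] with at least 4 non-collinear
#'   correspondences.
#' @param refine Logical; run the nonlinear refinement (default `TRUE`).
#' @return Canonicalized 3x3 homography mapping `pointsA` to `pointsB`.
#' @export
estimatePairwiseHomography <- function(corr, refine = TRUE) {
  A <- corr@pointsA; B <- corr@pointsB
  n <- nrow(A)
  if (n < 4) stop("insufficient-data: need at least 4 correspondences")
  H0 <- dltHomography(A, B)
  if (!refine) return(H0)
  h0 <- as.vector(H0)
  fn <- function(h) {
    H <- matrix(h, 3, 3)
    if (abs(det(H)) < 1e-14) return(rep(1e6, 4 * n))
    fw <- cbind(A, 1) %*% t(H)
    bw <- cbind(B, 1) %*% t(solve(H))
    if (any(abs(fw[, 3]) < 1e-12) || any(abs(bw[, 3]) < 1e-12))
      return(rep(1e6, 4 * n))
    c(as.vector(B - fw[, 1:2] / fw[, 3]), as.vector(A - bw[, 1:2] / bw[, 3]))
  }
  fit <- minpack.lm::nls.lm(par = h0, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 50, ftol = 1e-12, ptol = 1e-12))
  canonicalizeHomography(matrix(fit$par, 3, 3))
}

dltHomography <- function(A, B) {
  normalizePts <- function(P) {
    mu <- colMeans(P)
    d <- sqrt(rowSums((P - matrix(mu, nrow(P), 2, byrow = TRUE))^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * mu[1], -s * mu[2], 1), 3, 3)
    list(P = (P - matrix(mu, nrow(P), 2, byrow = TRUE)) * s, T = T)
  }
  na <- normalizePts(A); nb <- normalizePts(B)
  a <- na$P; b <- nb$P
  n <- nrow(a)
  M <- matrix(0, 2 * n, 9)
  M[seq(1, 2 * n, 2), ] <- cbind(-a[, 1], -a[, 2], -1, 0, 0, 0,
                                 b[, 1] * a[, 1], b[, 1] * a[, 2], b[, 1])
  M[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -a[, 1], -a[, 2], -1,
                                 b[, 2] * a[, 1], b[, 2] * a[, 2], b[, 2])
  sv <- svd(M, nu = 0, nv = 9)
  if (sv$d[8] / max(sv$d[1], .Machine$double.eps) < 1e-10)
    stop("insufficient-data: degenerate (collinear) correspondence geometry")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  canonicalizeHomography(solve(nb$T) %*% Hn %*% na$T)
}

#' PairVis: the chained pairwise baseline
#'
#' Estimates each adjacent pairwise homography from its correspondences and
#' composes the chain `H_j = H_{j,j-1} ... H_{2,1}` with `H_1 = I`. This is
#' the purely visual baseline whose error accumulates (drifts) with frame
#' index, and which breaks outright when any adjacent pair has no usable
#' matches.
#'
#' @param corrs A [CorrespondenceCollection-class] containing every adjacent
#'   pair `(k, k+1)`.
#' @param nFrames Number of frames in the chain.
#' @return List of `nFrames` canonicalized mosaic-to-frame homographies.
#' @export
pairvisChain <- function(corrs, nFrames) {
  Hs <- vector("list", nFrames)
  Hs[[1]] <- diag(3)
  for (k in 2:nFrames) {
    s <- corrSet(corrs, k - 1, k)
    if (is.null(s) || length(s) < 4)
      stop(sprintf(
        "broken-chain: no usable correspondences between frames %d and %d",
        k - 1, k))
    Hs[[k]] <- canonicalizeHomography(estimatePairwiseHomography(s) %*%
                                        Hs[[k - 1]])
  }
  Hs
}

## Evaluate the three cost terms of a state (used for reports and tests).
fusionCosts <- function(state, flat, K, Z = NULL, emt = NULL, motion = NULL,
                        emtTargets = NULL, priorTargets = NULL) {
  cv <- sum(visualResidualsFlat(state$poses, state$plane, flat, K)^2)
  ce <- if (!is.null(Z) && !is.null(emt))
    sum(emtResiduals(state, Z, emt, emtTargets)^2) else NA_real_
  cp <- if (!is.null(motion))
    sum(motionPriorResiduals(state, motion, priorTargets)^2) else NA_real_
  c(visual = cv, emt = ce, prior = cp)
}

#' Solve the fused bundle problem
#'
#' Minimizes the stacked weighted residuals (visual, plus EMT and
#' motion-prior terms when their models are supplied) over the free poses and
#' the plane by damped Gauss-Newton (Levenberg-Marquardt). With EMT
#' measurements the problem is fully anchored: the EMT term fixes the global
#' gauge and no pose is clamped. Without EMT (pure bundle adjustment) the
#' monocular gauge is fixed by clamping pose 1 (the caller keeps it out of
#' `freeMask`, typically at the identity) and the plane distance at its
#' initial value, leaving only the plane direction free.
#'
#' @param state A [problemState()] holding the initialization (with EMT
#'   available, initialize poses from the measurements).
#' @param corrs A [CorrespondenceCollection-class] (or list of sets); the
#'   visual term. May include pairs between fixed poses — those constrain
#'   only the plane.
#' @param Z N x 6 EMT measurement matrix, or `NULL` for vision-only.
#' @param K Intrinsics matrix.
#' @param visual,emt,motion Noise models ([visualNoiseModel()],
#'   [emtNoiseModel()], [motionModel()]); `emt`/`motion` may be `NULL` to drop
#'   their terms.
#' @param emtTargets,priorTargets Frame indices carrying EMT / prior terms;
#'   default: the free poses (for the prior, those with index >= 3).
#' @param control List: `maxIter` (default 100), `ftol`, `ptol` (1e-12).
#' @return `list(state =, report =)` with the optimized [problemState()] and a
#'   [SolveReport-class].
#' @export
solveBundle <- function(state, corrs, Z = NULL, K,
                        visual = visualNoiseModel(),
                        emt = if (!is.null(Z)) emtNoiseModel() else NULL,
                        motion = motionModel(),
                        emtTargets = NULL, priorTargets = NULL,
                        control = list()) {
  ctrl <- modifyList(list(maxIter = 100L, ftol = 1e-12, ptol = 1e-12), control)
  flat <- flattenCorrs(corrs, visual)
  if (is.null(Z)) emt <- NULL
  free <- which(state$freeMask)
  if (length(free) == 0 && !state$planeFree)
    stop("invalid-argument: nothing to estimate")
  if (length(flat) == 0 && is.null(emt))
    stop("invalid-argument: no residual terms")
  if (is.null(emtTargets)) emtTargets <- free
  if (is.null(priorTargets)) priorTargets <- free[free >= 3]
  visGauge <- is.null(Z) && state$planeFree
  d0 <- 1 / sqrt(sum(state$plane^2))          # clamped distance (vis gauge)

  packPlane <- function(plane) {
    if (!state$planeFree) return(numeric(0))
    if (visGauge) {
      s <- planeToSpherical(plane)
      c(s[1], s[2]) * pi / 180               # angles only, radians
    } else plane
  }
  unpackPlane <- function(p) {
    if (!state$planeFree) return(state$plane)
    if (visGauge) sphericalToPlane(p[1] * 180 / pi, p[2] * 180 / pi, d0)
    else p
  }
  par0 <- c(as.vector(t(state$poses[free, , drop = FALSE])),
            packPlane(state$plane))
  buildState <- function(par) {
    st <- state
    np <- 6L * length(free)
    if (np > 0)
      st$poses[free, ] <- matrix(par[seq_len(np)], ncol = 6, byrow = TRUE)
    if (state$planeFree)
      st$plane <- unpackPlane(par[(np + 1):length(par)])
    st
  }
  resFun <- function(par) {
    st <- buildState(par)
    r <- tryCatch(
      c(visualResidualsFlat(st$poses, st$plane, flat, K),
        if (!is.null(emt)) emtResiduals(st, Z, emt, emtTargets),
        if (!is.null(motion)) motionPriorResiduals(st, motion, priorTargets)),
      error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(rep(1e8, nRes))
    r
  }
  nRes <- 1L   # placeholder until first evaluation
  r0 <- tryCatch(
    c(visualResidualsFlat(state$poses, state$plane, flat, K),
      if (!is.null(emt)) emtResiduals(state, Z, emt, emtTargets),
      if (!is.null(motion)) motionPriorResiduals(state, motion, priorTargets)),
    error = function(e) stop("initialization error: ", conditionMessage(e)))
  if (any(!is.finite(r0))) stop("initialization error: non-finite residuals")
  nRes <- length(r0)
  # central-difference Jacobian: O(h^2) truncation keeps the attainable
  # parameter precision well below the forward-difference sqrt(eps) floor
  jacFun <- function(par) {
    h <- 6e-6 * pmax(abs(par), 0.05)
    J <- matrix(0, nRes, length(par))
    for (j in seq_along(par)) {
      pp <- par; pp[j] <- par[j] + h[j]
      pm <- par; pm[j] <- par[j] - h[j]
      J[, j] <- (resFun(pp) - resFun(pm)) / (2 * h[j])
    }
    J
  }
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = par0, fn = resFun, jac = jacFun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = ctrl$maxIter, ftol = ctrl$ftol,
                         ptol = ctrl$ptol, maxfev = 100000L)))
  stBest <- buildState(fit$par)
  initialCost <- sum(r0^2)
  finalCost <- sum(resFun(fit$par)^2)
  if (finalCost > initialCost) {            # LM must not accept ascent
    stBest <- state
    finalCost <- initialCost
  }
  costs <- fusionCosts(stBest, flat, K, Z, emt, motion, emtTargets,
                       priorTargets)
  report <- new("SolveReport",
                converged = fit$info %in% 1:4,
                iterations = as.integer(fit$niter),
                initialCost = initialCost, finalCost = finalCost,
                costVisual = costs[["visual"]], costEMT = costs[["emt"]],
                costPrior = costs[["prior"]], message = fit$message)
  list(state = stBest, report = report)
}

#' Batch solvers: fused bundle adjustment and vision-only bundle adjustment
#'
#' `solveBAVisEMT` solves the full-sequence fused problem (visual + EMT +
#' motion-prior terms), initialized at the EMT measurements. `solveBAVis`
#' solves pure bundle adjustment (visual term only) with pose 1 clamped to
#' its initialization and the plane distance clamped (monocular gauge).
#'
#' @param corrs A [CorrespondenceCollection-class].
#' @param Z N x 6 EMT measurements.
#' @param K Intrinsics.
#' @param planeInit Plane 3-vector initialization.
#' @param poseInit N x 6 pose initialization (`solveBAVisEMT` defaults to
#'   `Z`; required for `solveBAVis`).
#' @param visual,emt,motion Noise models.
#' @param control Solver control list (see [solveBundle()]).
#' @return `list(state =, report =, homographies =)`.
#' @export
solveBAVisEMT <- function(corrs, Z, K, planeInit, poseInit = Z,
                          visual = visualNoiseModel(), emt = emtNoiseModel(),
                          motion = motionModel(), control = list()) {
  st <- problemState(poseInit, planeInit)
  out <- solveBundle(st, corrs, Z, K, visual, emt, motion, control = control)
  out$homographies <- composeMosaicHomographies(out$state$poses,
                                                out$state$plane, K)
  out
}

#' @rdname solveBAVisEMT
#' @export
solveBAVis <- function(corrs, poseInit, K, planeInit,
                       visual = visualNoiseModel(), control = list()) {
  free <- rep(TRUE, nrow(poseInit))
  free[1] <- FALSE
  st <- problemState(poseInit, planeInit, freeMask = free)
  out <- solveBundle(st, corrs, Z = NULL, K, visual, emt = NULL,
                     motion = NULL, control = control)
  out$homographies <- composeMosaicHomographies(out$state$poses,
                                                out$state$plane, K)
  out
}
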