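## Synthetic-scene simulator: ground-truth trajectories over a planar texture,
## Gaussian EMT measurements, noisy point correspondences and black-frame
## dropout. Every downstream stage is testable against these sequences.

#' Configuration of a simulated planar scene
#'
#' Bundles the geometry of a simulated acquisition: camera intrinsics, scene
#' plane, trajectory shape and frame size. Defaults emulate the synthetic
#' sequences used throughout the package's experiments: 368 x 378 px frames
#' cut from a large planar texture, a camera orbiting the scene in a circular
#' pattern of four laps at a 50 mm standoff.
#'
#' @param nFrames Number of frames (>= 2).
#' @param trajectory `"circular"` (constant-velocity screw: camera centers on
#'   a circle, orientation advancing with the lap phase) or `"handheld"`
#'   (constant-velocity base plus seeded AR(1) jitter in all 6 DOF).
#' @param laps Number of laps around the circle (circular trajectory).
#' @param radius Circle radius in mm.
#' @param standoff Distance from the reference camera to the plane (mm); the
#'   plane is `pi = c(0, 0, -1/standoff)` in the reference frame.
#' @param frameSize Integer `c(w, h)` in pixels.
#' @param focal Focal length in pixels (fx = fy).
#' @param handheldStep Body-frame pose increment per frame for the handheld
#'   base motion, 6-vector `c(r, t)` (radians, mm).
#' @param jitterRotDeg,jitterTransMm Innovation standard deviations of the
#'   AR(1) handheld jitter (degrees, mm); 0 gives an exactly constant-velocity
#'   trajectory.
#' @param jitterPhi AR(1) coefficient of the handheld jitter.
#' @param seed Integer seed for all randomness derived from this config.
#' @return A list with the above fields plus `intrinsics` (3x3 `K`) and
#'   `plane` (truth 3-vector), of class `"sceneConfig"`.
#' @export
sceneConfig <- function(nFrames = 150, trajectory = c("circular", "handheld"),
                        laps = 4, radius = 20, standoff = 50,
                        frameSize = c(368L, 378L), focal = 500,
                        handheldStep = c(0, 0, 0.002, 1.2, 0.4, 0.05),
                        jitterRotDeg = 0.05, jitterTransMm = 0.1,
                        jitterPhi = 0.8, seed = 1L) {
  trajectory <- match.arg(trajectory)
  if (nFrames < 2) stop("invalid-argument: nFrames must be >= 2")
  stopifnot(standoff > 0, radius >= 0, length(frameSize) == 2)
  frameSize <- as.integer(frameSize)
  K <- cameraIntrinsics(focal, focal,
                        (frameSize[1] - 1) / 2, (frameSize[2] - 1) / 2)
  structure(list(nFrames = as.integer(nFrames), trajectory = trajectory,
                 laps = laps, radius = radius, standoff = standoff,
                 frameSize = frameSize, focal = focal,
                 handheldStep = handheldStep, jitterRotDeg = jitterRotDeg,
                 jitterTransMm = jitterTransMm, jitterPhi = jitterPhi,
                 seed = as.integer(seed), intrinsics = K,
                 plane = c(0, 0, -1 / standoff)),
            class = "sceneConfig")
}

rotZ <- function(th) matrix(c(cos(th), sin(th), 0,
                              -sin(th), cos(th), 0,
                              0, 0, 1), 3, 3)

#' Generate a ground-truth camera trajectory
#'
#' The circular trajectory is a constant-velocity screw motion: the camera
#' center orbits a circle in a plane parallel to the scene while the
#' orientation advances with the lap phase, so the pose increment
#' `T_k T_{k-1}^-1` is constant and the constant-velocity motion prior is
#' satisfied exactly. The handheld trajectory applies a fixed body-frame step
#' per frame plus seeded AR(1) perturbations in all six components.
#'
#' @param config A [sceneConfig()].
#' @return N x 6 matrix of poses; pose 1 is the identity (the reference /
#'   mosaic camera coincides with frame 1).
#' @export
makeTrajectory <- function(config) {
  n <- config$nFrames
  if (n < 2) stop("invalid-argument: nFrames must be >= 2")
  poses <- matrix(0, n, 6)
  colnames(poses) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  if (config$trajectory == "circular") {
    dth <- 2 * pi * config$laps / n
    m <- c(-config$radius, 0, 0)            # circle center (reference frame)
    for (k in seq_len(n)) {
      th <- dth * (k - 1)
      Rc <- rotZ(th)                         # camera-to-reference rotation
      ck <- m - Rc %*% m                     # camera center on the circle
      Rk <- t(Rc)                            # reference-to-camera
      poses[k, ] <- c(logSO3(Rk), -Rk %*% ck)
    }
  } else {
    set.seed(config$seed)
    S <- poseMatrix(config$handheldStep)     # body-frame increment
    P <- diag(4)                             # camera-to-reference transform
    sr <- config$jitterRotDeg * pi / 180
    st <- config$jitterTransMm
    j <- numeric(6)
    for (k in seq_len(n)) {
      if (k > 1) P <- P %*% S
      if (sr > 0 || st > 0) {
        j <- config$jitterPhi * j + rnorm(6, 0, c(rep(sr, 3), rep(st, 3)))
        Pk <- P %*% poseMatrix(j)
      } else Pk <- P
      poses[k, ] <- matrixPose(solve(Pk))
    }
  }
  poses
}

#' Simulate EMT pose measurements
#'
#' Each measurement is the true pose plus independent zero-mean Gaussian
#' noise, per-axis standard deviation `nu * baseSigmaRotDeg` (converted to
#' radians) on the rotation-vector components and `nu * baseSigmaTransMm` on
#' the translation — the additive diagonal-Gaussian pose noise model, with the
#' default base levels of 1 degree and 1 mm.
#'
#' @param poses N x 6 matrix of true poses.
#' @param nu Noise multiplier (>= 0); 0 returns the poses unchanged.
#' @param baseSigmaRotDeg,baseSigmaTransMm Base standard deviations.
#' @param seed Integer seed.
#' @return N x 6 matrix of measurements `z_k`.
#' @export
simulateEMT <- function(poses, nu = 1, baseSigmaRotDeg = 1,
                        baseSigmaTransMm = 1, seed = 1L) {
  stopifnot(nu >= 0, baseSigmaRotDeg > 0, baseSigmaTransMm > 0)
  if (nu == 0) return(poses)
  sig <- nu * c(rep(baseSigmaRotDeg * pi / 180, 3), rep(baseSigmaTransMm, 3))
  n <- nrow(poses)
  set.seed(seed)
  eps <- matrix(rnorm(6 * n), n, 6) %*% diag(sig)
  poses + eps
}

#' Procedural planar texture
#'
#' A seeded grayscale texture with smooth multi-scale structure and darker
#' vessel-like curves, standing in for the large planar image a simulated
#' camera observes. Values are in `[0.05, 1]` so blanked (all-zero) frames are
#' distinguishable from real content.
#'
#' @param width,height Texture size in pixels.
#' @param seed Integer seed.
#' @param nVessels Number of vessel-like curves to draw.
#' @return `height` x `width` numeric matrix in `[0, 1]`.
#' @export
proceduralTexture <- function(width, height, seed = 1L, nVessels = 12) {
  set.seed(seed)
  up <- function(coarse, h, w) {
    # bilinear upsampling of a coarse random grid
    ch <- nrow(coarse); cw <- ncol(coarse)
    ys <- seq(1, ch, length.out = h)
    xs <- seq(1, cw, length.out = w)
    y0 <- pmin(floor(ys), ch - 1); x0 <- pmin(floor(xs), cw - 1)
    fy <- ys - y0; fx <- xs - x0
    a <- coarse[y0, x0, drop = FALSE]; b <- coarse[y0, x0 + 1, drop = FALSE]
    c_ <- coarse[y0 + 1, x0, drop = FALSE]; d <- coarse[y0 + 1, x0 + 1, drop = FALSE]
    wa <- outer(1 - fy, 1 - fx); wb <- outer(1 - fy, fx)
    wc <- outer(fy, 1 - fx); wd <- outer(fy, fx)
    a * wa + b * wb + c_ * wc + d * wd
  }
  img <- 0.55 +
    0.25 * up(matrix(rnorm(12 * 12), 12), height, width) * 0.5 +
    0.20 * up(matrix(rnorm(40 * 40), 40), height, width) * 0.5 +
    0.10 * up(matrix(rnorm(140 * 140), 140), height, width) * 0.5
  for (v in seq_len(nVessels)) {
    # quadratic Bezier curve with a soft dark profile
    p <- matrix(runif(6, 0, 1), 3, 2) %*% diag(c(width - 1, height - 1))
    t <- seq(0, 1, length.out = 4 * max(width, height) %/% 2)
    b <- outer((1 - t)^2, p[1, ]) + outer(2 * t * (1 - t), p[2, ]) +
      outer(t^2, p[3, ])
    r <- sample(2:4, 1)
    for (dx in -r:r) for (dy in -r:r) {
      w <- exp(-(dx^2 + dy^2) / (0.5 * r^2))
      xi <- round(b[, 1]) + dx; yi <- round(b[, 2]) + dy
      ok <- xi >= 0 & xi < width & yi >= 0 & yi < height
      idx <- cbind(yi[ok] + 1, xi[ok] + 1)
      img[idx] <- img[idx] - 0.35 * w
    }
  }
  pmin(pmax(img, 0.05), 1)
}

## Bilinear sampling of img (h x w matrix) at continuous 0-based (x, y).
## Out-of-support samples return NA.
bilinearSample <- function(img, x, y) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  # clamp the base cell so exact right/bottom edges stay valid
  x0 <- pmin(pmax(floor(x), 0), w - 2)
  y0 <- pmin(pmax(floor(y), 0), h - 2)
  fx <- pmin(pmax(x - x0, 0), 1)
  fy <- pmin(pmax(y - y0, 0), 1)
  v <- img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
  v[!ok] <- NA_real_
  v
}

## Mosaic-space bounding box (xmin, ymin, xmax, ymax) of a set of frames.
footprintBounds <- function(homographies, frameSize) {
  w <- frameSize[1]; h <- frameSize[2]
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  box <- c(Inf, Inf, -Inf, -Inf)
  for (H in homographies) {
    cc <- applyHomography(solve(H), corners)
    box <- c(pmin(box[1:2], apply(cc, 2, min)),
             pmax(box[3:4], apply(cc, 2, max)))
  }
  box
}

#' Render frames from a planar texture
#'
#' Frame k is the texture resampled through its mosaic-to-frame homography
#' (bilinear interpolation), i.e. the image region a camera at pose k
#' observes.
#'
#' @param texture A list `list(image =, origin =)` as produced inside
#'   [simulateScene()], or a plain matrix (origin `c(0, 0)`): `image` is an
#'   h x w matrix, `origin` the mosaic-space pixel coordinate of its `[1, 1]`
#'   element.
#' @param poses N x 6 pose matrix.
#' @param plane Plane 3-vector.
#' @param K 3x3 intrinsics.
#' @param frameSize Integer `c(w, h)`.
#' @return List of N frames (h x w matrices).
#' @export
renderFrames <- function(texture, poses, plane, K, frameSize) {
  if (is.matrix(texture)) texture <- list(image = texture, origin = c(0, 0))
  w <- frameSize[1]; h <- frameSize[2]
  grid <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), w))
  lapply(seq_len(nrow(poses)), function(k) {
    H <- planeHomography(poses[k, ], plane, K)
    mos <- applyHomography(solve(H), grid)
    v <- bilinearSample(texture$image,
                        mos[, 1] - texture$origin[1],
                        mos[, 2] - texture$origin[2])
    if (anyNA(v))
      stop(sprintf("out-of-bounds: footprint of frame %d exits the texture", k))
    matrix(v, h, w)
  })
}

## Deterministic per-pair sub-seed (kept well below 2^31).
pairSeed <- function(seed, m, l) {
  (as.integer(seed) %% 100000L) * 20011L + 977L * (m %% 30000L) + l %% 30000L
}

#' Synthesize noisy point correspondences from ground truth
#'
#' For each requested ordered pair (m, l), samples points uniformly in frame
#' m, maps them through the true pairwise homography into frame l (the noise
#' model's mean), discards and resamples points falling outside frame l, and
#' perturbs the partner with isotropic Gaussian pixel noise of standard
#' deviation `sigmaV`.
#'
#' @param poses N x 6 true poses.
#' @param plane True plane 3-vector.
#' @param K Intrinsics.
#' @param pairs Integer matrix with columns m, l (one row per requested pair).
#' @param frameSize Integer `c(w, h)`.
#' @param nPoints Correspondences per pair.
#' @param sigmaV Matching noise standard deviation in pixels (>= 0).
#' @param seed Integer seed; each pair derives its own sub-seed, so the
#'   synthesized set for a pair does not depend on which other pairs are
#'   requested.
#' @param blank Frame indices with no visual content; pairs touching them are
#'   omitted.
#' @return A [CorrespondenceCollection-class]. Pairs whose footprints do not
#'   overlap are omitted (recorded in the `"skipped"` attribute).
#' @export
synthesizeCorrespondences <- function(poses, plane, K, pairs, frameSize,
                                      nPoints = 40, sigmaV = 1, seed = 1L,
                                      blank = integer(0)) {
  stopifnot(sigmaV >= 0, nPoints >= 1)
  sets <- list()
  skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    m <- pairs[i, 1]; l <- pairs[i, 2]
    if (m %in% blank || l %in% blank) next
    s <- synthesizePairCorr(poses, plane, K, m, l, frameSize, nPoints,
                            sigmaV, pairSeed(seed, m, l))
    if (is.null(s)) skipped <- c(skipped, list(c(m, l))) else
      sets <- c(sets, list(s))
  }
  out <- correspondenceCollection(sets)
  attr(out, "skipped") <- skipped
  out
}

synthesizePairCorr <- function(poses, plane, K, m, l, frameSize, nPoints,
                               sigmaV, seed) {
  H <- pairwiseHomography(poses[l, ], poses[m, ], plane, K)
  w <- frameSize[1]; h <- frameSize[2]
  set.seed(seed)
  ptsA <- matrix(0, 0, 2); ptsB <- matrix(0, 0, 2)
  for (round in 1:60) {
    need <- nPoints - nrow(ptsA)
    if (need <= 0) break
    cand <- cbind(runif(2 * need + 8, 0, w - 1), runif(2 * need + 8, 0, h - 1))
    mapped <- applyHomography(H, cand)
    ok <- mapped[, 1] >= 0 & mapped[, 1] <= w - 1 &
      mapped[, 2] >= 0 & mapped[, 2] <= h - 1
    if (any(ok)) {
      take <- utils::head(which(ok), need)
      ptsA <- rbind(ptsA, cand[take, , drop = FALSE])
      ptsB <- rbind(ptsB, mapped[take, , drop = FALSE])
    }
  }
  if (nrow(ptsA) < max(4, nPoints %/% 4)) return(NULL)  # no usable overlap
  if (sigmaV > 0)
    ptsB <- ptsB + matrix(rnorm(2 * nrow(ptsB), 0, sigmaV), ncol = 2)
  correspondenceSet(m, l, ptsA, ptsB)
}

#' Blank out frames of a sequence
#'
#' Replaces the listed frames with all-zero images (if frames are rendered),
#' removes every correspondence set touching them, and keeps the EMT
#' measurements — emulating sudden loss of visual content while the tracker
#' keeps reporting.
#'
#' @param sequence A [SyntheticSequence-class].
#' @param indices Frame indices to blank (1-based).
#' @return The modified [SyntheticSequence-class].
#' @export
blankFrames <- function(sequence, indices) {
  indices <- as.integer(indices)
  n <- length(sequence)
  if (length(indices) && (min(indices) < 1 || max(indices) > n))
    stop("invalid-argument: blank index out of range")
  if (length(indices) == 0) return(sequence)
  if (length(sequence@frames))
    for (k in indices)
      sequence@frames[[k]] <- matrix(0, nrow(sequence@frames[[k]]),
                                     ncol(sequence@frames[[k]]))
  keep <- vapply(sequence@correspondences@sets,
                 function(s) !any(s@pair %in% indices), logical(1))
  sequence@correspondences <- correspondenceCollection(
    unname(sequence@correspondences@sets[keep]))
  sequence@blankIndices <- sort(unique(c(sequence@blankIndices, indices)))
  validObject(sequence)
  sequence
}

#' Simulate a full synthetic sequence
#'
#' Orchestrates the generator: ground-truth trajectory and plane, EMT
#' measurements at noise level `nu`, synthesized correspondences for the
#' requested pairs, and (optionally) frames rendered from a seeded procedural
#' texture.
#'
#' @param config A [sceneConfig()].
#' @param nu EMT noise multiplier.
#' @param sigmaV Correspondence noise (px).
#' @param nPoints Correspondences per matched pair.
#' @param pairs `"adjacent"` for the chain (k, k+1), or an explicit integer
#'   matrix with columns m, l.
#' @param render Logical; render frames from the texture (slower, only needed
#'   for image-based matching and mosaic rendering).
#' @param blank Frame indices to blank after generation.
#' @param baseSigmaRotDeg,baseSigmaTransMm Base EMT noise (deg, mm).
#' @return A [SyntheticSequence-class].
#' @export
simulateScene <- function(config, nu = 1, sigmaV = 1, nPoints = 40,
                          pairs = "adjacent", render = FALSE,
                          blank = integer(0), baseSigmaRotDeg = 1,
                          baseSigmaTransMm = 1) {
  set.seed(config$seed)
  poses <- makeTrajectory(config)
  n <- nrow(poses)
  K <- config$intrinsics
  plane <- config$plane
  Hs <- lapply(seq_len(n), function(k) planeHomography(poses[k, ], plane, K))
  gt <- new("GroundTruth", poses = poses, plane = plane, homographies = Hs)
  emt <- simulateEMT(poses, nu, baseSigmaRotDeg, baseSigmaTransMm,
                     seed = config$seed + 7919L)
  if (identical(pairs, "adjacent"))
    pairs <- cbind(seq_len(n - 1), 2:n)
  corrs <- synthesizeCorrespondences(poses, plane, K, pairs, config$frameSize,
                                     nPoints = nPoints, sigmaV = sigmaV,
                                     seed = config$seed + 104729L,
                                     blank = blank)
  frames <- list()
  if (render) {
    box <- footprintBounds(Hs, config$frameSize)
    margin <- 8
    origin <- floor(box[1:2]) - margin
    tw <- ceiling(box[3] - origin[1]) + margin + 2
    th <- ceiling(box[4] - origin[2]) + margin + 2
    tex <- list(image = proceduralTexture(tw, th,
                                          seed = config$seed + 15013L),
                origin = origin)
    frames <- renderFrames(tex, poses, plane, K, config$frameSize)
  }
  seq <- new("SyntheticSequence", frames = frames, emt = emt,
             correspondences = corrs, groundTruth = gt, intrinsics = K,
             frameSize = config$frameSize,
             blankIndices = integer(0))
  if (length(blank)) seq <- blankFrames(seq, blank)
  seq
}

#' On-demand correspondence provider for a simulated sequence
#'
#' Returns a function `f(m, l)` that synthesizes (deterministically, from a
#' per-pair sub-seed) the correspondence set for any requested ordered pair of
#' the sequence — the sequential estimator uses it to obtain matches for
#' non-adjacent window/anchor pairs without pre-computing all O(N^2) sets.
#' Pairs touching blanked frames, and pairs with no footprint overlap, yield
#' `NULL`.
#'
#' @param sequence A [SyntheticSequence-class].
#' @param nPoints Correspondences per pair.
#' @param sigmaV Matching noise (px).
#' @param seed Integer seed.
#' @return A function `(m, l) -> CorrespondenceSet or NULL`.
#' @export
syntheticCorrProvider <- function(sequence, nPoints = 40, sigmaV = 1,
                                  seed = 1L) {
  force(sequence); force(nPoints); force(sigmaV); force(seed)
  gt <- sequence@groundTruth
  function(m, l) {
    if (m %in% sequence@blankIndices || l %in% sequence@blankIndices)
      return(NULL)
    synthesizePairCorr(gt@poses, gt@plane, sequence@intrinsics, m, l,
                       sequence@frameSize, nPoints, sigmaV,
                       pairSeed(seed, m, l))
  }
}
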