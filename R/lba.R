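## Sequential estimation by local bundle adjustment: sliding-window partition
## of the cameras, K-means anchor selection over projected image footprints,
## per-iteration windowed solves and homography composition.

#' Configuration of the sequential (local bundle adjustment) estimator
#'
#' @param W Temporal window size (cameras inside the window).
#' @param chiE Cameras estimated per iteration (`1 <= chiE <= W`); the
#'   remaining `chiG = W - chiE` window cameras are fixed.
#' @param kClusters Number of K-means anchor clusters over the explored area
#'   (0 disables anchors).
#' @param subsetLen Consecutive cameras taken per anchor cluster.
#' @param planeInit Plane initialization for the cold start; default is
#'   fronto-parallel at a 30 mm working distance, refined by a plane-only
#'   bootstrap solve before the first window.
#' @param freezePlane Logical; once the plane estimate changes by less than
#'   `1e-6` (max absolute component) for 5 consecutive iterations, stop
#'   re-estimating it.
#' @param recomposeAtEnd Logical; additionally recompose all homographies
#'   from the final plane (the default keeps, for each frame, the homography
#'   composed in the iteration that fixed it).
#' @param planeDistRange Plausible plane-distance interval `c(min, max)` in
#'   mm (default 5-500, generous bounds on an endoscope's working distance).
#'   A window solve whose plane estimate leaves this range is deemed
#'   degenerate — short-baseline windows under heavy tracker noise can make
#'   the plane unobservable — and is re-solved with the plane held at its
#'   previous value.
#' @param seed Integer seed (anchor-run sampling).
#' @return A list of class `"lbaConfig"`.
#' @export
lbaConfig <- function(W = 5L, chiE = 3L, kClusters = 3L, subsetLen = 5L,
                      planeInit = c(0, 0, -1 / 30), freezePlane = FALSE,
                      recomposeAtEnd = FALSE, planeDistRange = c(5, 500),
                      seed = 1L) {
  stopifnot(W >= 1, chiE >= 1, chiE <= W, kClusters >= 0, subsetLen >= 1,
            length(planeDistRange) == 2, planeDistRange[1] > 0,
            planeDistRange[1] < planeDistRange[2])
  structure(list(W = as.integer(W), chiE = as.integer(chiE),
                 kClusters = as.integer(kClusters),
                 subsetLen = as.integer(subsetLen), planeInit = planeInit,
                 freezePlane = isTRUE(freezePlane),
                 recomposeAtEnd = isTRUE(recomposeAtEnd),
                 planeDistRange = planeDistRange,
                 seed = as.integer(seed)),
            class = "lbaConfig")
}

#' Mosaic-space centroid of a camera's image footprint
#'
#' Maps the four frame corners through the inverse of the camera's
#' plane-induced homography into mosaic space and returns their mean.
#'
#' @param x Pose 6-vector.
#' @param plane Plane 3-vector.
#' @param K Intrinsics.
#' @param frameSize Integer `c(w, h)`.
#' @return Mosaic-space 2-vector.
#' @export
projectFootprintCentroid <- function(x, plane, K, frameSize) {
  colMeans(footprintCorners(x, plane, K, frameSize))
}

footprintCorners <- function(x, plane, K, frameSize) {
  w <- frameSize[1]; h <- frameSize[2]
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  applyHomography(solve(planeHomography(x, plane, K)), corners)
}

planeDistOk <- function(plane, config) {
  d <- 1 / sqrt(sum(plane^2))
  is.finite(d) && d >= config$planeDistRange[1] &&
    d <= config$planeDistRange[2]
}

boxesOverlap <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

cornerBox <- function(cc) c(min(cc[, 1]), min(cc[, 2]),
                            max(cc[, 1]), max(cc[, 2]))

#' Select spatially distributed anchor cameras
#'
#' Clusters the mosaic-space footprint centroids of the already-fixed cameras
#' with (seeded) K-means and draws one random consecutive run of frames from
#' each cluster. The runs, with their stored correspondences, give the
#' windowed solver wide-baseline visual constraints on the plane.
#'
#' @param fixedIds Indices of the fixed cameras to draw from.
#' @param poses N x 6 matrix of current pose estimates.
#' @param plane Current plane estimate.
#' @param K Intrinsics.
#' @param frameSize Integer `c(w, h)`.
#' @param config An [lbaConfig()].
#' @return List with `centroids` (one row per fixed camera), `runs` (list of
#'   consecutive id vectors, at most `kClusters`), and `ids` (their union).
#' @export
selectAnchors <- function(fixedIds, poses, plane, K, frameSize, config) {
  stopifnot(length(fixedIds) >= 1)
  cent <- t(vapply(fixedIds, function(id)
    projectFootprintCentroid(poses[id, ], plane, K, frameSize), numeric(2)))
  if (length(fixedIds) <= config$kClusters) {
    return(list(centroids = cent, runs = list(fixedIds), ids = fixedIds))
  }
  k <- min(config$kClusters, nrow(unique(round(cent, 6))))
  set.seed(config$seed + 131L * (length(fixedIds) %% 9973L))
  cl <- if (k > 1) kmeans(cent, centers = k, nstart = 3)$cluster
        else rep(1L, nrow(cent))
  runs <- lapply(seq_len(k), function(ci) {
    ids <- sort(fixedIds[cl == ci])
    if (length(ids) == 0) return(integer(0))
    # maximal consecutive runs within the cluster
    brk <- c(0, which(diff(ids) > 1), length(ids))
    pieces <- lapply(seq_len(length(brk) - 1),
                     function(i) ids[(brk[i] + 1):brk[i + 1]])
    piece <- pieces[[sample.int(length(pieces), 1)]]
    len <- min(config$subsetLen, length(piece))
    start <- sample.int(length(piece) - len + 1, 1)
    piece[start:(start + len - 1)]
  })
  runs <- Filter(length, runs)
  list(centroids = cent, runs = runs, ids = sort(unique(unlist(runs))))
}

#' Enumerate the correspondence pairs used by a window solve
#'
#' All adjacent pairs inside the temporal window, plus — when geometry is
#' supplied — pairs linking each window frame to its nearest anchor frame in
#' every anchor run whose projected footprint overlaps it, and the adjacent
#' pairs inside each anchor run.
#'
#' @param windowIds Frame indices inside the window (sorted).
#' @param anchorRuns List of consecutive anchor id vectors (may be empty).
#' @param poses,plane,K,frameSize Current geometry used to predict footprint
#'   overlap; omit (`poses = NULL`) to skip overlap-based anchor pairs.
#' @param windowPolicy `"adjacent"` links consecutive window frames only;
#'   `"all"` links every frame pair inside the window, trading extra matching
#'   cost for longer intra-window baselines (which stabilize the plane depth;
#'   the sequencer uses this policy by default).
#' @return Integer matrix with columns `m`, `l` (`m < l`).
#' @export
enumerateWindowPairs <- function(windowIds, anchorRuns = list(), poses = NULL,
                                 plane = NULL, K = NULL, frameSize = NULL,
                                 windowPolicy = c("adjacent", "all")) {
  windowPolicy <- match.arg(windowPolicy)
  pairs <- if (length(windowIds) < 2) matrix(integer(0), 0, 2)
  else if (windowPolicy == "adjacent")
    cbind(windowIds[-length(windowIds)], windowIds[-1])
  else t(utils::combn(windowIds, 2))
  for (run in anchorRuns) {
    if (length(run) > 1)
      pairs <- rbind(pairs, cbind(run[-length(run)], run[-1]))
    if (!is.null(poses) && length(run) > 0) {
      runBoxes <- lapply(run, function(id)
        cornerBox(footprintCorners(poses[id, ], plane, K, frameSize)))
      runCent <- t(vapply(run, function(id)
        projectFootprintCentroid(poses[id, ], plane, K, frameSize),
        numeric(2)))
      for (e in windowIds) {
        eBox <- cornerBox(footprintCorners(poses[e, ], plane, K, frameSize))
        hit <- which(vapply(runBoxes, boxesOverlap, logical(1), b = eBox))
        hit <- setdiff(run[hit], windowIds)
        if (length(hit)) {
          ec <- colMeans(matrix(eBox, 2, 2, byrow = TRUE))
          d <- rowSums((runCent[match(hit, run), , drop = FALSE] -
                          matrix(ec, length(hit), 2, byrow = TRUE))^2)
          a <- hit[which.min(d)]
          pairs <- rbind(pairs, c(min(a, e), max(a, e)))
        }
      }
    }
  }
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  colnames(pairs) <- c("m", "l")
  pairs
}

#' Advance the sliding-window partition
#'
#' Moves the newly estimated cameras into the fixed-in-window set, spills the
#' oldest overflow into the outside set, and takes the next `chiE` incoming
#' frames as the new estimation set, preserving `W = chiE + chiG`.
#'
#' @param ws List with `estimateIds`, `fixedInWindowIds`, `outsideIds`.
#' @param config An [lbaConfig()].
#' @param nFrames Total frames available (incoming ids are clipped to it).
#' @return Updated list, or `NULL` when no frames remain.
#' @export
advanceWindow <- function(ws, config, nFrames) {
  processed <- sort(c(ws$outsideIds, ws$fixedInWindowIds, ws$estimateIds))
  last <- max(processed)
  if (last >= nFrames) return(NULL)
  est <- (last + 1):min(last + config$chiE, nFrames)
  chiG <- min(config$W - length(est), length(processed))
  fixedInWin <- if (chiG > 0) utils::tail(processed, chiG) else integer(0)
  list(estimateIds = est, fixedInWindowIds = fixedInWin,
       outsideIds = setdiff(processed, fixedInWin))
}

#' Compose mosaic homographies from poses and a plane
#'
#' `H_j = K (R_j - t_j pi') K^-1` for every frame.
#'
#' @param poses N x 6 pose matrix.
#' @param plane Plane 3-vector.
#' @param K Intrinsics.
#' @return List of canonicalized homographies.
#' @export
composeMosaicHomographies <- function(poses, plane, K) {
  lapply(seq_len(nrow(poses)), function(k)
    planeHomography(poses[k, ], plane, K))
}

#' Print a compact summary of a sequential estimation result
#'
#' @param x An `"lbaResult"` from [runSequential()].
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
print.lbaResult <- function(x, ...) {
  sph <- planeToSpherical(x$plane)
  cat(sprintf(
    "LBAVis+EMT result: %d poses over %d iterations (%d failed windows)\n",
    nrow(x$poses), nrow(x$planeTrace), length(x$failedWindows)))
  cat(sprintf("  plane: az %.1f deg, el %.1f deg, d %.2f mm\n",
              sph[1], sph[2], sph[3]))
  cat(sprintf("  compose-at-fix vs recompose-at-end divergence: %.3g\n",
              x$policyDivergence))
  invisible(x)
}

#' Run the sequential fused estimator (LBAVis+EMT)
#'
#' Iterates the sliding-window local bundle adjustment: gather the window and
#' anchor correspondences, solve the windowed fused problem over the `chiE`
#' new cameras and the plane (fixed cameras enter the residuals as constants,
#' including the two boundary motion-prior terms), compose the homographies
#' of the newly fixed frames with the iteration's plane, and advance. Frames
#' without visual data are still estimated from the EMT and motion-prior
#' terms, so the pipeline never breaks on blank frames; if a window solve
#' fails numerically, the window falls back to its EMT initialization and the
#' failure is recorded.
#'
#' @param Z N x 6 matrix of EMT pose measurements.
#' @param corrs A [CorrespondenceCollection-class] (typically all adjacent
#'   pairs).
#' @param K Intrinsics.
#' @param frameSize Integer `c(w, h)`.
#' @param config An [lbaConfig()].
#' @param visual,emt,motion Noise models.
#' @param corrProvider Optional function `(m, l) -> CorrespondenceSet or
#'   NULL` used to fetch pairs absent from `corrs` (e.g.
#'   [syntheticCorrProvider()], or an image matcher); fetched sets are cached
#'   and reused as anchor correspondences.
#' @return List of class `"lbaResult"`: `poses` (N x 6), `plane` (final),
#'   `planeTrace` (one row per iteration: iteration, azimuth, elevation,
#'   distance), `homographies` (per frame, composed at fix time),
#'   `reports` (per-iteration [SolveReport-class]s), `failedWindows`.
#' @export
runSequential <- function(Z, corrs, K, frameSize, config = lbaConfig(),
                          visual = visualNoiseModel(), emt = emtNoiseModel(),
                          motion = motionModel(), corrProvider = NULL) {
  n <- nrow(Z)
  stopifnot(n >= 2)
  W <- min(config$W, n)
  getCorr <- function(m, l) {
    s <- corrSet(corrs, m, l)
    if (is.null(s) && !is.null(corrProvider)) {
      s <- corrProvider(m, l)
      if (!is.null(s)) corrs <<- corrInsert(corrs, s)
    }
    s
  }
  gatherSets <- function(pairs) {
    sets <- list()
    for (i in seq_len(nrow(pairs))) {
      s <- getCorr(pairs[i, 1], pairs[i, 2])
      if (!is.null(s) && length(s) >= 4) sets <- c(sets, list(s))
    }
    sets
  }

  poses <- Z                       # EMT initialization everywhere
  plane <- config$planeInit
  homographies <- vector("list", n)
  reports <- list()
  planeTrace <- NULL
  failed <- integer(0)
  planeFrozen <- FALSE
  stillCount <- 0L

  recordPlane <- function(it) {
    sph <- planeToSpherical(plane)
    planeTrace <<- rbind(planeTrace,
                         c(iteration = it, sph[1], sph[2], sph[3]))
  }

  solveWindow <- function(estIds, windowIds, it) {
    fixedAll <- setdiff(seq_len(max(windowIds)), estIds)
    fixedOutside <- setdiff(fixedAll, windowIds)
    anchorRuns <- list()
    if (config$kClusters > 0 && length(fixedOutside) > 0) {
      anc <- selectAnchors(fixedOutside, poses, plane, K, frameSize, config)
      anchorRuns <- anc$runs
    }
    pairs <- enumerateWindowPairs(windowIds, anchorRuns, poses, plane, K,
                                  frameSize, windowPolicy = "all")
    sets <- gatherSets(pairs)
    freeMask <- rep(FALSE, n)
    freeMask[estIds] <- TRUE
    trySolve <- function(planeFree) tryCatch(
      solveBundle(problemState(poses, plane, freeMask,
                               planeFree = planeFree),
                  sets, Z, K, visual, emt, motion,
                  emtTargets = estIds,
                  priorTargets = estIds[estIds >= 3]),
      error = function(e) NULL)
    out <- trySolve(!planeFrozen)
    if (!is.null(out) && !planeDistOk(out$state$plane, config)) {
      # degenerate plane geometry in this window: keep the previous plane
      out <- trySolve(FALSE)
      if (!is.null(out)) out$state$plane <- plane
    }
    if (is.null(out)) {
      failed <<- c(failed, it)
      poses[estIds, ] <<- Z[estIds, , drop = FALSE]   # EMT-only fallback
    } else {
      prevPlane <- plane
      poses <<- out$state$poses
      plane <<- out$state$plane
      reports[[length(reports) + 1]] <<- out$report
      if (config$freezePlane && !planeFrozen) {
        stillCount <<- if (max(abs(plane - prevPlane)) < 1e-6)
          stillCount + 1L else 0L
        if (stillCount >= 5L) planeFrozen <<- TRUE
      }
    }
    for (k in estIds)
      homographies[[k]] <<- planeHomography(poses[k, ], plane, K)
    recordPlane(it)
  }

  ## Cold start: plane bootstrap (poses pinned at the EMT measurements), then
  ## one batch solve of the first W frames.
  coldIds <- seq_len(W)
  coldPairs <- enumerateWindowPairs(coldIds, windowPolicy = "all")
  coldSets <- gatherSets(coldPairs)
  if (length(coldSets) > 0) {
    bst <- problemState(poses, plane, freeMask = rep(FALSE, n),
                        planeFree = TRUE)
    boot <- tryCatch(
      solveBundle(bst, coldSets, Z, K, visual, emt, motion,
                  emtTargets = integer(0), priorTargets = integer(0)),
      error = function(e) NULL)
    if (!is.null(boot) && planeDistOk(boot$state$plane, config))
      plane <- boot$state$plane
  }
  solveWindow(coldIds, coldIds, 1L)

  ws <- list(estimateIds = coldIds, fixedInWindowIds = integer(0),
             outsideIds = integer(0))
  it <- 1L
  repeat {
    ws <- advanceWindow(ws, config, n)
    if (is.null(ws)) break
    it <- it + 1L
    solveWindow(ws$estimateIds,
                sort(c(ws$fixedInWindowIds, ws$estimateIds)), it)
  }
  ## Homographies of already-fixed frames keep the plane of the iteration
  ## that composed them; recomposing everything from the final plane is the
  ## alternative policy. The divergence between the two is always reported.
  recomposed <- composeMosaicHomographies(poses, plane, K)
  divergence <- max(vapply(seq_len(n), function(k)
    homographyDistance(homographies[[k]], recomposed[[k]]), numeric(1)))
  if (config$recomposeAtEnd) homographies <- recomposed
  colnames(planeTrace) <- c("iteration", "azimuth", "elevation", "distance")
  structure(list(poses = poses, plane = plane, planeTrace = planeTrace,
                 homographies = homographies, reports = reports,
                 failedWindows = failed, policyDivergence = divergence,
                 correspondences = corrs),
            class = "lbaResult")
}
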