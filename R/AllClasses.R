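## S4 containers for the package's central data objects.

#' Matched point sets between an image pair
#'
#' Holds the correspondences found from source frame `m` to target frame `l`:
#' `pointsA` are pixel locations in frame `m`, `pointsB` the matched locations
#' in frame `l`, row i of one matching row i of the other.
#'
#' @slot pair Integer 2-vector `c(m, l)` (1-based frame indices).
#' @slot pointsA,pointsB n x 2 matrices of 0-based pixel coordinates.
#' @export
setClass("CorrespondenceSet",
  representation(pair = "integer", pointsA = "matrix", pointsB = "matrix"),
  validity = function(object) {
    if (length(object@pair) != 2 || any(object@pair < 1))
      return("pair must be two positive frame indices")
    if (!is.numeric(object@pointsA) || !is.numeric(object@pointsB))
      return("points must be numeric matrices")
    if (ncol(object@pointsA) != 2 || ncol(object@pointsB) != 2)
      return("points must be n x 2 matrices")
    if (nrow(object@pointsA) != nrow(object@pointsB))
      return("pointsA and pointsB must have the same number of rows")
    if (nrow(object@pointsA) > 0 &&
        (!all(is.finite(object@pointsA)) || !all(is.finite(object@pointsB))))
      return("points must be finite")
    TRUE
  })

#' @describeIn CorrespondenceSet Constructor.
#' @param m,l Source and target frame indices.
#' @param pointsA,pointsB n x 2 matrices (pixels, frame m resp. l).
#' @export
correspondenceSet <- function(m, l, pointsA, pointsB) {
  new("CorrespondenceSet", pair = as.integer(c(m, l)),
      pointsA = as.matrix(pointsA), pointsB = as.matrix(pointsB))
}

#' @describeIn CorrespondenceSet Number of correspondences `N_{l,m}`.
#' @param x A `CorrespondenceSet`.
#' @export
setMethod("length", "CorrespondenceSet", function(x) nrow(x@pointsA))

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf("CorrespondenceSet %d -> %d with %d matches\n",
              object@pair[1], object@pair[2], length(object)))
})

pairKey <- function(m, l) paste0(m, "->", l)

#' Collection of correspondence sets keyed by ordered frame pair
#'
#' @slot sets Named list of [CorrespondenceSet-class] objects; names are
#'   `"m->l"` keys, at most one set per ordered pair.
#' @export
setClass("CorrespondenceCollection",
  representation(sets = "list"),
  validity = function(object) {
    if (length(object@sets) == 0) return(TRUE)
    if (!all(vapply(object@sets, is, logical(1), "CorrespondenceSet")))
      return("all elements must be CorrespondenceSet objects")
    keys <- vapply(object@sets, function(s) pairKey(s@pair[1], s@pair[2]),
                   character(1))
    if (anyDuplicated(keys)) return("duplicate ordered pair")
    if (!identical(unname(names(object@sets)), unname(keys)))
      return("list names must equal the 'm->l' pair keys")
    TRUE
  })

#' @describeIn CorrespondenceCollection Constructor from a list of sets.
#' @param sets List of [CorrespondenceSet-class] objects.
#' @export
correspondenceCollection <- function(sets = list()) {
  names(sets) <- vapply(sets, function(s) pairKey(s@pair[1], s@pair[2]),
                        character(1))
  new("CorrespondenceCollection", sets = sets)
}

#' @describeIn CorrespondenceCollection Number of stored pairs.
#' @param x A `CorrespondenceCollection`.
#' @export
setMethod("length", "CorrespondenceCollection", function(x) length(x@sets))

setMethod("show", "CorrespondenceCollection", function(object) {
  n <- vapply(object@sets, length, integer(1))
  cat(sprintf("CorrespondenceCollection: %d pairs, %d matches total\n",
              length(object@sets), sum(n)))
})

#' Look up / insert a correspondence set in a collection
#'
#' @param coll A [CorrespondenceCollection-class].
#' @param m,l Ordered pair of frame indices.
#' @return `corrSet`: the stored [CorrespondenceSet-class] or `NULL`;
#'   `corrPairs`: integer matrix with columns `m`, `l`.
#' @export
corrSet <- function(coll, m, l) coll@sets[[pairKey(m, l)]]

#' @rdname corrSet
#' @export
corrPairs <- function(coll) {
  if (length(coll@sets) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("m", "l"))))
  out <- t(vapply(coll@sets, function(s) s@pair, integer(2)))
  dimnames(out) <- list(NULL, c("m", "l"))
  out
}

#' @rdname corrSet
#' @param set A [CorrespondenceSet-class] to insert (replacing any set stored
#'   for the same ordered pair).
#' @export
corrInsert <- function(coll, set) {
  coll@sets[[pairKey(set@pair[1], set@pair[2])]] <- set
  coll
}

#' Ground truth of a simulated sequence
#'
#' @slot poses N x 6 matrix of true camera poses.
#' @slot plane True plane 3-vector `pi = n/d`.
#' @slot homographies List of the N true mosaic-to-frame homographies.
#' @export
setClass("GroundTruth",
  representation(poses = "matrix", plane = "numeric", homographies = "list"),
  validity = function(object) {
    if (ncol(object@poses) != 6) return("poses must be an N x 6 matrix")
    if (length(object@plane) != 3 || sum(object@plane^2) == 0)
      return("plane must be a nonzero 3-vector")
    if (length(object@homographies) != nrow(object@poses))
      return("one homography per pose required")
    TRUE
  })

setMethod("show", "GroundTruth", function(object) {
  sph <- planeToSpherical(object@plane)
  cat(sprintf(
    "GroundTruth: %d poses; plane az %.1f deg, el %.1f deg, d %.1f mm\n",
    nrow(object@poses), sph[1], sph[2], sph[3]))
})

#' A simulated mosaicking sequence
#'
#' The full bundle a sequential estimator consumes: rendered (or blanked)
#' frames, per-frame EMT pose measurements, pairwise correspondences, camera
#' intrinsics — plus the generating ground truth for evaluation.
#'
#' @slot frames List of frames (numeric h x w matrices in `[0, 1]`, possibly
#'   all-zero for blanked frames); may be empty when rendering was skipped.
#' @slot emt N x 6 matrix of EMT pose measurements `z_k`.
#' @slot correspondences A [CorrespondenceCollection-class].
#' @slot groundTruth A [GroundTruth-class].
#' @slot intrinsics 3x3 intrinsics matrix.
#' @slot frameSize Integer `c(w, h)` in pixels.
#' @slot blankIndices Integer vector of blanked frame indices.
#' @export
setClass("SyntheticSequence",
  representation(frames = "list", emt = "matrix",
                 correspondences = "CorrespondenceCollection",
                 groundTruth = "GroundTruth", intrinsics = "matrix",
                 frameSize = "integer", blankIndices = "integer"),
  validity = function(object) {
    n <- nrow(object@groundTruth@poses)
    if (nrow(object@emt) != n) return("one EMT measurement per frame required")
    if (length(object@frames) > 0 && length(object@frames) != n)
      return("frames, if rendered, must match the number of poses")
    if (length(object@frameSize) != 2 || any(object@frameSize < 1))
      return("frameSize must be positive c(w, h)")
    if (length(object@blankIndices) &&
        (min(object@blankIndices) < 1 || max(object@blankIndices) > n))
      return("blankIndices out of range")
    TRUE
  })

#' @describeIn SyntheticSequence Number of frames.
#' @param x A `SyntheticSequence`.
#' @export
setMethod("length", "SyntheticSequence", function(x) nrow(x@groundTruth@poses))

setMethod("show", "SyntheticSequence", function(object) {
  cat(sprintf(
    "SyntheticSequence: %d frames (%dx%d px), %d rendered, %d blanked\n",
    length(object), object@frameSize[1], object@frameSize[2],
    length(object@frames), length(object@blankIndices)))
  show(object@correspondences)
})

#' @describeIn SyntheticSequence EMT measurements (N x 6 matrix).
#' @param object A `SyntheticSequence`.
#' @export
emtMeasurements <- function(object) object@emt

#' @describeIn SyntheticSequence Ground-truth poses (N x 6 matrix).
#' @export
truePoses <- function(object) object@groundTruth@poses

#' @describeIn SyntheticSequence Ground-truth plane 3-vector.
#' @export
truePlane <- function(object) object@groundTruth@plane

#' Outcome of a nonlinear least-squares solve
#'
#' @slot converged Logical.
#' @slot iterations Number of optimizer iterations used.
#' @slot initialCost,finalCost Total cost before/after.
#' @slot costVisual,costEMT,costPrior Per-term final costs (`C_v`, `C_EMT`,
#'   `C_p`); `NA` for absent terms.
#' @slot message Solver status string.
#' @export
setClass("SolveReport",
  representation(converged = "logical", iterations = "integer",
                 initialCost = "numeric", finalCost = "numeric",
                 costVisual = "numeric", costEMT = "numeric",
                 costPrior = "numeric", message = "character"))

setMethod("show", "SolveReport", function(object) {
  cat(sprintf(
    "SolveReport: %s in %d iterations; cost %.6g -> %.6g (Cv %.4g, Cemt %.4g, Cp %.4g)\n",
    if (object@converged) "converged" else "not converged",
    object@iterations, object@initialCost, object@finalCost,
    object@costVisual, object@costEMT, object@costPrior))
})

#' Reprojection-grid error report for a set of frames
#'
#' @slot perFrame Per-frame errors `e_j` (pixels, >= 0).
#' @slot eM Mean error over frames (pixels).
#' @slot nGrid Grid resolution per side used in the metric.
#' @slot frameSize Integer `c(w, h)`.
#' @export
setClass("ErrorReport",
  representation(perFrame = "numeric", eM = "numeric", nGrid = "integer",
                 frameSize = "integer"),
  validity = function(object) {
    if (length(object@perFrame) == 0) return("perFrame must be non-empty")
    if (any(object@perFrame < 0)) return("errors must be nonnegative")
    if (abs(object@eM - mean(object@perFrame)) > 1e-9 * (1 + object@eM))
      return("eM must be the mean of perFrame")
    TRUE
  })

setMethod("show", "ErrorReport", function(object) {
  cat(sprintf("ErrorReport: %d frames, e_M = %.4g px (max e_j = %.4g px)\n",
              length(object@perFrame), object@eM, max(object@perFrame)))
})

#' @describeIn ErrorReport Per-frame errors `e_j`.
#' @param object An `ErrorReport`.
#' @export
frameErrors <- function(object) object@perFrame

#' @describeIn ErrorReport Aggregate mosaic error `e_M`.
#' @export
mosaicErrorValue <- function(object) object@eM
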