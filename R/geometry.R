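## Rotation / pose algebra, plane parametrization and plane-induced
## homographies: the deterministic geometric substrate of the package.

#' Build a camera intrinsics matrix
#'
#' @param fx,fy Focal lengths in pixels (must be > 0).
#' @param cx,cy Principal point in pixels (0-based image coordinates).
#' @return A 3x3 intrinsics matrix with zero skew.
#' @examples
#' K <- cameraIntrinsics(500, 500, 183.5, 188.5)
#' @export
cameraIntrinsics <- function(fx, fy, cx, cy) {
  stopifnot(is.finite(fx), is.finite(fy), is.finite(cx), is.finite(cy),
            fx > 0, fy > 0)
  matrix(c(fx, 0, 0,
           0, fy, 0,
           cx, cy, 1), 3, 3)
}

skewMatrix <- function(r) {
  matrix(c(0, r[3], -r[2],
           -r[3], 0, r[1],
           r[2], -r[1], 0), 3, 3)
}

#' Exponential map on SO(3)
#'
#' Converts a rotation vector (axis-angle, so(3)) to a rotation matrix using
#' the closed form of the matrix exponential, with a series expansion for
#' small angles.
#'
#' @param r Numeric rotation 3-vector (radians).
#' @return 3x3 rotation matrix.
#' @seealso [logSO3()]
#' @export
expSO3 <- function(r) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  th2 <- sum(r * r)
  S <- skewMatrix(r)
  if (th2 < 1e-16) {
    # second-order series: exact to machine precision in this regime
    return(diag(3) + S + 0.5 * (S %*% S))
  }
  th <- sqrt(th2)
  diag(3) + (sin(th) / th) * S + ((1 - cos(th)) / th2) * (S %*% S)
}

#' Logarithm map on SO(3)
#'
#' Inverse of [expSO3()]; returns the canonical rotation vector with
#' `norm <= pi`. Uses quaternion extraction (Shepperd's method) for numerical
#' robustness near the `pi` boundary.
#'
#' @param R 3x3 rotation matrix (orthogonality and unit determinant are
#'   checked to 1e-8).
#' @return Rotation 3-vector.
#' @export
logSO3 <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("logSO3: input is not a rotation matrix")
  # quaternion (w, x, y, z) via the most stable of the four Shepperd branches
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr >= max(diag(R))) {
    w <- sqrt(max(0, 1 + tr)) / 2
    q <- c(w,
           (R[3, 2] - R[2, 3]) / (4 * w),
           (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else {
    i <- which.max(diag(R))
    j <- (i %% 3) + 1
    k <- (j %% 3) + 1
    s <- sqrt(max(0, 1 + R[i, i] - R[j, j] - R[k, k])) * 2
    v <- numeric(3)
    v[i] <- s / 4
    v[j] <- (R[j, i] + R[i, j]) / s
    v[k] <- (R[k, i] + R[i, k]) / s
    q <- c((R[k, j] - R[j, k]) / s, v)
  }
  q <- q / sqrt(sum(q * q))
  if (q[1] < 0) q <- -q                       # canonical: angle in [0, pi]
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-12) return(c(0, 0, 0))
  th <- 2 * atan2(vn, q[1])
  (th / vn) * q[2:4]
}

#' Convert a pose 6-vector to a 4x4 rigid transform (and back)
#'
#' `poseMatrix` returns the homogeneous transform `T = [R t; 0 1]` mapping
#' reference coordinates to camera coordinates; `matrixPose` decomposes such a
#' transform back into the canonical 6-vector.
#'
#' @param x Pose 6-vector `c(r, t)`.
#' @param T 4x4 rigid transform.
#' @return `poseMatrix`: 4x4 matrix; `matrixPose`: pose 6-vector.
#' @export
poseMatrix <- function(x) {
  stopifnot(length(x) == 6, all(is.finite(x)))
  T <- diag(4)
  T[1:3, 1:3] <- expSO3(x[1:3])
  T[1:3, 4] <- x[4:6]
  T
}

#' @rdname poseMatrix
#' @export
matrixPose <- function(T) {
  stopifnot(is.matrix(T), all(dim(T) == c(4, 4)))
  c(logSO3(T[1:3, 1:3]), T[1:3, 4])
}

#' Compose and invert poses
#'
#' `poseCompose(a, b)` returns the pose of the transform `T_a T_b`
#' (apply `b`, then `a`); `poseInverse(a)` the pose of `T_a^-1`.
#'
#' @param a,b Pose 6-vectors.
#' @return Pose 6-vector.
#' @export
poseCompose <- function(a, b) {
  Ra <- expSO3(a[1:3]); Rb <- expSO3(b[1:3])
  R <- Ra %*% Rb
  c(logSO3(R), as.vector(Ra %*% b[4:6]) + a[4:6])
}

#' @rdname poseCompose
#' @export
poseInverse <- function(a) {
  R <- expSO3(a[1:3])
  c(logSO3(t(R)), as.vector(-t(R) %*% a[4:6]))
}

#' Canonicalize the scale of a homography
#'
#' Homographies are defined up to scale; the canonical representative has unit
#' Frobenius norm and a positive bottom-right entry (falling back to the
#' largest-magnitude entry when the bottom-right is numerically zero).
#'
#' @param H 3x3 matrix.
#' @return Canonicalized 3x3 matrix.
#' @export
canonicalizeHomography <- function(H) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)), all(is.finite(H)))
  f <- sqrt(sum(H * H))
  if (f == 0) stop("canonicalizeHomography: zero matrix")
  # already-canonical inputs are returned untouched (bit-exact idempotence)
  if (abs(f - 1) > 4 * .Machine$double.eps) H <- H / f
  s <- if (abs(H[3, 3]) > 1e-9) sign(H[3, 3]) else sign(H[which.max(abs(H))])
  if (s < 0) H <- -H
  if (abs(det(H)) <= 1e-12)
    stop("degenerate-geometry: homography is singular")
  H
}

#' Plane-induced homography of a camera pose
#'
#' The homography `H = K (R - t pi') K^-1` mapping mosaic (virtual-camera)
#' pixel coordinates to the pixel coordinates of the camera at pose `x`,
#' induced by the scene plane `pi = n / d`.
#'
#' @param x Pose 6-vector.
#' @param plane Plane 3-vector `pi = n / d` (1/mm), reference-frame
#'   convention `n' p + d = 0`.
#' @param K 3x3 intrinsics matrix.
#' @return Canonicalized 3x3 homography.
#' @export
planeHomography <- function(x, plane, K) {
  stopifnot(length(plane) == 3, sum(plane^2) > 0)
  Hn <- expSO3(x[1:3]) - x[4:6] %o% plane
  canonicalizeHomography(K %*% Hn %*% solve(K))
}

#' Pairwise plane-induced homography between two poses
#'
#' `H_{k,k-1} = H_k H_{k-1}^-1`, the map from image `k-1` pixels to image `k`
#' pixels induced by the common scene plane.
#'
#' @param xk,xkm1 Pose 6-vectors of the target (`k`) and source (`k-1`) frames.
#' @inheritParams planeHomography
#' @return Canonicalized 3x3 homography.
#' @export
pairwiseHomography <- function(xk, xkm1, plane, K) {
  Hk <- planeHomography(xk, plane, K)
  Hkm1 <- planeHomography(xkm1, plane, K)
  canonicalizeHomography(Hk %*% solve(Hkm1))
}

#' Apply a homography to 2-D points
#'
#' Propagates points through `H` in homogeneous coordinates and converts back
#' to Cartesian pixel coordinates.
#'
#' @param H 3x3 homography.
#' @param q Numeric 2-vector, or an n x 2 matrix of points (one per row).
#' @return Same shape as `q`.
#' @export
applyHomography <- function(H, q) {
  one <- FALSE
  if (is.null(dim(q))) { q <- matrix(q, 1, 2); one <- TRUE }
  P <- cbind(q, 1) %*% t(H)
  if (any(abs(P[, 3]) <= 1e-12))
    stop("infinite-point: homography maps a point to infinity")
  out <- P[, 1:2, drop = FALSE] / P[, 3]
  if (one) as.vector(out) else out
}

#' Compose a chain of pairwise homographies
#'
#' Left-multiplied product `H_{j,k} = H_{j,j-1} ... H_{k+1,k}` of consecutive
#' pairwise homographies, in the order the list supplies them
#' (`list(H_{k+1,k}, H_{k+2,k+1}, ...)`).
#'
#' @param pairwise Non-empty list of 3x3 homographies.
#' @return Canonicalized 3x3 homography.
#' @export
chainCompose <- function(pairwise) {
  if (!is.list(pairwise) || length(pairwise) == 0)
    stop("invalid-argument: empty homography chain")
  H <- diag(3)
  for (Hi in pairwise) H <- Hi %*% H
  canonicalizeHomography(H)
}

#' Convert a plane between scaled-normal and spherical parametrizations
#'
#' The spherical form (azimuth, elevation, distance) is the human-readable
#' view of the plane used when plotting plane traces: `distance = 1/|pi|`,
#' `azimuth = atan2(ny, nx)` and `elevation = asin(nz)` of the unit normal,
#' both in degrees.
#'
#' @param plane Plane 3-vector `pi = n/d`.
#' @param azimuth,elevation Angles in degrees.
#' @param distance Distance in mm (> 0).
#' @return `planeToSpherical`: named numeric vector
#'   `c(azimuth, elevation, distance)`; `sphericalToPlane`: plane 3-vector.
#' @export
planeToSpherical <- function(plane) {
  stopifnot(length(plane) == 3, sum(plane^2) > 0)
  nrm <- sqrt(sum(plane^2))
  n <- plane / nrm
  c(azimuth = atan2(n[2], n[1]) * 180 / pi,
    elevation = asin(max(-1, min(1, n[3]))) * 180 / pi,
    distance = 1 / nrm)
}

#' @rdname planeToSpherical
#' @export
sphericalToPlane <- function(azimuth, elevation, distance) {
  stopifnot(distance > 0)
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  c(cos(el) * cos(az), cos(el) * sin(az), sin(el)) / distance
}

## Relative matrix distance up to scale: 0 when A and B are equal projective
## maps. Used by tests and the sequencer's plane-freeze heuristic.
homographyDistance <- function(A, B) {
  a <- canonicalizeHomography(A)
  b <- canonicalizeHomography(B)
  min(max(abs(a - b)), max(abs(a + b)))
}
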