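## Feature-based pairwise matching: Harris corners, normalized patch
## descriptors, ratio-test matching and RANSAC homography filtering.
## Deliberately standard plumbing — the probabilistic model consumes the
## resulting correspondences and does not care how they were found; the
## synthetic correspondence generator is the fast path for experiments.

#' Parameters of the pairwise matcher
#'
#' @param maxCorners Maximum corners kept per image.
#' @param minDistance Minimum distance between kept corners (px).
#' @param patchRadius Descriptor patch radius (patch side `2r + 1`).
#' @param ratio Ratio-test threshold on descriptor distances.
#' @param ransacThresh RANSAC inlier threshold on the symmetric transfer
#'   error (px).
#' @param ransacIter Number of RANSAC iterations.
#' @param minInliers Minimum inlier count below which the pair is declared
#'   unmatched.
#' @param seed Integer seed for RANSAC sampling.
#' @return Parameter list.
#' @export
matchParams <- function(maxCorners = 400L, minDistance = 7, patchRadius = 6L,
                        ratio = 0.8, ransacThresh = 3, ransacIter = 500L,
                        minInliers = 8L, seed = 42L) {
  list(maxCorners = maxCorners, minDistance = minDistance,
       patchRadius = patchRadius, ratio = ratio,
       ransacThresh = ransacThresh, ransacIter = ransacIter,
       minInliers = minInliers, seed = seed)
}

boxBlur <- function(img, r) {
  # separable box filter via padded cumulative sums
  h <- nrow(img); w <- ncol(img)
  blur1 <- function(m, r) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    i1 <- pmax(1, seq_len(n) - r); i2 <- pmin(n, seq_len(n) + r)
    (cs[i2 + 1, , drop = FALSE] - cs[i1, , drop = FALSE]) / (i2 - i1 + 1)
  }
  t(blur1(t(blur1(img, r)), r))
}

harrisCorners <- function(img, params) {
  h <- nrow(img); w <- ncol(img)
  if (h < 8 || w < 8 || sd(img) < 1e-8) return(NULL)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  Sxx <- boxBlur(gx * gx, 2); Syy <- boxBlur(gy * gy, 2)
  Sxy <- boxBlur(gx * gy, 2)
  R <- (Sxx * Syy - Sxy^2) - 0.04 * (Sxx + Syy)^2
  b <- params$patchRadius + 2
  mask <- matrix(FALSE, h, w)
  mask[(b + 1):(h - b), (b + 1):(w - b)] <- TRUE
  # 8-neighbour non-maximum suppression
  isMax <- mask & R > 0
  sh <- function(m, dy, dx) {
    out <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy); xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (R >= sh(R, dy, dx))
  }
  idx <- which(isMax)
  if (length(idx) == 0) return(NULL)
  resp <- R[idx]
  ord <- order(resp, decreasing = TRUE)
  ys <- ((idx - 1) %% h) + 1; xs <- ((idx - 1) %/% h) + 1
  # greedy spacing on the response-sorted list
  keep <- integer(0)
  kx <- numeric(0); ky <- numeric(0)
  md2 <- params$minDistance^2
  for (i in ord) {
    if (length(keep) >= params$maxCorners) break
    if (length(kx) == 0 || min((kx - xs[i])^2 + (ky - ys[i])^2) >= md2) {
      keep <- c(keep, i); kx <- c(kx, xs[i]); ky <- c(ky, ys[i])
    }
  }
  cbind(x = xs[keep] - 1, y = ys[keep] - 1)     # 0-based pixel coordinates
}

patchDescriptors <- function(img, corners, r) {
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  D <- matrix(0, nrow(corners), nrow(offs))
  for (j in seq_len(nrow(offs)))
    D[, j] <- img[cbind(corners[, 2] + 1 + offs$dy[j],
                        corners[, 1] + 1 + offs$dx[j])]
  D <- D - rowMeans(D)
  nrm <- sqrt(rowSums(D * D))
  ok <- nrm > 1e-8
  D[ok, ] <- D[ok, ] / nrm[ok]
  list(D = D, ok = ok)
}

#' Detect and match features between two frames
#'
#' Harris corners with normalized patch-correlation descriptors, Lowe ratio
#' filtering and RANSAC homography verification. Returns `NULL` ("no match")
#' when fewer than `minInliers` matches survive — the sequential estimator's
#' signal that a frame pair carries no usable visual information (an all-black
#' frame never matches anything).
#'
#' @param imgA,imgB Grayscale frames (h x w matrices in `[0, 1]`).
#' @param params A [matchParams()] list.
#' @param m,l Frame indices recorded in the returned set.
#' @return A [CorrespondenceSet-class] of RANSAC inliers, or `NULL`.
#' @export
detectAndMatch <- function(imgA, imgB, params = matchParams(), m = 1L,
                           l = 2L) {
  if (!is.matrix(imgA) || !is.matrix(imgB))
    stop("I/O error: images must be numeric matrices")
  ca <- harrisCorners(imgA, params)
  cb <- harrisCorners(imgB, params)
  if (is.null(ca) || is.null(cb)) return(NULL)
  da <- patchDescriptors(imgA, ca, params$patchRadius)
  db <- patchDescriptors(imgB, cb, params$patchRadius)
  ca <- ca[da$ok, , drop = FALSE]; Da <- da$D[da$ok, , drop = FALSE]
  cb <- cb[db$ok, , drop = FALSE]; Db <- db$D[db$ok, , drop = FALSE]
  if (nrow(ca) < params$minInliers || nrow(cb) < params$minInliers)
    return(NULL)
  corr <- Da %*% t(Db)                       # correlation in [-1, 1]
  d2 <- pmax(2 - 2 * corr, 0)                # squared descriptor distance
  best <- apply(d2, 1, which.min)
  d1 <- d2[cbind(seq_len(nrow(d2)), best)]
  d2nd <- apply(d2, 1, function(v) sort(v, partial = 2)[2])
  pass <- sqrt(d1) < params$ratio * sqrt(pmax(d2nd, 1e-12))
  if (sum(pass) < params$minInliers) return(NULL)
  A <- ca[pass, , drop = FALSE]
  B <- cb[best[pass], , drop = FALSE]
  inl <- ransacHomographyInliers(A, B, params)
  if (length(inl) < params$minInliers) return(NULL)
  correspondenceSet(m, l, A[inl, , drop = FALSE], B[inl, , drop = FALSE])
}

ransacHomographyInliers <- function(A, B, params) {
  n <- nrow(A)
  if (n < 4) return(integer(0))
  set.seed(params$seed)
  bestInl <- integer(0)
  th2 <- params$ransacThresh^2
  for (i in seq_len(params$ransacIter)) {
    s <- sample.int(n, 4)
    H <- tryCatch(dltHomography(A[s, , drop = FALSE], B[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(H) || abs(det(H)) < 1e-12) next
    e2 <- symTransfer2(H, A, B)
    inl <- which(e2 < th2)
    if (length(inl) > length(bestInl)) bestInl <- inl
    if (length(bestInl) > 0.9 * n) break
  }
  if (length(bestInl) >= 4) {
    H <- tryCatch(dltHomography(A[bestInl, , drop = FALSE],
                                B[bestInl, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(H)) bestInl <- which(symTransfer2(H, A, B) < th2)
  }
  bestInl
}

symTransfer2 <- function(H, A, B) {
  fw <- cbind(A, 1) %*% t(H)
  bw <- cbind(B, 1) %*% t(solve(H))
  bad <- abs(fw[, 3]) < 1e-12 | abs(bw[, 3]) < 1e-12
  e <- rowSums((B - fw[, 1:2] / fw[, 3])^2) +
    rowSums((A - bw[, 1:2] / bw[, 3])^2)
  e[bad] <- Inf
  e
}

#' Correspondence provider backed by the image matcher
#'
#' Wraps [detectAndMatch()] over a list of rendered frames so the sequential
#' estimator can request matches for arbitrary pairs.
#'
#' @param frames List of grayscale frames.
#' @param params A [matchParams()] list.
#' @return A function `(m, l) -> CorrespondenceSet or NULL`.
#' @export
imageCorrProvider <- function(frames, params = matchParams()) {
  force(frames); force(params)
  function(m, l) detectAndMatch(frames[[m]], frames[[l]], params, m, l)
}
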