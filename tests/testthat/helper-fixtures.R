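# Shared fixture builders and independent oracles used across test files.

# Independent Rodrigues formula (closed form), the oracle for expSO3.
rodrigues <- function(r) {
  th <- sqrt(sum(r^2))
  S <- matrix(c(0, r[3], -r[2], -r[3], 0, r[1], r[2], -r[1], 0), 3, 3)
  if (th < 1e-12) return(diag(3) + S)
  diag(3) + sin(th) / th * S + (1 - cos(th)) / th^2 * (S %*% S)
}

# Random pose with rotation magnitude below rmax and translation scale tmax.
randomPose <- function(rmax = 0.5, tmax = 10) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  c(ax * runif(1, 0, rmax), runif(3, -tmax, tmax))
}

# Random plane with distance in [dmin, dmax], normal near -z (in front of
# the reference camera, pointing back toward it).
randomPlane <- function(dmin = 30, dmax = 80) {
  n <- c(rnorm(2, 0, 0.15), -1)
  n <- n / sqrt(sum(n^2))
  n / runif(1, dmin, dmax)
}

testIntrinsics <- function() cameraIntrinsics(400, 420, 120.5, 110.5)

# Project a mosaic pixel onto the plane and through the camera at pose x:
# the independent ray-plane oracle for plane-induced homographies.
rayPlaneProject <- function(q, x, plane, K) {
  pn <- solve(K) %*% c(q, 1)
  lam <- -1 / sum(plane * pn)        # plane: pi' p = -1
  p3 <- lam * pn
  pc <- rodrigues(x[1:3]) %*% p3 + x[4:6]
  qc <- K %*% pc
  as.vector(qc[1:2] / qc[3])
}

# A small noise-free simulated sequence reused by several files.
tinyScene <- function(nFrames = 10, seed = 5, nu = 0, sigmaV = 0,
                      nPoints = 30, laps = 0.5, ...) {
  simulateScene(sceneConfig(nFrames = nFrames, laps = laps, seed = seed, ...),
                nu = nu, sigmaV = sigmaV, nPoints = nPoints)
}

maxAbs <- function(x) max(abs(x))
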