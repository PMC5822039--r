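test_that("expSO3 matches the closed-form Rodrigues formula", {
  expect_equal(expSO3(c(0, 0, 0)), diag(3))
  expect_equal(as.vector(expSO3(c(0, 0, pi / 2)) %*% c(1, 0, 0)),
               c(0, 1, 0), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:100) {
    r <- randomPose(rmax = pi - 1e-3)[1:3]
    R <- expSO3(r)
    expect_lt(maxAbs(R - rodrigues(r)), 1e-12)
    expect_lt(maxAbs(crossprod(R) - diag(3)), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("logSO3 inverts expSO3, including near the pi boundary", {
  expect_equal(logSO3(diag(3)), c(0, 0, 0))
  expect_equal(logSO3(expSO3(c(0.1, -0.2, 0.3))), c(0.1, -0.2, 0.3),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    r <- randomPose(rmax = pi - 1e-6)[1:3]
    expect_lt(maxAbs(logSO3(expSO3(r)) - r), 1e-8)
  }
  # stress the near-pi branch explicitly
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    r <- ax * (pi - 1e-6)
    back <- logSO3(expSO3(r))
    expect_lt(min(maxAbs(back - r), maxAbs(back + r)), 1e-6)
    expect_lte(sqrt(sum(back^2)), pi + 1e-12)
  }
  expect_error(logSO3(matrix(1, 3, 3)), "not a rotation")
})

test_that("pose composition and inversion match 4x4 rigid-matrix algebra", {
  set.seed(3)
  x <- randomPose()
  expect_equal(poseCompose(x, c(0, 0, 0, 0, 0, 0)), x, tolerance = 1e-12)
  expect_equal(poseCompose(x, poseInverse(x)), rep(0, 6), tolerance = 1e-10)
  for (i in 1:25) {
    a <- randomPose(); b <- randomPose(); c3 <- randomPose()
    expect_lt(maxAbs(poseMatrix(poseCompose(a, b)) -
                       poseMatrix(a) %*% poseMatrix(b)), 1e-10)
    expect_lt(maxAbs(poseMatrix(poseInverse(a)) - solve(poseMatrix(a))),
              1e-10)
    lhs <- poseCompose(a, poseCompose(b, c3))
    rhs <- poseCompose(poseCompose(a, b), c3)
    expect_lt(maxAbs(poseMatrix(lhs) - poseMatrix(rhs)), 1e-10)
  }
})

test_that("plane-induced homography reproduces direct ray-plane projection", {
  K <- testIntrinsics()
  set.seed(4)
  for (i in 1:10) {
    x <- randomPose(rmax = 0.3, tmax = 8)
    plane <- randomPlane()
    H <- planeHomography(x, plane, K)
    for (j in 1:50) {
      q <- c(runif(1, 0, 240), runif(1, 0, 220))
      expect_lt(maxAbs(applyHomography(H, q) - rayPlaneProject(q, x, plane, K)),
                1e-8)
    }
  }
})

test_that("identity pose gives the identity homography; axial translation scales about the principal point", {
  K <- testIntrinsics()
  plane <- c(0, 0, -1 / 50)
  H <- planeHomography(rep(0, 6), plane, K)
  expect_lt(maxAbs(H - canonicalizeHomography(diag(3))), 1e-12)
  # pure optical-axis translation tau: x' - cx = (x - cx) / (1 + tau/d)
  tau <- 7
  Hz <- planeHomography(c(0, 0, 0, 0, 0, tau), plane, K)
  q <- c(200, 40)
  pp <- c(K[1, 3], K[2, 3])
  expect_equal(applyHomography(Hz, q), pp + (q - pp) / (1 + tau / 50),
               tolerance = 1e-10)
  expect_equal(applyHomography(Hz, pp), pp, tolerance = 1e-10)
})

test_that("plane homography agrees with a DLT fit on projected on-plane points", {
  K <- testIntrinsics()
  set.seed(5)
  x <- randomPose(rmax = 0.2, tmax = 6)
  plane <- randomPlane()
  q <- cbind(runif(12, 0, 240), runif(12, 0, 220))
  p <- t(apply(q, 1, rayPlaneProject, x = x, plane = plane, K = K))
  # independent DLT: homogeneous linear system solved by SVD in test code
  M <- do.call(rbind, lapply(seq_len(nrow(q)), function(i) {
    a <- q[i, ]; b <- p[i, ]
    rbind(c(-a[1], -a[2], -1, 0, 0, 0, b[1] * a[1], b[1] * a[2], b[1]),
          c(0, 0, 0, -a[1], -a[2], -1, b[2] * a[1], b[2] * a[2], b[2]))
  }))
  Hdlt <- canonicalizeHomography(matrix(svd(M)$v[, 9], 3, 3, byrow = TRUE))
  H <- planeHomography(x, plane, K)
  expect_lt(min(maxAbs(H - Hdlt), maxAbs(H + Hdlt)), 1e-8)
})

test_that("pairwise homography equals the relative pose with the plane re-expressed", {
  K <- testIntrinsics()
  set.seed(6)
  for (i in 1:10) {
    xm <- randomPose(rmax = 0.2, tmax = 5)
    xl <- randomPose(rmax = 0.2, tmax = 5)
    plane <- randomPlane()
    H12 <- pairwiseHomography(xl, xm, plane, K)
    # plane in frame m: n' = R_m n, d' = d - n'^T t_m
    nrm <- sqrt(sum(plane^2)); n <- plane / nrm; d <- 1 / nrm
    n2 <- as.vector(expSO3(xm[1:3]) %*% n)
    d2 <- d - sum(n2 * xm[4:6])
    rel <- poseCompose(xl, poseInverse(xm))
    Hrel <- planeHomography(rel, n2 / d2, K)
    expect_lt(min(maxAbs(H12 - Hrel), maxAbs(H12 + Hrel)), 1e-10)
  }
  x <- randomPose()
  expect_lt(maxAbs(pairwiseHomography(x, x, randomPlane(), K) -
                     canonicalizeHomography(diag(3))), 1e-10)
})

test_that("applyHomography matches scalar projective arithmetic and flags points at infinity", {
  expect_equal(applyHomography(diag(3), c(10, 20)), c(10, 20))
  Ht <- matrix(c(1, 0, 0, 0, 1, 0, 3, 4, 1), 3, 3)
  expect_equal(applyHomography(Ht, c(0, 0)), c(3, 4))
  set.seed(7)
  for (i in 1:20) {
    H <- matrix(rnorm(9), 3, 3); H[3, 3] <- 5
    q <- runif(2, -10, 10)
    den <- H[3, 1] * q[1] + H[3, 2] * q[2] + H[3, 3]
    manual <- c((H[1, 1] * q[1] + H[1, 2] * q[2] + H[1, 3]) / den,
                (H[2, 1] * q[1] + H[2, 2] * q[2] + H[2, 3]) / den)
    expect_equal(applyHomography(H, q), manual, tolerance = 1e-12)
  }
  Hinf <- diag(3); Hinf[3, ] <- c(1, 0, 0)
  expect_error(applyHomography(Hinf, c(0, 5)), "infinite-point")
})

test_that("chainCompose composes pairwise homographies into the direct ratio", {
  expect_lt(maxAbs(chainCompose(rep(list(diag(3)), 5)) -
                     canonicalizeHomography(diag(3))), 1e-12)
  t1 <- diag(3); t1[1:2, 3] <- c(3, 4)
  t2 <- diag(3); t2[1:2, 3] <- c(1, 1)
  comp <- chainCompose(list(t1, t2))
  expect_equal(applyHomography(comp, c(0, 0)), c(4, 5), tolerance = 1e-12)
  expect_error(chainCompose(list()), "invalid-argument")
  # chain over poses equals H_j H_k^-1
  K <- testIntrinsics()
  set.seed(8)
  plane <- randomPlane()
  poses <- t(replicate(5, randomPose(rmax = 0.15, tmax = 4)))
  pw <- lapply(1:4, function(k)
    pairwiseHomography(poses[k + 1, ], poses[k, ], plane, K))
  direct <- canonicalizeHomography(
    planeHomography(poses[5, ], plane, K) %*%
      solve(planeHomography(poses[1, ], plane, K)))
  chain <- chainCompose(pw)
  expect_lt(min(maxAbs(chain - direct), maxAbs(chain + direct)), 1e-10)
})

test_that("canonicalization is idempotent bit-for-bit and scale invariant", {
  set.seed(9)
  for (i in 1:20) {
    H <- matrix(rnorm(9), 3, 3)
    if (abs(det(H)) < 1e-6) next
    C1 <- canonicalizeHomography(H)
    expect_identical(canonicalizeHomography(C1), C1)
    expect_lt(maxAbs(canonicalizeHomography(-3.7 * H) - C1), 1e-12)
    expect_equal(sqrt(sum(C1^2)), 1, tolerance = 1e-12)
  }
})

test_that("spherical plane conversion round-trips and has the declared conventions", {
  s <- planeToSpherical(c(0, 0, 1 / 50))
  expect_equal(unname(s["elevation"]), 90)
  expect_equal(unname(s["distance"]), 50)
  set.seed(10)
  for (i in 1:100) {
    plane <- rnorm(3) / runif(1, 10, 100)
    s <- planeToSpherical(plane)
    back <- sphericalToPlane(s["azimuth"], s["elevation"], s["distance"])
    expect_lt(maxAbs(back - plane), 1e-10 * maxAbs(plane))
  }
  p <- c(0.3, -0.2, -0.9) / 40
  s1 <- planeToSpherical(p); s2 <- planeToSpherical(2 * p)
  expect_equal(unname(s2["distance"]), unname(s1["distance"]) / 2)
  expect_equal(unname(s2[c("azimuth", "elevation")]),
               unname(s1[c("azimuth", "elevation")]))
})
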