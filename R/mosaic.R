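## Mosaic rendering: canvas bounds, inverse warping, feathered linear
## blending with an optional thin circular border marking each stitched frame.

#' Compute the mosaic canvas bounds
#'
#' Axis-aligned bounding box (padded by `pad` pixels) of all frame corners
#' mapped into mosaic space by the inverse homographies. A configurable area
#' cap turns runaway bounds — the signature of accumulated drift producing
#' projections of unnatural size — into a diagnostic error instead of an
#' allocation failure.
#'
#' @param homographies List of mosaic-to-frame homographies.
#' @param frameSize Integer `c(w, h)`.
#' @param pad Padding in pixels.
#' @param areaCap Maximum canvas area in pixels.
#' @return Numeric `c(xmin, ymin, xmax, ymax)` (integral, mosaic pixels).
#' @export
computeCanvas <- function(homographies, frameSize, pad = 2, areaCap = 4e7) {
  if (length(homographies) < 1)
    stop("invalid-argument: need at least one homography")
  box <- footprintBounds(homographies, frameSize)
  b <- c(floor(box[1:2]) - pad, ceiling(box[3:4]) + pad)
  area <- (b[3] - b[1] + 1) * (b[4] - b[2] + 1)
  if (area > areaCap)
    stop(sprintf(
      "canvas-overflow: %.0f px exceeds the %.0f px cap (drift diagnostic)",
      area, areaCap))
  b
}

#' Warp and blend frames into a mosaic
#'
#' Inverse-warps each frame into mosaic space (bilinear sampling) and blends
#' linearly with feather weights proportional to the distance from the frame
#' edge, so seams fade smoothly. With `border = TRUE` a thin black ring at
#' each frame's circular field-of-view boundary is stamped to visualize where
#' frames were stitched.
#'
#' @param frames List of grayscale frames (h x w matrices).
#' @param homographies List of mosaic-to-frame homographies (same length).
#' @param frameSize Integer `c(w, h)`.
#' @param canvas Canvas bounds from [computeCanvas()] (computed if `NULL`).
#' @param border Logical; stamp the circular border ring.
#' @param borderRadius Ring radius in px (default `min(w, h) / 2`).
#' @return List: `image` (canvas matrix, unobserved pixels `NA`), `weight`
#'   (accumulated blend weights), `bounds`.
#' @export
warpBlend <- function(frames, homographies, frameSize, canvas = NULL,
                      border = FALSE, borderRadius = min(frameSize) / 2) {
  if (length(frames) != length(homographies))
    stop("invalid-argument: frames and homographies differ in length")
  if (is.null(canvas)) canvas <- computeCanvas(homographies, frameSize)
  W <- canvas[3] - canvas[1] + 1
  Hh <- canvas[4] - canvas[2] + 1
  acc <- matrix(0, Hh, W)
  wgt <- matrix(0, Hh, W)
  w <- frameSize[1]; h <- frameSize[2]
  cxy <- c((w - 1) / 2, (h - 1) / 2)
  for (k in seq_along(frames)) {
    img <- frames[[k]]
    Hk <- homographies[[k]]
    cc <- applyHomography(solve(Hk), rbind(c(0, 0), c(w - 1, 0), c(0, h - 1),
                                           c(w - 1, h - 1)))
    x0 <- max(canvas[1], floor(min(cc[, 1]))); x1 <- min(canvas[3], ceiling(max(cc[, 1])))
    y0 <- max(canvas[2], floor(min(cc[, 2]))); y1 <- min(canvas[4], ceiling(max(cc[, 2])))
    if (x1 < x0 || y1 < y0) next
    nx <- x1 - x0 + 1; ny <- y1 - y0 + 1
    grid <- cbind(rep(x0:x1, each = ny), rep(y0:y1, nx))
    q <- applyHomography(Hk, grid)                 # mosaic -> frame pixels
    v <- bilinearSample(img, q[, 1], q[, 2])
    fw <- pmin(pmin(q[, 1] + 1, w - q[, 1]), pmin(q[, 2] + 1, h - q[, 2]))
    fw[is.na(v) | fw < 0] <- 0
    if (border) {
      r <- sqrt((q[, 1] - cxy[1])^2 + (q[, 2] - cxy[2])^2)
      ring <- !is.na(v) & r >= borderRadius - 2 & r <= borderRadius
      v[ring] <- 0
      fw[ring] <- pmax(fw[ring], 1e3)              # ring overrides blending
      fw[!is.na(v) & r > borderRadius] <- 0        # circular field of view
    }
    v[is.na(v)] <- 0
    rows <- grid[, 2] - canvas[2] + 1
    cols <- grid[, 1] - canvas[1] + 1
    idx <- cbind(rows, cols)
    acc[idx] <- acc[idx] + fw * v
    wgt[idx] <- wgt[idx] + fw
  }
  out <- acc / wgt
  out[wgt == 0] <- NA_real_
  list(image = out, weight = wgt, bounds = canvas)
}

#' Write a mosaic to PNG with a JSON sidecar
#'
#' @param mosaic Result of [warpBlend()].
#' @param path Output PNG path; the sidecar is written next to it as
#'   `<path>.json` and records the canvas bounds (the mosaic-space transform:
#'   mosaic pixel = canvas pixel + `bounds[1:2]`).
#' @return `path`, invisibly.
#' @export
writeMosaicPNG <- function(mosaic, path) {
  img <- mosaic$image
  img[is.na(img)] <- 0
  png::writePNG(pmin(pmax(img, 0), 1), path)
  jsonlite::write_json(list(bounds = mosaic$bounds),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}
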