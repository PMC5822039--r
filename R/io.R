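## File formats: CSV for poses / homographies / correspondences / metrics,
## JSON for intrinsics and planes, PNG frames, YAML configs and manifests.
## All tables are indexed by integer frame number; alignment is by index,
## never by timestamp (acquisition-time synchronization is upstream).

#' Read and write pose tables
#'
#' CSV schema: `frame, rx, ry, rz, tx, ty, tz` (radians, mm), one row per
#' frame, sorted by `frame` on read.
#'
#' @param poses N x 6 pose matrix (rows are taken as frames `1..N`).
#' @param path File path.
#' @return `readPoses`: N x 6 matrix with frame numbers as row names.
#' @export
writePoses <- function(poses, path) {
  df <- data.frame(frame = seq_len(nrow(poses)), poses)
  colnames(df) <- c("frame", "rx", "ry", "rz", "tx", "ty", "tz")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoses
#' @export
readPoses <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "rx", "ry", "rz", "tx", "ty", "tz")
  if (!all(need %in% colnames(df)))
    stop("schema error: pose CSV must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$frame), ]
  m <- as.matrix(df[, need[-1]])
  rownames(m) <- df$frame
  m
}

#' Read and write homography tables
#'
#' CSV schema: `frame, h11..h33` (row-major 3x3 entries).
#'
#' @param homographies List of 3x3 matrices.
#' @param path File path.
#' @return `readHomographies`: list of 3x3 matrices.
#' @export
writeHomographies <- function(homographies, path) {
  rows <- t(vapply(homographies, function(H) as.vector(t(H)), numeric(9)))
  df <- data.frame(frame = seq_along(homographies), rows)
  colnames(df) <- c("frame", paste0("h", rep(1:3, each = 3), rep(1:3, 3)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHomographies
#' @export
readHomographies <- function(path) {
  df <- read.csv(path)
  df <- df[order(df$frame), ]
  lapply(seq_len(nrow(df)), function(i)
    matrix(as.numeric(df[i, -1]), 3, 3, byrow = TRUE))
}

#' Read and write correspondence tables
#'
#' CSV schema: `m, l, xA, yA, xB, yB`, one row per correspondence.
#'
#' @param coll A [CorrespondenceCollection-class].
#' @param path File path.
#' @return `readCorrespondences`: a [CorrespondenceCollection-class].
#' @export
writeCorrespondences <- function(coll, path) {
  rows <- lapply(coll@sets, function(s)
    data.frame(m = s@pair[1], l = s@pair[2], xA = s@pointsA[, 1],
               yA = s@pointsA[, 2], xB = s@pointsB[, 1], yB = s@pointsB[, 2]))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(m = integer(0), l = integer(0), xA = numeric(0),
               yA = numeric(0), xB = numeric(0), yB = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorrespondences
#' @export
readCorrespondences <- function(path) {
  df <- read.csv(path)
  if (nrow(df) == 0) return(correspondenceCollection())
  keys <- paste(df$m, df$l)
  sets <- lapply(split(df, factor(keys, levels = unique(keys))), function(d)
    correspondenceSet(d$m[1], d$l[1], cbind(d$xA, d$yA), cbind(d$xB, d$yB)))
  correspondenceCollection(unname(sets))
}

#' Read and write camera intrinsics
#'
#' JSON object `{fx, fy, cx, cy}` (pixels).
#'
#' @param K 3x3 intrinsics matrix.
#' @param path File path.
#' @return `readIntrinsics`: 3x3 intrinsics matrix.
#' @export
writeIntrinsics <- function(K, path) {
  jsonlite::write_json(list(fx = K[1, 1], fy = K[2, 2], cx = K[1, 3],
                            cy = K[2, 3]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeIntrinsics
#' @export
readIntrinsics <- function(path) {
  j <- jsonlite::read_json(path)
  for (f in c("fx", "fy", "cx", "cy"))
    if (is.null(j[[f]])) stop("schema error: intrinsics JSON missing ", f)
  cameraIntrinsics(j$fx, j$fy, j$cx, j$cy)
}

#' Read and write a plane estimate
#'
#' JSON object `{pi: [3], azimuth, elevation, distance}` — the scaled normal
#' plus its human-readable spherical form.
#'
#' @param plane Plane 3-vector.
#' @param path File path.
#' @return `readPlane`: plane 3-vector.
#' @export
writePlane <- function(plane, path) {
  sph <- planeToSpherical(plane)
  jsonlite::write_json(list(pi = plane, azimuth = sph[["azimuth"]],
                            elevation = sph[["elevation"]],
                            distance = sph[["distance"]]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePlane
#' @export
readPlane <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$pi) || length(j$pi) != 3)
    stop("schema error: plane JSON missing 'pi'")
  as.numeric(unlist(j$pi))
}

#' Write a simulated sequence to a directory
#'
#' Layout: `frames/frame_%04d.png` (when rendered), `emt.csv`,
#' `gt_poses.csv`, `gt_plane.json`, `correspondences.csv`,
#' `intrinsics.json`, `manifest.yaml`.
#'
#' @param sequence A [SyntheticSequence-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSequence <- function(sequence, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(sequence@frames)) {
    fdir <- file.path(dir, "frames")
    dir.create(fdir, showWarnings = FALSE)
    for (k in seq_along(sequence@frames))
      png::writePNG(pmin(pmax(sequence@frames[[k]], 0), 1),
                    file.path(fdir, sprintf("frame_%04d.png", k)))
  }
  writePoses(sequence@emt, file.path(dir, "emt.csv"))
  writePoses(truePoses(sequence), file.path(dir, "gt_poses.csv"))
  writePlane(truePlane(sequence), file.path(dir, "gt_plane.json"))
  writeCorrespondences(sequence@correspondences,
                       file.path(dir, "correspondences.csv"))
  writeIntrinsics(sequence@intrinsics, file.path(dir, "intrinsics.json"))
  yaml::write_yaml(list(nFrames = length(sequence),
                        frameSize = as.integer(sequence@frameSize),
                        blankIndices = as.integer(sequence@blankIndices)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a sequence directory
#'
#' Reads frames (sorted by index), EMT poses and intrinsics, checks that
#' frame and EMT indices align, and applies an optional precomputed rigid
#' hand-eye transform to the raw sensor poses (`T_cam = T_handeye T_sensor`).
#'
#' @param dir Directory with `emt.csv`, `intrinsics.json` and optionally
#'   `frames/` (PNG), `gt_poses.csv`, `gt_plane.json`,
#'   `correspondences.csv`.
#' @param handEye Optional 4x4 rigid transform applied to each sensor pose.
#' @return List: `frames`, `emt`, `intrinsics`, and when present
#'   `gtPoses`, `gtPlane`, `correspondences`, `manifest`.
#' @export
loadSequence <- function(dir, handEye = NULL) {
  emtPath <- file.path(dir, "emt.csv")
  if (!file.exists(emtPath)) stop("I/O error: missing ", emtPath)
  emt <- readPoses(emtPath)
  if (!is.null(handEye)) {
    stopifnot(is.matrix(handEye), all(dim(handEye) == c(4, 4)))
    emt <- t(apply(emt, 1, function(z)
      matrixPose(handEye %*% poseMatrix(z))))
  }
  out <- list(emt = emt,
              intrinsics = readIntrinsics(file.path(dir, "intrinsics.json")))
  fdir <- file.path(dir, "frames")
  if (dir.exists(fdir)) {
    files <- sort(list.files(fdir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    idx <- as.integer(sub("^frame_0*(\\d+)\\.png$", "\\1", basename(files)))
    expect <- as.integer(rownames(emt))
    if (!setequal(idx, expect))
      stop("alignment error: frame files ",
           paste(setdiff(expect, idx), collapse = ","),
           " missing for EMT rows (and/or extra frames ",
           paste(setdiff(idx, expect), collapse = ","), ")")
    frames <- lapply(files[order(idx)], function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1] * 0.299 +
          img[, , 2] * 0.587 + img[, , 3] * 0.114
      img
    })
    out$frames <- frames
  }
  gp <- file.path(dir, "gt_poses.csv")
  if (file.exists(gp)) out$gtPoses <- readPoses(gp)
  pl <- file.path(dir, "gt_plane.json")
  if (file.exists(pl)) out$gtPlane <- readPlane(pl)
  cc <- file.path(dir, "correspondences.csv")
  if (file.exists(cc)) out$correspondences <- readCorrespondences(cc)
  mf <- file.path(dir, "manifest.yaml")
  if (file.exists(mf)) out$manifest <- yaml::read_yaml(mf)
  out
}
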