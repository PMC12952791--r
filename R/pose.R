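# Pose sequences: 12 keypoints per frame with confidences, stored in a
# documented HDF5 dialect (group /poseest, datasets points and confidence).
#
# Coordinate convention used everywhere in the package: origin at the
# top-left of the image, x rightward, y downward, pixel units, frames indexed
# from 0 in all user-facing bout/frame arithmetic.

#' Canonical keypoint names
#'
#' Ordered names of the 12 tracked keypoints. The ordering is a package
#' convention (nose to tail tip), documented once and used everywhere.
#'
#' @return Character vector of length 12.
#' @export
keypoint_names <- function() {
  c("nose", "left_ear", "right_ear", "base_neck",
    "left_forepaw", "right_forepaw", "mid_spine",
    "left_hind_paw", "right_hind_paw", "base_tail", "mid_tail", "tip_tail")
}

N_KEYPOINTS <- 12L

#' Construct a pose sequence
#'
#' @param keypoints Numeric array `n_frames x 12 x 2` of (x, y) pixel
#'   coordinates (finite, non-negative).
#' @param confidence Numeric matrix `n_frames x 12` of per-keypoint
#'   confidences in `[0, 1]`.
#' @param fps Frames per second (default 30).
#' @param kp_names Ordered keypoint names; defaults to [keypoint_names()].
#'
#' @return An object of class `PoseSequence` with fields `keypoints`,
#'   `confidence`, `fps`, `n_frames`, `keypoint_names`.
#' @export
pose_sequence <- function(keypoints, confidence, fps = 30,
                          kp_names = keypoint_names()) {
  keypoints <- unname(keypoints)
  confidence <- unname(as.matrix(confidence))
  if (length(dim(keypoints)) != 3L)
    stop("keypoints must be an n_frames x 12 x 2 array")
  n <- dim(keypoints)[1L]
  if (n < 1L) stop("n_frames must be >= 1")
  if (dim(keypoints)[2L] != N_KEYPOINTS || dim(keypoints)[3L] != 2L)
    stop("keypoints must be an n_frames x 12 x 2 array")
  if (!all(dim(confidence) == c(n, N_KEYPOINTS)))
    stop("confidence must be an n_frames x 12 matrix matching keypoints")
  if (!all(is.finite(keypoints)) || any(keypoints < 0))
    stop("keypoint coordinates must be finite and non-negative")
  if (any(!is.finite(confidence)) || any(confidence < 0 | confidence > 1))
    stop("confidence values must lie in [0, 1]")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  if (length(kp_names) != N_KEYPOINTS) stop("keypoint_names must have length 12")
  structure(list(keypoints = keypoints, confidence = confidence,
                 fps = as.numeric(fps), n_frames = n,
                 keypoint_names = as.character(kp_names)),
            class = "PoseSequence")
}

#' @export
print.PoseSequence <- function(x, ...) {
  cat(sprintf("<PoseSequence> %d frames, %d keypoints, %.4g fps\n",
              x$n_frames, N_KEYPOINTS, x$fps))
  invisible(x)
}

#' Write a pose sequence to an HDF5 file
#'
#' Dialect: group `poseest` with datasets `points` (`n_frames x 12 x 2`,
#' pixels) and `confidence` (`n_frames x 12`), plus group attributes `fps`
#' and `keypoint_names`.
#'
#' @param seq A `PoseSequence`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_pose <- function(seq, path) {
  stopifnot(inherits(seq, "PoseSequence"))
  if (!dir.exists(dirname(path)))
    stop("cannot write pose file: directory does not exist: ", dirname(path))
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create HDF5 file at ", path)
  rhdf5::h5createGroup(path, "poseest")
  rhdf5::h5write(seq$keypoints, path, "poseest/points")
  rhdf5::h5write(seq$confidence, path, "poseest/confidence")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "poseest")
  rhdf5::h5writeAttribute(seq$fps, gid, "fps")
  rhdf5::h5writeAttribute(seq$keypoint_names, gid, "keypoint_names")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a pose sequence from an HDF5 file
#'
#' @param path Path to a file written in the dialect of [write_pose()].
#' @return A validated `PoseSequence`.
#' @export
read_pose <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  contents <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop("not a readable HDF5 file: ", path))
  have <- paste0(contents$group, "/", contents$name)
  for (ds in c("/poseest/points", "/poseest/confidence")) {
    if (!ds %in% have)
      stop("pose format error: missing dataset ", ds)
  }
  pts <- rhdf5::h5read(path, "poseest/points")
  conf <- rhdf5::h5read(path, "poseest/confidence")
  attrs <- rhdf5::h5readAttributes(path, "poseest")
  rhdf5::h5closeAll()
  if (length(dim(pts)) != 3L || dim(pts)[2L] != N_KEYPOINTS ||
      dim(pts)[3L] != 2L)
    stop("pose format error: dataset poseest/points must be n_frames x 12 x 2")
  conf <- as.matrix(conf)
  if (!all(dim(conf) == c(dim(pts)[1L], N_KEYPOINTS)))
    stop("pose format error: dataset poseest/confidence must be n_frames x 12")
  if (any(!is.finite(conf)) || any(conf < 0 | conf > 1))
    stop("pose format error: dataset poseest/confidence outside [0, 1]")
  fps <- if (!is.null(attrs$fps)) as.numeric(attrs$fps) else 30
  knm <- if (!is.null(attrs$keypoint_names)) as.character(attrs$keypoint_names)
         else keypoint_names()
  pose_sequence(pts, conf, fps = fps, kp_names = knm)
}

#' Pose quality report
#'
#' Report-only quality control: per-keypoint coverage (fraction of frames at
#' or above `min_confidence`), a per-frame validity flag (all keypoints
#' confident), and overall coverage.
#'
#' @param seq A `PoseSequence`.
#' @param min_confidence Confidence threshold in `[0, 1]` (default 0.3).
#' @return List with `keypoint_coverage` (named, length 12), `frame_valid`
#'   (logical, length `n_frames`), `coverage` (scalar fraction of all
#'   keypoint-frame entries above threshold).
#' @export
validate_pose <- function(seq, min_confidence = 0.3) {
  stopifnot(inherits(seq, "PoseSequence"))
  if (min_confidence < 0 || min_confidence > 1)
    stop("min_confidence must be in [0, 1]")
  ok <- seq$confidence >= min_confidence
  kp_cov <- colMeans(ok)
  names(kp_cov) <- seq$keypoint_names
  list(keypoint_coverage = kp_cov,
       frame_valid = rowSums(ok) == N_KEYPOINTS,
       coverage = mean(ok))
}

#' Interpolate low-confidence keypoints
#'
#' Keypoints with confidence below `min_confidence` are linearly interpolated
#' across gaps of at most `max_gap` frames (per keypoint and coordinate).
#' Frames containing longer gaps, or gaps touching the sequence ends, stay
#' invalid and are flagged so feature extraction can mask them.
#'
#' @param seq A `PoseSequence`.
#' @param min_confidence Confidence threshold (default 0.3).
#' @param max_gap Longest gap, in frames, that is interpolated (default 5).
#' @return A `PoseSequence` with an added logical attribute `valid_mask`
#'   (TRUE for frames usable in feature extraction).
#' @export
interpolate_pose <- function(seq, min_confidence = 0.3, max_gap = 5) {
  stopifnot(inherits(seq, "PoseSequence"))
  n <- seq$n_frames
  kp <- seq$keypoints
  valid <- rep(TRUE, n)
  for (k in seq_len(N_KEYPOINTS)) {
    good <- seq$confidence[, k] >= min_confidence
    if (all(good)) next
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[i]) next
      a <- starts[i]; b <- ends[i]
      if (a > 1L && b < n && r$lengths[i] <= max_gap) {
        for (d in 1:2) {
          v0 <- kp[a - 1L, k, d]; v1 <- kp[b + 1L, k, d]
          w <- seq_len(r$lengths[i]) / (r$lengths[i] + 1)
          kp[a:b, k, d] <- v0 + w * (v1 - v0)
        }
      } else {
        valid[a:b] <- FALSE
      }
    }
  }
  out <- pose_sequence(pmax(kp, 0), seq$confidence, fps = seq$fps,
                       kp_names = seq$keypoint_names)
  attr(out, "valid_mask") <- valid
  out
}
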