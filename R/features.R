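# Kinematic features from pose keypoints.
#
# Per-frame feature set (89 columns):
#   - 66 pairwise keypoint distances (pixels)
#   - 12 per-keypoint speeds (pixels/s; central differences, one-sided at the
#     sequence ends, scaled by fps)
#   - centroid speed (pixels/s)
#   - body-axis heading (radians; direction base_tail -> base_neck) and its
#     angular velocity (rad/s, angle differences wrapped to (-pi, pi])
#   - 8 internal joint angles (radians): nose/neck/spine, neck/spine/tail,
#     fore- and hind-limb angles, and two tail angles
# Velocities are reported per second (scaled by fps) so features are
# comparable across frame rates.

#' Construct a feature matrix
#'
#' @param values Numeric matrix, one row per frame.
#' @param feature_names Unique column names, length `ncol(values)`.
#' @param window_size Window half-width `w` used (0 for per-frame features).
#' @param fps Frames per second of the source sequence.
#' @param valid_mask Logical per-frame validity (default all TRUE).
#' @return Object of class `FeatureMatrix`.
#' @export
feature_matrix <- function(values, feature_names, window_size = 0, fps = 30,
                           valid_mask = NULL) {
  values <- as.matrix(values)
  if (length(feature_names) != ncol(values))
    stop("feature_names must match the number of columns")
  if (anyDuplicated(feature_names)) stop("feature_names must be unique")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, nrow(values))
  if (length(valid_mask) != nrow(values))
    stop("valid_mask must have one entry per frame")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = as.character(feature_names),
                 window_size = as.integer(window_size), fps = fps,
                 valid_mask = as.logical(valid_mask)),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix> %d frames x %d features (w = %d, fps = %.4g)\n",
              nrow(x$values), ncol(x$values), x$window_size, x$fps))
  invisible(x)
}

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# finite difference along rows: central inside, one-sided at the ends
fdiff <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 frames")
  d <- numeric(n)
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d
}

joint_angle <- function(a, b, c) {
  # interior angle at b formed by segments b->a and b->c, rows = frames
  v1 <- a - b
  v2 <- c - b
  dot <- rowSums(v1 * v2)
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  cosang <- dot / pmax(n1 * n2, .Machine$double.eps)
  acos(pmin(1, pmax(-1, cosang)))
}

#' Per-frame kinematic features
#'
#' @param seq A `PoseSequence`. Low-confidence keypoints are interpolated
#'   first via [interpolate_pose()]; frames inside long gaps are flagged
#'   invalid in the returned `valid_mask`.
#' @param min_confidence Confidence threshold for interpolation (default 0.3).
#' @param max_gap Longest interpolated gap in frames (default 5).
#' @return A `FeatureMatrix` with `window_size = 0`, one row per frame.
#' @export
frame_features <- function(seq, min_confidence = 0.3, max_gap = 5) {
  stopifnot(inherits(seq, "PoseSequence"))
  if (seq$n_frames < 2L)
    stop("frame_features needs at least 2 frames (velocities undefined)")
  seq <- interpolate_pose(seq, min_confidence, max_gap)
  valid <- attr(seq, "valid_mask")
  kp <- seq$keypoints
  fps <- seq$fps
  nm <- seq$keypoint_names
  n <- seq$n_frames

  cols <- list()
  # pairwise distances
  for (i in 1:(N_KEYPOINTS - 1L)) {
    for (j in (i + 1L):N_KEYPOINTS) {
      d <- sqrt((kp[, i, 1] - kp[, j, 1])^2 + (kp[, i, 2] - kp[, j, 2])^2)
      cols[[paste0("dist_", nm[i], "_", nm[j])]] <- d
    }
  }
  # per-keypoint speeds
  for (i in seq_len(N_KEYPOINTS)) {
    dx <- fdiff(kp[, i, 1]); dy <- fdiff(kp[, i, 2])
    cols[[paste0("speed_", nm[i])]] <- sqrt(dx^2 + dy^2) * fps
  }
  # centroid speed
  cx <- rowMeans(kp[, , 1])
  cy <- rowMeans(kp[, , 2])
  cols[["speed_centroid"]] <- sqrt(fdiff(cx)^2 + fdiff(cy)^2) * fps
  # body-axis heading (base_tail -> base_neck) and angular velocity
  i_neck <- match("base_neck", nm); i_tail <- match("base_tail", nm)
  if (is.na(i_neck)) i_neck <- 4L
  if (is.na(i_tail)) i_tail <- 10L
  heading <- atan2(kp[, i_neck, 2] - kp[, i_tail, 2],
                   kp[, i_neck, 1] - kp[, i_tail, 1])
  cols[["heading"]] <- heading
  dh <- numeric(n)
  dh[1L] <- wrap_angle(heading[2L] - heading[1L])
  dh[n] <- wrap_angle(heading[n] - heading[n - 1L])
  if (n > 2L)
    dh[2:(n - 1L)] <- wrap_angle(heading[3:n] - heading[1:(n - 2L)]) / 2
  cols[["angular_velocity"]] <- dh * fps
  # joint angles
  P <- function(i) kp[, i, , drop = TRUE]
  idx <- function(name, fallback) {
    i <- match(name, nm); if (is.na(i)) fallback else i
  }
  nose <- idx("nose", 1L); neck <- i_neck; spine <- idx("mid_spine", 7L)
  btail <- i_tail; mtail <- idx("mid_tail", 11L); ttail <- idx("tip_tail", 12L)
  lf <- idx("left_forepaw", 5L); rf <- idx("right_forepaw", 6L)
  lh <- idx("left_hind_paw", 8L); rh <- idx("right_hind_paw", 9L)
  angles <- list(
    angle_nose_neck_spine   = joint_angle(P(nose), P(neck), P(spine)),
    angle_neck_spine_tail   = joint_angle(P(neck), P(spine), P(btail)),
    angle_lforepaw          = joint_angle(P(lf), P(spine), P(neck)),
    angle_rforepaw          = joint_angle(P(rf), P(spine), P(neck)),
    angle_lhindpaw          = joint_angle(P(lh), P(btail), P(spine)),
    angle_rhindpaw          = joint_angle(P(rh), P(btail), P(spine)),
    angle_spine_btail_mtail = joint_angle(P(spine), P(btail), P(mtail)),
    angle_btail_mtail_ttail = joint_angle(P(btail), P(mtail), P(ttail)))
  cols <- c(cols, angles)

  values <- do.call(cbind, cols)
  feature_matrix(values, names(cols), window_size = 0L, fps = fps,
                 valid_mask = valid)
}

#' Windowed summary features
#'
#' For every base feature, appends its mean, standard deviation, minimum,
#' maximum, and median over frames `[t - w, t + w]`, clamped at the sequence
#' ends. Invalid frames are excluded from windows (the current frame is
#' always included). `w = 0` reproduces the base values (sd 0).
#'
#' @param base A `FeatureMatrix` of per-frame features.
#' @param w Window half-width in frames (`w >= 0`).
#' @return A `FeatureMatrix` with `ncol(base) * 6` columns and
#'   `window_size = w`.
#' @export
window_features <- function(base, w) {
  stopifnot(inherits(base, "FeatureMatrix"))
  if (length(w) != 1L || is.na(w) || w < 0) stop("window size w must be >= 0")
  w <- as.integer(w)
  stats <- .window_stats(base$values, w, base$valid_mask)
  p <- ncol(base$values)
  stat_names <- c("mean", "sd", "min", "max", "median")
  nms <- unlist(lapply(stat_names, function(s)
    paste0("w", w, "_", s, "_", base$feature_names)))
  values <- cbind(base$values, stats)
  feature_matrix(values, c(base$feature_names, nms), window_size = w,
                 fps = base$fps, valid_mask = base$valid_mask)
}

#' Export a feature matrix as CSV
#'
#' @param fm A `FeatureMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  df <- as.data.frame(fm$values)
  df$valid <- fm$valid_mask
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
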