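`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures and independent brute-force oracles. Oracles are written
# directly against definitions (frame sets, explicit loops) so they stay
# independent of the implementation paths they check.

random_pose <- function(n_frames, seed = 1, fps = 30) {
  set.seed(seed)
  kp <- array(runif(n_frames * 12 * 2, 0, 800), dim = c(n_frames, 12, 2))
  conf <- matrix(runif(n_frames * 12, 0.5, 1), n_frames, 12)
  pose_sequence(kp, conf, fps = fps)
}

random_track <- function(n, p_behavior = 0.3, p_unlabeled = 0) {
  lab <- rbinom(n, 1, p_behavior)
  if (p_unlabeled > 0) lab[runif(n) < p_unlabeled] <- NA
  lab
}

# oracle: bouts as maximal runs, via explicit frame scan
oracle_bouts <- function(labels) {
  x <- !is.na(labels) & labels == 1L
  starts <- integer(); ends <- integer()
  inb <- FALSE
  for (i in seq_along(x)) {
    if (x[i] && !inb) { starts <- c(starts, i - 1L); inb <- TRUE }
    if (!x[i] && inb) { ends <- c(ends, i - 2L); inb <- FALSE }
  }
  if (inb) ends <- c(ends, length(x) - 1L)
  data.frame(start = starts, end = ends)
}

# oracle: stitching == filling gaps shorter than the threshold on the frame
# track (morphological closing), then re-extracting bouts
oracle_stitch <- function(labels, gap_threshold) {
  x <- !is.na(labels) & labels == 1L
  r <- rle(x)
  ends <- cumsum(r$lengths)
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] && i > 1L && i < length(r$lengths) &&
        r$lengths[i] < gap_threshold) {
      x[(ends[i] - r$lengths[i] + 1L):ends[i]] <- TRUE
    }
  }
  oracle_bouts(as.integer(x))
}

# oracle: interval IoU via explicit frame sets
oracle_iou <- function(u, v) {
  fu <- u[1]:u[2]; fv <- v[1]:v[2]
  length(intersect(fu, fv)) / length(union(fu, fv))
}

# oracle: AUROC as the Mann-Whitney U normalization with tie correction
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# oracle: BH step-up rule written straight from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# small labeled synthetic video for classifier tests
turn_video <- function(seed, n_frames = 900, w = 15) {
  sim <- synth_pose(behavior_script(kinematic = "turn_left"),
                    n_frames = n_frames, seed = seed)
  fm <- frame_features(sim$pose)
  if (w > 0) fm <- window_features(fm, w)
  list(features = fm, labels = sim$truth)
}

# linearly separable two-video dataset with a given number of labeled frames
separable_dataset <- function(n_videos = 2, n_frames = 200, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_videos), function(i) {
    x1 <- runif(n_frames, -1, 1)
    x2 <- runif(n_frames, -1, 1)
    y <- as.integer(x1 > 0)
    fm <- feature_matrix(cbind(f1 = x1, f2 = x2), c("f1", "f2"), fps = 30)
    list(features = fm, labels = ethogram(y))
  })
}
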