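# Ethograms (per-frame ternary label tracks) and bouts (contiguous behavior
# intervals), plus the stitch-and-filter post-processing applied to
# classifier predictions.
#
# Labels are coded 1 = behavior, 0 = not_behavior, NA = unlabeled. Bouts use
# 0-based inclusive frame indices: a bout (start, end) covers
# end - start + 1 frames.

#' Construct an ethogram
#'
#' @param labels Vector codeable to {1, 0, NA}: numeric 0/1, logical, or
#'   character ("behavior"/"not_behavior"/"unlabeled").
#' @param probabilities Optional per-frame behavior probability in `[0, 1]`
#'   (NA allowed for frames with no prediction).
#' @param fps Frames per second (default 30).
#' @param behavior_name Name of the behavior (default "behavior").
#' @param source Annotator or classifier id (default "unknown").
#' @return Object of class `Ethogram`.
#' @export
ethogram <- function(labels, probabilities = NULL, fps = 30,
                     behavior_name = "behavior", source = "unknown") {
  if (is.character(labels)) {
    lab <- rep(NA_integer_, length(labels))
    lab[labels == "behavior"] <- 1L
    lab[labels == "not_behavior"] <- 0L
  } else {
    lab <- as.integer(labels)
  }
  if (length(lab) < 1L) stop("ethogram must cover at least one frame")
  if (!all(lab %in% c(0L, 1L, NA_integer_)))
    stop("labels must be 0, 1, or NA (unlabeled)")
  if (!is.null(probabilities)) {
    probabilities <- as.numeric(probabilities)
    if (length(probabilities) != length(lab))
      stop("probabilities must match the number of frames")
    pr <- probabilities[!is.na(probabilities)]
    if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  }
  structure(list(labels = lab, probabilities = probabilities,
                 fps = as.numeric(fps), behavior_name = behavior_name,
                 source = source),
            class = "Ethogram")
}

#' @export
print.Ethogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<Ethogram> '%s' (%s): %d frames, %d behavior, %d unlabeled\n",
              x$behavior_name, x$source, n, sum(x$labels == 1L, na.rm = TRUE),
              sum(is.na(x$labels))))
  invisible(x)
}

#' @export
length.Ethogram <- function(x) length(x$labels)

#' Construct a bout list
#'
#' @param start,end Integer vectors of 0-based inclusive frame indices.
#' @return A data.frame with columns `start`, `end` (class `bout_list`).
#' @export
bout_list <- function(start = integer(), end = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end must match")
  if (any(start < 0) || any(end < start))
    stop("bouts need 0 <= start <= end")
  structure(data.frame(start = start, end = end),
            class = c("bout_list", "data.frame"))
}

check_sorted_disjoint <- function(bouts) {
  if (nrow(bouts) > 1L) {
    if (any(diff(bouts$start) <= 0) ||
        any(bouts$start[-1L] <= bouts$end[-nrow(bouts)]))
      stop("bouts must be sorted and disjoint")
  }
  invisible(bouts)
}

#' Extract bouts from an ethogram
#'
#' Maximal runs of behavior frames. Unlabeled frames break runs exactly like
#' not_behavior frames.
#'
#' @param e An `Ethogram`.
#' @return A `bout_list` (sorted, disjoint, non-adjacent).
#' @export
bouts_from_frames <- function(e) {
  stopifnot(inherits(e, "Ethogram"))
  x <- !is.na(e$labels) & e$labels == 1L
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  bout_list(starts[keep] - 1L, ends[keep] - 1L)
}

#' Build an ethogram from a bout list
#'
#' Inverse of [bouts_from_frames()] for binary tracks.
#'
#' @param bouts A `bout_list` (sorted, disjoint, within `[0, n_frames - 1]`).
#' @param n_frames Total frame count.
#' @param ... Passed to [ethogram()] (fps, behavior_name, source).
#' @return An `Ethogram` with labels in {0, 1}.
#' @export
frames_from_bouts <- function(bouts, n_frames, ...) {
  check_sorted_disjoint(bouts)
  if (nrow(bouts) > 0L && max(bouts$end) > n_frames - 1L)
    stop("bouts exceed [0, n_frames - 1]")
  lab <- integer(n_frames)
  for (i in seq_len(nrow(bouts)))
    lab[(bouts$start[i] + 1L):(bouts$end[i] + 1L)] <- 1L
  ethogram(lab, ...)
}

#' Stitch nearby bouts
#'
#' Neighboring bouts whose inter-bout gap (`start_next - end_prev - 1`
#' non-behavior frames) is strictly less than `gap_threshold` are merged,
#' left to right and transitively, so chains of close bouts collapse into
#' one.
#'
#' @param bouts A sorted, disjoint `bout_list`.
#' @param gap_threshold Gap threshold in frames (`>= 0`); 0 leaves the input
#'   unchanged.
#' @return A `bout_list`.
#' @export
stitch_bouts <- function(bouts, gap_threshold) {
  check_sorted_disjoint(bouts)
  if (gap_threshold < 0) stop("gap_threshold must be >= 0")
  n <- nrow(bouts)
  if (n <= 1L) return(bouts)
  start <- bouts$start; end <- bouts$end
  out_s <- start[1L]; out_e <- end[1L]
  for (i in 2:n) {
    gap <- start[i] - out_e[length(out_e)] - 1L
    if (gap < gap_threshold) {
      out_e[length(out_e)] <- end[i]
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  bout_list(out_s, out_e)
}

#' Filter short bouts
#'
#' Retains bouts of length (`end - start + 1`) at least `min_length`.
#'
#' @param bouts A `bout_list`.
#' @param min_length Minimum bout length in frames (`>= 1`).
#' @return A `bout_list`.
#' @export
filter_bouts <- function(bouts, min_length) {
  if (min_length < 1) stop("min_length must be >= 1")
  keep <- (bouts$end - bouts$start + 1L) >= min_length
  bout_list(bouts$start[keep], bouts$end[keep])
}

#' Stitch-then-filter post-processing of a predicted ethogram
#'
#' Applies [stitch_bouts()] then [filter_bouts()] to the bouts of a binary
#' prediction track, in that order, and returns the post-processed ethogram.
#'
#' @param e An `Ethogram` (unlabeled frames are treated as not_behavior).
#' @param stitch Gap threshold for stitching (default 0 = off).
#' @param filter Minimum bout length (default 1 = off).
#' @return An `Ethogram`.
#' @export
postprocess_ethogram <- function(e, stitch = 0, filter = 1) {
  b <- bouts_from_frames(e)
  b <- filter_bouts(stitch_bouts(b, stitch), filter)
  frames_from_bouts(b, length(e$labels), fps = e$fps,
                    behavior_name = e$behavior_name, source = e$source)
}

#' Read/write ethograms as CSV
#'
#' CSV layout: columns `frame` (0-based), `label` (0/1/empty for unlabeled),
#' and optionally `probability`.
#'
#' @param e An `Ethogram`.
#' @param path File path.
#' @return `path` (write) or an `Ethogram` (read).
#' @export
write_ethogram_csv <- function(e, path) {
  stopifnot(inherits(e, "Ethogram"))
  df <- data.frame(frame = seq_along(e$labels) - 1L, label = e$labels)
  if (!is.null(e$probabilities)) df$probability <- e$probabilities
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ethogram_csv
#' @param ... Passed to [ethogram()].
#' @export
read_ethogram_csv <- function(path, ...) {
  df <- read.csv(path)
  if (!all(c("frame", "label") %in% names(df)))
    stop("ethogram CSV needs columns frame and label")
  df <- df[order(df$frame), ]
  ethogram(df$label,
           probabilities = if ("probability" %in% names(df)) df$probability,
           ...)
}
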