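# Frame-level comparison statistics between two label tracks, and
# threshold-free score metrics (ROC/AUROC, TPR at a fixed FPR budget).
#
# Frames unlabeled (NA) in either track are excluded from every frame-wise
# statistic: classifier tracks are fully labeled, but ground-truth tracks
# may be sparse.

labels_of <- function(x) {
  if (inherits(x, "Ethogram")) x$labels else as.integer(x)
}

compared_frames <- function(a, b) {
  la <- labels_of(a); lb <- labels_of(b)
  if (length(la) != length(lb))
    stop("tracks differ in length (", length(la), " vs ", length(lb), ")")
  ok <- !is.na(la) & !is.na(lb)
  if (!any(ok)) stop("no mutually labeled frames to compare")
  list(a = la[ok], b = lb[ok])
}

#' Frame-wise confusion metrics
#'
#' Counts and rates over frames labeled in both tracks, with `reference` as
#' truth. F1 is defined as 0 when precision + recall is 0.
#'
#' @param reference,predicted `Ethogram`s (or 0/1/NA vectors) of equal
#'   length.
#' @return List of class `FrameComparison`: TP, TN, FP, FN, accuracy,
#'   precision, recall, F1, kappa, n_compared.
#' @export
frame_metrics <- function(reference, predicted) {
  cf <- compared_frames(reference, predicted)
  tp <- sum(cf$a == 1L & cf$b == 1L)
  tn <- sum(cf$a == 0L & cf$b == 0L)
  fp <- sum(cf$a == 0L & cf$b == 1L)
  fn <- sum(cf$a == 1L & cf$b == 0L)
  n <- tp + tn + fp + fn
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = (tp + tn) / n, precision = prec, recall = rec,
                 F1 = f1, kappa = cohen_kappa(reference, predicted),
                 n_compared = n),
            class = "FrameComparison")
}

#' @export
print.FrameComparison <- function(x, ...) {
  cat(sprintf(paste0("<FrameComparison> n=%d TP=%d TN=%d FP=%d FN=%d\n",
                     "  accuracy=%.4f precision=%.4f recall=%.4f F1=%.4f ",
                     "kappa=%.4f\n"),
              x$n_compared, x$TP, x$TN, x$FP, x$FN, x$accuracy, x$precision,
              x$recall, x$F1, x$kappa))
  invisible(x)
}

#' Cohen's kappa between two label tracks
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement and `p_e` the agreement expected from the marginal
#' label frequencies. The degenerate case `p_e = 1` (both tracks constant)
#' returns 1 when `p_o = 1` and 0 otherwise.
#'
#' @param a,b `Ethogram`s (or 0/1/NA vectors) of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(a, b) {
  cf <- compared_frames(a, b)
  n <- length(cf$a)
  po <- mean(cf$a == cf$b)
  pa1 <- mean(cf$a == 1L); pb1 <- mean(cf$b == 1L)
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1 - .Machine$double.eps^0.5) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve, AUROC, and TPR at an FPR budget
#'
#' The ROC curve is traced over the unique score values as thresholds
#' (predict behavior when score >= threshold); tied scores cross the
#' threshold simultaneously. AUROC is the trapezoidal integral of TPR over
#' FPR; `tpr_at_target` is the maximum TPR over curve points with
#' FPR <= `fpr_target`.
#'
#' @param scores Per-frame behavior scores/probabilities (finite).
#' @param labels An `Ethogram` or 0/1 vector; NA frames are dropped with
#'   their scores.
#' @param fpr_target Maximum allowed FPR (default 0.05).
#' @return List with `auroc`, `tpr_at_target`, `fpr_target`, and `curve`
#'   (data.frame fpr/tpr/threshold).
#' @export
roc_metrics <- function(scores, labels, fpr_target = 0.05) {
  y <- labels_of(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  ok <- !is.na(y) & !is.na(scores)
  y <- y[ok]; s <- scores[ok]
  if (!all(is.finite(s))) stop("scores must be finite")
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0L || nn == 0L)
    stop("roc_metrics needs both classes present")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  # counts at each distinct threshold (descending)
  last <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  thr <- c(Inf, s[last])
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  ok_fpr <- fpr <= fpr_target
  tpr_at <- if (any(ok_fpr)) max(tpr[ok_fpr]) else 0
  list(auroc = auroc, tpr_at_target = tpr_at, fpr_target = fpr_target,
       curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr))
}

#' Venn overlap of behavior frames
#'
#' Counts frames labeled behavior by exactly one track or both, and the
#' corresponding fractions of the union.
#'
#' @param a,b `Ethogram`s (or 0/1/NA vectors) of equal length.
#' @return List with counts `only_a`, `only_b`, `both` and fractions
#'   `frac_only_a`, `frac_only_b`, `frac_both` (all 0 for an empty union).
#' @export
venn_fractions <- function(a, b) {
  la <- labels_of(a); lb <- labels_of(b)
  if (length(la) != length(lb)) stop("tracks differ in length")
  ia <- !is.na(la) & la == 1L
  ib <- !is.na(lb) & lb == 1L
  both <- sum(ia & ib)
  only_a <- sum(ia & !ib)
  only_b <- sum(!ia & ib)
  u <- both + only_a + only_b
  frac <- function(x) if (u > 0) x / u else 0
  list(only_a = only_a, only_b = only_b, both = both,
       frac_only_a = frac(only_a), frac_only_b = frac(only_b),
       frac_both = frac(both))
}

#' Percentage of frames labeled behavior
#'
#' @param e An `Ethogram`; unlabeled frames count toward the total.
#' @return Percentage in `[0, 100]`.
#' @export
behavior_density <- function(e) {
  lab <- labels_of(e)
  100 * sum(lab == 1L, na.rm = TRUE) / length(lab)
}
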