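# The ethograph: a bipartite graph over the bouts of two annotators (or
# classifiers), with edges weighted by interval intersection-over-union.
# Bout-level agreement is the fraction of bouts whose best overlap exceeds a
# threshold w*, averaged over the two sides so the statistic is symmetric.

#' Interval IoU between two bouts
#'
#' `|frames(u) & frames(v)| / |frames(u) | frames(v)|`; symmetric, in
#' `[0, 1]`.
#'
#' @param u,v Bouts given as `c(start, end)` (0-based inclusive) or one-row
#'   `bout_list`s.
#' @return Overlap fraction.
#' @export
bout_overlap <- function(u, v) {
  u <- as.numeric(unlist(u[c(1, 2)])); v <- as.numeric(unlist(v[c(1, 2)]))
  inter <- min(u[2], v[2]) - max(u[1], v[1]) + 1
  if (inter <= 0) return(0)
  union <- (u[2] - u[1] + 1) + (v[2] - v[1] + 1) - inter
  inter / union
}

#' Build the ethograph of two bout lists
#'
#' One edge per overlapping bout pair, weighted by interval IoU. Bouts with
#' no overlapping partner are flagged "missed" (best overlap 0).
#'
#' @param bouts_a,bouts_b Sorted, disjoint `bout_list`s (sides U and V).
#' @return Object of class `Ethograph`: `U`, `V` (bout data.frames),
#'   `edges` (data.frame `u`, `v`, `weight` with 1-based bout indices),
#'   `missed_u`, `missed_v` (indices of zero-degree bouts).
#' @export
build_ethograph <- function(bouts_a, bouts_b) {
  check_sorted_disjoint(bouts_a)
  check_sorted_disjoint(bouts_b)
  nu <- nrow(bouts_a); nv <- nrow(bouts_b)
  eu <- integer(); ev <- integer(); ew <- numeric()
  j0 <- 1L
  for (i in seq_len(nu)) {
    for (j in seq_len(nv)) {
      if (bouts_b$end[j] < bouts_a$start[i]) next
      if (bouts_b$start[j] > bouts_a$end[i]) break
      w <- bout_overlap(c(bouts_a$start[i], bouts_a$end[i]),
                        c(bouts_b$start[j], bouts_b$end[j]))
      if (w > 0) {
        eu <- c(eu, i); ev <- c(ev, j); ew <- c(ew, w)
      }
    }
  }
  structure(list(U = as.data.frame(bouts_a), V = as.data.frame(bouts_b),
                 edges = data.frame(u = eu, v = ev, weight = ew),
                 missed_u = setdiff(seq_len(nu), eu),
                 missed_v = setdiff(seq_len(nv), ev)),
            class = "Ethograph")
}

#' @export
print.Ethograph <- function(x, ...) {
  cat(sprintf("<Ethograph> |U| = %d, |V| = %d, %d edges, missed: %d U / %d V\n",
              nrow(x$U), nrow(x$V), nrow(x$edges),
              length(x$missed_u), length(x$missed_v)))
  invisible(x)
}

best_overlaps <- function(g) {
  bu <- numeric(nrow(g$U)); bv <- numeric(nrow(g$V))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      e <- g$edges[r, ]
      bu[e$u] <- max(bu[e$u], e$weight)
      bv[e$v] <- max(bv[e$v], e$weight)
    }
  }
  list(u = bu, v = bv)
}

#' Bout-level agreement
#'
#' Each bout's best overlap is the maximum weight over its incident edges
#' (0 if missed). The agreement is the mean of the two per-side fractions of
#' bouts with best overlap strictly greater than `w_star`. Conventions: two
#' empty bout lists agree perfectly (1); an empty side is vacuously in full
#' agreement, so empty-vs-nonempty scores 0.5.
#'
#' @param g An `Ethograph`.
#' @param w_star Overlap threshold, `0 <= w_star < 1` (default 0.5).
#' @return Agreement fraction in `[0, 1]`.
#' @export
bout_agreement <- function(g, w_star = 0.5) {
  stopifnot(inherits(g, "Ethograph"))
  if (w_star < 0 || w_star >= 1) stop("w_star must lie in [0, 1)")
  nu <- nrow(g$U); nv <- nrow(g$V)
  if (nu == 0L && nv == 0L) return(1)
  b <- best_overlaps(g)
  fu <- if (nu > 0L) mean(b$u > w_star) else 1
  fv <- if (nv > 0L) mean(b$v > w_star) else 1
  (fu + fv) / 2
}

#' Stitch/filter hyperparameter scan
#'
#' For every (stitch, filter, w_star) triple, both prediction tracks are
#' post-processed (stitch then filter), the ethograph rebuilt, and the bout
#' agreement recorded.
#'
#' @param pred_a,pred_b `Ethogram`s (predictions of the two annotators'
#'   classifiers).
#' @param stitch_grid,filter_grid Integer grids of gap thresholds and
#'   minimum bout lengths.
#' @param w_star_list Overlap thresholds (default `c(0.25, 0.5, 0.75)`).
#' @return data.frame (stitch, filter, w_star, agreement) with attribute
#'   `best` = the row of maximal agreement (first by grid order on ties).
#' @export
scan_stitch_filter <- function(pred_a, pred_b, stitch_grid, filter_grid,
                               w_star_list = c(0.25, 0.5, 0.75)) {
  if (!length(stitch_grid) || !length(filter_grid) || !length(w_star_list))
    stop("scan grids must be non-empty")
  ba0 <- bouts_from_frames(pred_a)
  bb0 <- bouts_from_frames(pred_b)
  rows <- vector("list", length(stitch_grid) * length(filter_grid) *
                   length(w_star_list))
  r <- 0L
  for (s in stitch_grid) {
    bas <- stitch_bouts(ba0, s); bbs <- stitch_bouts(bb0, s)
    for (f in filter_grid) {
      g <- build_ethograph(filter_bouts(bas, f), filter_bouts(bbs, f))
      for (ws in w_star_list) {
        r <- r + 1L
        rows[[r]] <- data.frame(stitch = s, filter = f, w_star = ws,
                                agreement = bout_agreement(g, ws))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "best") <- out[which.max(out$agreement), ]
  out
}
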