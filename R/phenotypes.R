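# Aggregate phenotypes and strain-level statistics.
#
# Each behavior yields nine aggregate phenotypes: three metrics (total
# duration in minutes, number of bouts, average bout length in seconds)
# crossed with three time bins (the first 5, 20, and 55 minutes of a
# recording). Bin-boundary convention (stated once, tested): a bout belongs
# to a bin when its onset falls inside the bin; duration truncates behavior
# frames at the bin boundary; avgLen uses the full (untruncated) lengths of
# the bouts counted in the bin.

#' Aggregate phenotypes of one ethogram
#'
#' @param e An `Ethogram` (unlabeled frames count as not_behavior).
#' @param fps Frames per second (default: the ethogram's fps).
#' @param bins_minutes Time bins in minutes (default `c(5, 20, 55)`).
#' @return Named numeric vector `duration_T<bin>`, `nBouts_T<bin>`,
#'   `avgLen_T<bin>` for each bin; duration in minutes, avgLen in seconds
#'   (0 when a bin holds no bouts). An attribute `partial` flags bins longer
#'   than the recording.
#' @export
aggregate_phenotypes <- function(e, fps = NULL, bins_minutes = c(5, 20, 55)) {
  stopifnot(inherits(e, "Ethogram"))
  fps <- fps %||% e$fps
  if (fps <= 0) stop("fps must be positive")
  n <- length(e$labels)
  beh <- !is.na(e$labels) & e$labels == 1L
  bouts <- bouts_from_frames(e)
  lens <- bouts$end - bouts$start + 1L
  out <- numeric(0)
  partial <- logical(0)
  for (bin in bins_minutes) {
    cutoff <- bin * 60 * fps            # frames [0, cutoff) are in the bin
    dur_min <- sum(beh[seq_len(min(n, cutoff))]) / fps / 60
    in_bin <- bouts$start < cutoff
    nb <- sum(in_bin)
    avg_s <- if (nb > 0) mean(lens[in_bin]) / fps else 0
    v <- c(dur_min, nb, avg_s)
    names(v) <- paste0(c("duration", "nBouts", "avgLen"), "_T", bin)
    out <- c(out, v)
    partial <- c(partial, n < cutoff)
  }
  attr(out, "partial") <- stats::setNames(rep(partial, each = 3), names(out))
  out
}

#' Assemble a phenotype table
#'
#' @param animal,strain,sex Vectors of animal ids, strain names, and sexes
#'   ("M"/"F"), one entry per animal.
#' @param values Numeric matrix or data.frame of phenotype values, one row
#'   per animal; column names follow `<behavior>_<metric>_T<bin>`.
#' @return data.frame of class `PhenotypeTable` with columns `animal`,
#'   `strain`, `sex`, then the phenotypes.
#' @export
phenotype_table <- function(animal, strain, sex, values) {
  values <- as.data.frame(values)
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (any(!nzchar(strain))) stop("strain names must be non-empty")
  n <- length(animal)
  if (length(strain) != n || length(sex) != n || nrow(values) != n)
    stop("animal, strain, sex, and values must align")
  if (anyDuplicated(names(values))) stop("phenotype names must be unique")
  out <- cbind(data.frame(animal = animal, strain = strain, sex = sex,
                          stringsAsFactors = FALSE), values)
  class(out) <- c("PhenotypeTable", "data.frame")
  out
}

pheno_cols <- function(t) setdiff(names(t), c("animal", "strain", "sex"))

#' Strain-level z-score matrix
#'
#' Animal values are averaged within strain per phenotype, then each
#' phenotype column is z-scored across strains: `z = (x - mu) / sigma` with
#' the sample (n-1) standard deviation. Columns with zero spread yield z = 0
#' and are flagged degenerate.
#'
#' @param t A `PhenotypeTable` with at least 2 strains.
#' @param threshold Masking threshold on `|z|` (default 1).
#' @return List: `z` (strain x phenotype matrix), `mask` (`|z| > threshold`),
#'   `strain_means`, `degenerate` (logical per phenotype).
#' @export
zscore_table <- function(t, threshold = 1) {
  stopifnot(inherits(t, "PhenotypeTable"))
  ph <- pheno_cols(t)
  strains <- sort(unique(t$strain))
  if (length(strains) < 2L) stop("z-scoring requires at least 2 strains")
  sm <- matrix(NA_real_, length(strains), length(ph),
               dimnames = list(strains, ph))
  for (i in seq_along(strains)) {
    rows <- t$strain == strains[i]
    sm[i, ] <- vapply(ph, function(p) mean(t[[p]][rows], na.rm = TRUE), 0)
  }
  mu <- colMeans(sm, na.rm = TRUE)
  sigma <- apply(sm, 2, sd, na.rm = TRUE)
  degenerate <- !is.finite(sigma) | sigma == 0
  z <- sweep(sm, 2, mu, "-")
  z <- sweep(z, 2, ifelse(degenerate, 1, sigma), "/")
  z[, degenerate] <- 0
  list(z = z, mask = abs(z) > threshold, strain_means = sm,
       degenerate = stats::setNames(degenerate, ph))
}

rank_biserial <- function(x_m, x_f) {
  # rank-biserial correlation from the Mann-Whitney U of M vs F;
  # positive when males rank higher
  r <- rank(c(x_m, x_f))
  u_m <- sum(r[seq_along(x_m)]) - length(x_m) * (length(x_m) + 1) / 2
  2 * u_m / (length(x_m) * length(x_f)) - 1
}

#' Per-strain sex-effect tests
#'
#' Wilcoxon rank-sum test of male vs female animals for every (strain,
#' phenotype) cell with at least `min_per_sex` animals per sex, with
#' Benjamini-Hochberg FDR correction across all tested cells. The score is
#' `-log10(p)` and the effect size is the signed rank-biserial correlation
#' (positive = males higher).
#'
#' @param t A `PhenotypeTable`.
#' @param min_per_sex Minimum animals per sex per cell (default 2).
#' @return data.frame (strain, phenotype, n_m, n_f, p, q, score, effect);
#'   skipped cells are absent, with reasons in attribute `skipped`.
#' @export
sex_effect <- function(t, min_per_sex = 2L) {
  stopifnot(inherits(t, "PhenotypeTable"))
  ph <- pheno_cols(t)
  strains <- sort(unique(t$strain))
  rows <- list(); skipped <- list()
  for (s in strains) {
    sel <- t$strain == s
    for (p in ph) {
      xm <- t[[p]][sel & t$sex == "M"]; xm <- xm[!is.na(xm)]
      xf <- t[[p]][sel & t$sex == "F"]; xf <- xf[!is.na(xf)]
      if (length(xm) < min_per_sex || length(xf) < min_per_sex) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          strain = s, phenotype = p,
          reason = sprintf("needs >= %d animals per sex (got %d M, %d F)",
                           min_per_sex, length(xm), length(xf)))
        next
      }
      pv <- suppressWarnings(wilcox.test(xm, xf, exact = FALSE)$p.value)
      if (is.na(pv)) pv <- 1   # zero-variance ties
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, phenotype = p, n_m = length(xm), n_f = length(xf),
        p = pv, effect = rank_biserial(xm, xf))
    }
  }
  if (!length(rows)) stop("no (strain, phenotype) cell had enough animals")
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$score <- -log10(out$p)
  out <- out[, c("strain", "phenotype", "n_m", "n_f", "p", "q", "score",
                 "effect")]
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  out
}

#' Dataset imbalance metrics
#'
#' Strain imbalance `SI = max_i |share_i - 1/n|` where `share_i` is strain
#' i's fraction of all animals; per-strain sex imbalance
#' `GI_i = |m_i - f_i| / (m_i + f_i)`; and their mean `AGI`.
#'
#' @param counts data.frame or matrix with columns `male` and `female`
#'   (optionally `strain` for row names), one row per strain, totals > 0.
#' @return List: `SI` (scalar), `GI` (per strain), `AGI` (scalar).
#' @export
imbalance_metrics <- function(counts) {
  counts <- as.data.frame(counts)
  if (!all(c("male", "female") %in% names(counts)))
    stop("counts needs columns 'male' and 'female'")
  m <- counts$male; f <- counts$female
  tot <- m + f
  if (any(tot <= 0)) stop("every strain must have a positive animal count")
  n <- length(tot)
  si <- max(abs(tot / sum(tot) - 1 / n))
  gi <- abs(m - f) / tot
  if (!is.null(counts$strain)) names(gi) <- counts$strain
  list(SI = si, GI = gi, AGI = mean(gi))
}
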