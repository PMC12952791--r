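# Genetics utilities for strain-survey phenotypes: genotype QC, a
# fixed-effect single-marker association scan, permutation-based
# significance thresholds, GWAS power simulation, greedy LD-based QTL
# grouping, and Haseman-Elston (moment-based) estimators of SNP
# heritability and genetic correlation from a genetic relatedness matrix.
#
# Inbred di-allelic genotypes are coded 0/1 with missing allowed. The
# association engine is ordinary least squares with optional fixed-effect
# covariates (an LMM engine can be dropped in via the same ScanResult
# contract); permutation thresholds, the power simulation, QC and grouping
# are engine-agnostic.

#' Construct a genotype matrix
#'
#' @param genotypes Numeric matrix, samples (strains) x SNPs, codes
#'   {0, 1, NA}.
#' @param map data.frame with columns `snp`, `chr`, `pos` (one row per SNP;
#'   positions non-decreasing within chromosome).
#' @return Object of class `GenotypeMatrix` (fields `genotypes`, `map`).
#' @export
genotype_matrix <- function(genotypes, map = NULL) {
  genotypes <- as.matrix(genotypes)
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("genotype codes must be 0, 1, or NA")
  if (is.null(map)) {
    map <- data.frame(snp = colnames(genotypes) %||%
                        paste0("snp", seq_len(ncol(genotypes))),
                      chr = "1", pos = seq_len(ncol(genotypes)))
  }
  if (nrow(map) != ncol(genotypes))
    stop("map must have one row per SNP column")
  if (!all(c("snp", "chr", "pos") %in% names(map)))
    stop("map needs columns snp, chr, pos")
  for (ch in unique(map$chr)) {
    if (is.unsorted(map$pos[map$chr == ch]))
      stop("positions must be non-decreasing within chromosome ", ch)
  }
  colnames(genotypes) <- map$snp
  structure(list(genotypes = genotypes, map = map), class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("<GenotypeMatrix> %d samples x %d SNPs (%d chromosome(s))\n",
              nrow(x$genotypes), ncol(x$genotypes), length(unique(x$map$chr))))
  invisible(x)
}

#' Per-SNP allele frequency
#'
#' Frequency of the 1 allele among observed calls.
#'
#' @param g A `GenotypeMatrix`.
#' @return Numeric vector, one value per SNP.
#' @export
allele_frequency <- function(g) {
  colMeans(g$genotypes, na.rm = TRUE)
}

#' Genotype quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min` or missing-call
#' fraction above `missing_max`; remaining missing calls are mean-imputed
#' per SNP.
#'
#' @param g A `GenotypeMatrix`.
#' @param maf_min Minimum minor allele frequency (default 0.10).
#' @param missing_max Maximum missing fraction (default 0.05).
#' @return A filtered, imputed `GenotypeMatrix`.
#' @export
qc_genotypes <- function(g, maf_min = 0.10, missing_max = 0.05) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  af <- allele_frequency(g)
  maf <- pmin(af, 1 - af)
  missing <- colMeans(is.na(g$genotypes))
  keep <- !is.na(maf) & maf >= maf_min & missing <= missing_max
  if (!any(keep)) stop("QC removed every SNP")
  geno <- g$genotypes[, keep, drop = FALSE]
  for (j in which(colSums(is.na(geno)) > 0L)) {
    geno[is.na(geno[, j]), j] <- mean(geno[, j], na.rm = TRUE)
  }
  out <- list(genotypes = geno, map = g$map[keep, , drop = FALSE])
  class(out) <- "GenotypeMatrix"
  out
}

#' Expand strain genotypes to animal rows
#'
#' @param g A `GenotypeMatrix` whose rows are strains (rownames = strain
#'   names).
#' @param strains Character vector of per-animal strain assignments.
#' @return A `GenotypeMatrix` with one row per animal.
#' @export
expand_genotypes <- function(g, strains) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  idx <- match(strains, rownames(g$genotypes))
  if (anyNA(idx)) stop("unknown strain(s): ",
                       paste(unique(strains[is.na(idx)]), collapse = ", "))
  out <- list(genotypes = g$genotypes[idx, , drop = FALSE], map = g$map)
  rownames(out$genotypes) <- NULL
  class(out) <- "GenotypeMatrix"
  out
}

geno_of <- function(g) {
  if (inherits(g, "GenotypeMatrix")) g$genotypes else as.matrix(g)
}

# residualize y and the columns of G on [1 | covariates]
project_out <- function(y, G, covariates = NULL) {
  n <- length(y)
  X0 <- cbind(rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    X0 <- cbind(X0, covariates)
  }
  qr0 <- qr(X0)
  list(y = qr.resid(qr0, y),
       G = qr.resid(qr0, G),
       df = n - ncol(X0) - 1L)
}

#' Single-marker association scan
#'
#' Per-SNP least-squares regression of the phenotype on genotype plus
#' optional fixed-effect covariates (e.g. sex, weight, coat color), with a
#' two-sided Wald p-value. SNPs constant after QC get `p = 1` and are
#' flagged.
#'
#' @param g A `GenotypeMatrix` (or plain matrix), rows aligned with `y`.
#' @param y Numeric phenotype vector.
#' @param covariates Optional data.frame/matrix of covariates.
#' @return data.frame of class `ScanResult`: snp, chr, pos, af, beta, se, p,
#'   flag ("ok" or "constant"). Attribute `covariates` records the names
#'   used.
#' @export
association_scan <- function(g, y, covariates = NULL) {
  G <- geno_of(g)
  y <- as.numeric(y)
  if (nrow(G) != length(y)) stop("sample sizes of genotypes and phenotype differ")
  p0 <- 1L + if (is.null(covariates)) 0L else ncol(as.data.frame(covariates))
  if (nrow(G) < p0 + 3L) stop("need at least 3 more samples than covariates")
  pr <- project_out(y, G, covariates)
  df <- pr$df
  ssx <- colSums(pr$G^2)
  sxy <- as.numeric(crossprod(pr$G, pr$y))
  ssy <- sum(pr$y^2)
  const <- ssx < .Machine$double.eps * nrow(G)
  beta <- ifelse(const, 0, sxy / ssx)
  rss <- pmax(ssy - beta * sxy, 0)
  se <- ifelse(const, NA_real_, sqrt(rss / df / ifelse(const, 1, ssx)))
  tstat <- ifelse(const, 0, ifelse(se == 0, Inf, beta / se))
  pval <- ifelse(const, 1, 2 * pt(-abs(tstat), df))
  pval <- pmin(pmax(pval, .Machine$double.xmin), 1)
  map <- if (inherits(g, "GenotypeMatrix")) g$map else
    data.frame(snp = colnames(G) %||% paste0("snp", seq_len(ncol(G))),
               chr = "1", pos = seq_len(ncol(G)))
  out <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                    af = colMeans(G), beta = beta, se = se, p = pval,
                    flag = ifelse(const, "constant", "ok"),
                    stringsAsFactors = FALSE)
  class(out) <- c("ScanResult", "data.frame")
  attr(out, "covariates") <- if (is.null(covariates)) character(0) else
    colnames(as.data.frame(covariates))
  out
}

#' Permutation-based significance threshold
#'
#' The phenotype is shuffled across samples `n_perm` times; each
#' permutation's minimum scan p-value is recorded, and the threshold is the
#' empirical `alpha`-quantile of that min-p distribution (family-wise error
#' rate `alpha`).
#'
#' @inheritParams association_scan
#' @param n_perm Number of permutations (`>= 20`).
#' @param alpha Family-wise error rate (default 0.05).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return The p-value threshold, with the min-p draws in attribute
#'   `min_p`.
#' @export
permutation_threshold <- function(g, y, n_perm = 1000, alpha = 0.05,
                                  seed = 1, covariates = NULL) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  G <- geno_of(g)
  y <- as.numeric(y)
  set.seed(seed)
  pr <- project_out(y, G, covariates)
  df <- pr$df
  ssx <- colSums(pr$G^2)
  keep <- ssx > .Machine$double.eps * nrow(G)
  Gs <- sweep(pr$G[, keep, drop = FALSE], 2, sqrt(ssx[keep]), "/")
  minp <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- pr$y[sample.int(length(y))]
    ssy <- sum(yp^2)
    if (ssy == 0) { minp[i] <- 1; next }
    r2 <- as.numeric(crossprod(Gs, yp))^2 / ssy   # squared partial correlation
    r2max <- min(max(r2), 1 - 1e-12)
    tmax <- sqrt(r2max * df / (1 - r2max))
    minp[i] <- 2 * pt(-tmax, df)
  }
  thr <- as.numeric(quantile(minp, alpha, type = 1))
  attr(thr, "min_p") <- minp
  thr
}

#' Effect size for a target variance explained
#'
#' `sqrt(PVE * Var(y) / (AF * (1 - AF)))`: the additive allele effect needed
#' for one SNP at allele frequency AF to explain a fraction PVE of the
#' phenotypic variance.
#'
#' @param pve Proportion of variance explained, `0 <= pve < 1`.
#' @param var_y Phenotypic variance (> 0).
#' @param af Allele frequency, strictly between 0 and 1.
#' @return Effect size (same units as the phenotype per allele).
#' @export
causal_effect_size <- function(pve, var_y, af) {
  if (pve < 0 || pve >= 1) stop("pve must lie in [0, 1)")
  if (var_y <= 0) stop("var_y must be positive")
  if (af <= 0 || af >= 1) stop("af must lie strictly between 0 and 1")
  sqrt(pve * var_y / (af * (1 - af)))
}

#' GWAS power simulation
#'
#' Reproduces the standard simulation recipe: SNPs with nominal association
#' (`p < prefilter`) to the base phenotype are sorted by genomic position
#' and `n_causal` evenly spaced ones declared causal. For each causal SNP,
#' an effect sized to a target PVE (via [causal_effect_size()]) is added to
#' the base phenotype, the scan repeated, and the SNP counted as detected
#' when its new p-value falls below `threshold`. Power is the detected
#' fraction.
#'
#' @inheritParams association_scan
#' @param y_base Base phenotype vector.
#' @param pve Target per-SNP proportion of variance explained.
#' @param n_causal Number of causal SNPs (`>= 1`).
#' @param threshold Genome-wide significance threshold on p.
#' @param seed Integer seed.
#' @param prefilter Nominal p cutoff for the causal-SNP pool (default 0.05).
#' @return List: `power`, `detail` (per causal SNP: snp, af, effect, p,
#'   detected).
#' @export
simulate_power <- function(g, y_base, pve, n_causal, threshold, seed = 1,
                           covariates = NULL, prefilter = 0.05) {
  if (n_causal < 1) stop("n_causal must be >= 1")
  set.seed(seed)
  base_scan <- association_scan(g, y_base, covariates)
  pool <- base_scan[base_scan$p < prefilter & base_scan$flag == "ok", ]
  if (nrow(pool) < n_causal)
    stop("only ", nrow(pool), " SNPs pass the p < ", prefilter,
         " prefilter; cannot pick ", n_causal, " causal SNPs")
  pool <- pool[order(pool$chr, pool$pos), ]
  pick <- pool$snp[unique(round(seq(1, nrow(pool), length.out = n_causal)))]
  G <- geno_of(g)
  vy <- var(y_base)
  rows <- vector("list", length(pick))
  for (i in seq_along(pick)) {
    j <- match(pick[i], colnames(G))
    af <- mean(G[, j])
    eff <- causal_effect_size(pve, vy, af)
    y_sim <- y_base + eff * G[, j]
    sc <- association_scan(G[, j, drop = FALSE], y_sim, covariates)
    rows[[i]] <- data.frame(snp = pick[i], af = af, effect = eff, p = sc$p,
                            detected = sc$p < threshold)
  }
  detail <- do.call(rbind, rows)
  list(power = mean(detail$detected), detail = detail)
}

#' Greedy LD-based QTL grouping
#'
#' Starting from the unassigned significant SNP with the smallest p-value, a
#' locus is grown by contiguous extension along the chromosome over the
#' remaining significant SNPs: extension proceeds outward from the peak and
#' stops, per direction, at the first SNP whose genotype correlation with
#' the peak falls below `r2_min`. Repeats until every significant SNP is
#' assigned.
#'
#' @param scan A `ScanResult`.
#' @param g The matching `GenotypeMatrix` (post-QC).
#' @param threshold Significance threshold on p.
#' @param r2_min Minimum squared genotype correlation to the peak (default
#'   0.2).
#' @return data.frame (snp, chr, pos, p, locus, is_peak) for significant
#'   SNPs; locus ids are 1, 2, ... in order of peak discovery.
#' @export
greedy_qtl_grouping <- function(scan, g, threshold, r2_min = 0.2) {
  stopifnot(inherits(scan, "ScanResult"))
  G <- geno_of(g)
  sig <- which(scan$p < threshold & scan$flag == "ok")
  if (!length(sig)) stop("no SNP is significant at the given threshold")
  sig_df <- scan[sig, ]
  sig_df$col <- match(sig_df$snp, colnames(G))
  if (anyNA(sig_df$col)) stop("scan SNPs missing from the genotype matrix")
  sig_df$locus <- NA_integer_
  sig_df$is_peak <- FALSE
  locus <- 0L
  while (anyNA(sig_df$locus)) {
    locus <- locus + 1L
    open <- which(is.na(sig_df$locus))
    peak <- open[which.min(sig_df$p[open])]
    sig_df$locus[peak] <- locus
    sig_df$is_peak[peak] <- TRUE
    chr_open <- function() which(is.na(sig_df$locus) &
                                   sig_df$chr == sig_df$chr[peak])
    xg <- G[, sig_df$col[peak]]
    # same-chromosome significant SNPs ordered by position
    same <- which(sig_df$chr == sig_df$chr[peak])
    same <- same[order(sig_df$pos[same])]
    at <- match(peak, same)
    for (dir in c(-1L, 1L)) {
      i <- at + dir
      while (i >= 1L && i <= length(same)) {
        cand <- same[i]
        if (!is.na(sig_df$locus[cand])) break
        r <- suppressWarnings(cor(xg, G[, sig_df$col[cand]]))
        if (is.na(r) || r^2 < r2_min) break
        sig_df$locus[cand] <- locus
        i <- i + dir
      }
    }
  }
  out <- sig_df[, c("snp", "chr", "pos", "p", "locus", "is_peak")]
  rownames(out) <- NULL
  out
}

#' Genetic relatedness matrix
#'
#' `K = Z Z' / M` from column-standardized genotypes `Z` over the `M`
#' polymorphic SNPs; symmetric with mean diagonal approximately 1.
#'
#' @param g A post-QC `GenotypeMatrix` (or plain matrix) with rows =
#'   samples.
#' @return Symmetric n x n kinship matrix.
#' @export
grm <- function(g) {
  G <- geno_of(g)
  mu <- colMeans(G)
  cent <- sweep(G, 2, mu)
  sds <- sqrt(colMeans(cent^2))   # population scaling -> mean diagonal 1
  keep <- sds > 0
  if (!any(keep)) stop("no polymorphic SNPs for the GRM")
  Z <- sweep(cent[, keep, drop = FALSE], 2, sds[keep], "/")
  K <- tcrossprod(Z) / sum(keep)
  rownames(K) <- colnames(K) <- rownames(G)
  K
}

he_slope <- function(K, cp) {
  # regress off-diagonal cross-products on off-diagonal kinship (intercept in)
  off <- upper.tri(K)
  k <- K[off]
  if (sd(k) == 0) stop("degenerate kinship matrix: off-diagonals constant")
  x <- cbind(1, k)
  as.numeric(qr.solve(crossprod(x), crossprod(x, cp[off])))[2L]
}

#' Haseman-Elston heritability
#'
#' Regresses off-diagonal products of the standardized phenotype,
#' `y_i * y_j`, on off-diagonal kinship `K_ij`; the slope estimates the
#' narrow-sense SNP heritability and is clamped to `[0, 1]`.
#'
#' @param K Kinship matrix from [grm()].
#' @param y Phenotype vector aligned with `K` (variance > 0).
#' @return h^2 estimate in `[0, 1]`, with the raw slope in attribute
#'   `raw_slope`.
#' @export
he_heritability <- function(K, y) {
  y <- as.numeric(y)
  if (length(y) != nrow(K)) stop("K and y must align")
  if (var(y) == 0) stop("phenotype has zero variance")
  ys <- as.numeric(scale(y))
  slope <- he_slope(K, tcrossprod(ys))
  out <- min(1, max(0, slope))
  attr(out, "raw_slope") <- slope
  out
}

#' Haseman-Elston genetic correlation
#'
#' Cross-product Haseman-Elston: the genetic covariance slope (regression of
#' symmetrized `y1_i * y2_j` cross-products on kinship) normalized by the
#' geometric mean of the two heritability slopes, clamped to `[-1, 1]`.
#' Returns NA (flagged) when either heritability slope is non-positive.
#'
#' @param K Kinship matrix.
#' @param y1,y2 Phenotype vectors aligned with `K`.
#' @return rg in `[-1, 1]`, or NA with attribute `reason` when undefined.
#' @export
he_genetic_correlation <- function(K, y1, y2) {
  y1 <- as.numeric(scale(y1)); y2 <- as.numeric(scale(y2))
  if (length(y1) != nrow(K) || length(y2) != nrow(K)) stop("K and y must align")
  s1 <- he_slope(K, tcrossprod(y1))
  s2 <- he_slope(K, tcrossprod(y2))
  if (s1 <= 0 || s2 <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "non-positive heritability slope"
    return(out)
  }
  cp <- (tcrossprod(y1, y2) + tcrossprod(y2, y1)) / 2
  s12 <- he_slope(K, cp)
  min(1, max(-1, s12 / sqrt(s1 * s2)))
}
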