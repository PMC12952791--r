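make_geno <- function(n, m, seed = 1, af = NULL) {
  set.seed(seed)
  if (is.null(af)) af <- runif(m, 0.2, 0.8)
  G <- sapply(af, function(a) rbinom(n, 1, a))
  genotype_matrix(G)
}

test_that("QC filters on MAF and missingness exactly, then imputes", {
  G <- matrix(rbinom(400, 1, 0.5), 40, 10)
  G[, 1] <- c(rep(1, 2), rep(0, 38))        # MAF 0.05 -> removed
  G[1:4, 2] <- NA                           # 10% missing -> removed
  G[1, 3] <- NA                             # 2.5% missing -> kept, imputed
  g <- genotype_matrix(G)
  qc <- qc_genotypes(g, maf_min = 0.10, missing_max = 0.05)
  expect_false("snp1" %in% qc$map$snp)
  expect_false("snp2" %in% qc$map$snp)
  expect_true("snp3" %in% qc$map$snp)
  expect_false(anyNA(qc$genotypes))
  expect_equal(unname(qc$genotypes[1, "snp3"]), mean(G[-1, 3]))

  clean <- make_geno(50, 5, seed = 2)
  expect_identical(qc_genotypes(clean)$genotypes, clean$genotypes)
  allbad <- genotype_matrix(matrix(c(rep(0, 99), 1), 50, 2))
  expect_error(qc_genotypes(allbad), "every SNP")
})

test_that("association scan finds perfect signals and is null-calibrated", {
  g <- make_geno(120, 50, seed = 3)
  y <- g$genotypes[, 25] + rnorm(120, 0, 1e-8)
  sc <- association_scan(g, y)
  expect_equal(which.min(sc$p), 25L)
  expect_lt(sc$p[25], 1e-100)

  # null uniformity by KS
  set.seed(4)
  g2 <- make_geno(100, 500, seed = 5)
  y0 <- rnorm(100)
  sc0 <- association_scan(g2, y0)
  expect_gt(ks.test(sc0$p, "punif")$p.value, 0.01)

  # signal carried entirely by a covariate stays null
  set.seed(6)
  covar <- data.frame(sex = rbinom(100, 1, 0.5))
  y1 <- 3 * covar$sex + rnorm(100)
  sc1 <- association_scan(g2, y1, covariates = covar)
  expect_gt(ks.test(sc1$p, "punif")$p.value, 0.01)

  # constant SNP flagged with p = 1
  gc <- genotype_matrix(cbind(snpA = rep(1, 30), snpB = rbinom(30, 1, 0.5)))
  scc <- association_scan(gc, rnorm(30))
  expect_equal(scc$p[1], 1)
  expect_equal(scc$flag[1], "constant")
})

test_that("permutation thresholds hit alpha for one SNP and Sidak brackets for many", {
  g1 <- make_geno(80, 1, seed = 7)
  thr1 <- permutation_threshold(g1, rnorm(80), n_perm = 1000, seed = 1)
  expect_lt(abs(thr1 - 0.05), 0.02)

  g100 <- make_geno(80, 100, seed = 8)
  set.seed(9)
  thr100 <- permutation_threshold(g100, rnorm(80), n_perm = 2000, seed = 2)
  # Sidak bracket, with slack for the finite permutation sample
  expect_gte(thr100, 0.75 * 0.05 / 100)
  expect_lte(thr100, 0.05)
  expect_lte(thr100, 1.5 * (1 - 0.95^(1 / 100)))
  expect_error(permutation_threshold(g1, rnorm(80), n_perm = 5), "n_perm")

  # determinism
  set.seed(10)
  y_fixed <- rnorm(80)
  thr1b <- permutation_threshold(g1, y_fixed, n_perm = 100, seed = 42)
  thr1c <- permutation_threshold(g1, y_fixed, n_perm = 100, seed = 42)
  expect_identical(as.numeric(thr1b), as.numeric(thr1c))
})

test_that("causal effect size follows the PVE formula", {
  expect_equal(causal_effect_size(0, 1, 0.5), 0)
  expect_equal(causal_effect_size(0.25, 1, 0.5), 1)
  expect_equal(causal_effect_size(0.1, 4, 0.2),
               sqrt(0.1 * 4 / (0.2 * 0.8)))
  expect_error(causal_effect_size(0.2, 1, 0), "af")
  expect_error(causal_effect_size(1, 1, 0.5), "pve")
  expect_error(causal_effect_size(0.2, 0, 0.5), "var_y")
})

test_that("power simulation detects strong effects and respects the null", {
  g <- make_geno(200, 100, seed = 10)
  set.seed(11)
  y <- rnorm(200)
  pw <- simulate_power(g, y, pve = 0.5, n_causal = 5, threshold = 0.05,
                       seed = 12)
  expect_gte(pw$power, 0.95)
  expect_equal(nrow(pw$detail), 5)

  # at pve = 0 the simulated phenotype equals the base one, so detection is
  # just the chance that a nominally associated SNP clears a genome-wide
  # threshold - essentially never at a strict threshold
  pw0 <- simulate_power(g, y, pve = 0, n_causal = 5, threshold = 1e-4,
                        seed = 12)
  expect_lte(pw0$power, 0.2)
  expect_error(simulate_power(g, y, 0.5, n_causal = 1e4, threshold = 0.05),
               "prefilter")
})

test_that("greedy QTL grouping resolves LD blocks", {
  set.seed(13)
  n <- 100
  # block 1: SNPs 1-5 near-copies; block 2: SNPs 6-10 near-copies
  f1 <- rbinom(n, 1, 0.5); f2 <- rbinom(n, 1, 0.5)
  mut <- function(x) ifelse(runif(n) < 0.03, 1 - x, x)
  G <- cbind(sapply(1:5, function(i) mut(f1)),
             sapply(1:5, function(i) mut(f2)))
  g <- genotype_matrix(G)
  y <- f1 - f2 + rnorm(n, 0, 0.4)
  sc <- association_scan(g, y)
  loci <- greedy_qtl_grouping(sc, g, threshold = 1e-4, r2_min = 0.2)
  expect_equal(length(unique(loci$locus)), 2L)
  expect_equal(sum(loci$is_peak), 2L)

  # mutually uncorrelated significant SNPs: one locus each
  set.seed(14)
  G2 <- sapply(1:4, function(i) rbinom(n, 1, 0.5))
  g2 <- genotype_matrix(G2)
  y2 <- rowSums(G2) + rnorm(n, 0, 0.3)
  sc2 <- association_scan(g2, y2)
  loci2 <- greedy_qtl_grouping(sc2, g2, threshold = 1e-3, r2_min = 0.2)
  expect_equal(length(unique(loci2$locus)), nrow(loci2))

  # perfectly correlated significant SNPs: a single locus
  G3 <- matrix(rep(f1, 3), n, 3)
  g3 <- genotype_matrix(G3)
  y3 <- f1 + rnorm(n, 0, 0.2)
  sc3 <- association_scan(g3, y3)
  loci3 <- greedy_qtl_grouping(sc3, g3, threshold = 1e-3, r2_min = 0.2)
  expect_equal(unique(loci3$locus), 1L)
  expect_error(greedy_qtl_grouping(sc3, g3, threshold = 1e-300), "significant")
})

test_that("the GRM is a standardized Gram matrix with unit mean diagonal", {
  g <- make_geno(60, 400, seed = 15)
  K <- grm(g)
  expect_equal(K, t(K))
  expect_equal(mean(diag(K)), 1, tolerance = 1e-9)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # identical genotype rows agree with their diagonals
  G <- g$genotypes
  G[2, ] <- G[1, ]
  K2 <- grm(genotype_matrix(G))
  expect_equal(K2[1, 2], K2[1, 1], tolerance = 1e-9)
  # independent genotypes: off-diagonals concentrate near 0
  expect_lt(mean(abs(K[upper.tri(K)])), 3 / sqrt(400))
})

test_that("HE regression recovers heritability and genetic correlation", {
  # recovery at h2 = 0.5 over replicates (scaled down; the fuller grid runs
  # in the acceptance suite)
  ests <- vapply(1:15, function(s) {
    panel <- synth_panel(n_strains = 200, reps_per_strain = 1, n_snps = 300,
                         n_causal = 40, h2 = 0.5, seed = s)
    K <- grm(panel$genotypes)
    as.numeric(he_heritability(K, panel$phenotypes$trait))
  }, 0)
  expect_lt(abs(mean(ests) - 0.5), 0.1)

  # pure noise phenotype
  null_ests <- vapply(1:15, function(s) {
    panel <- synth_panel(n_strains = 150, reps_per_strain = 1, n_snps = 300,
                         n_causal = 40, h2 = 0, seed = s + 100)
    as.numeric(he_heritability(grm(panel$genotypes),
                               panel$phenotypes$trait))
  }, 0)
  expect_lt(mean(null_ests), 0.1)

  # perfectly heritable trait
  panel <- synth_panel(n_strains = 200, reps_per_strain = 1, n_snps = 300,
                       n_causal = 40, h2 = 0.8, seed = 1)
  K <- grm(panel$genotypes)
  gv <- panel$truth$genetic_values
  expect_gt(as.numeric(he_heritability(K, gv)), 0.9)

  # genetic correlation limits
  y1 <- panel$phenotypes$trait
  expect_gt(he_genetic_correlation(K, y1, y1), 0.99)
  rg_flip <- vapply(1:10, function(s) {
    p <- synth_panel(n_strains = 200, reps_per_strain = 1, n_snps = 300,
                     n_causal = 40, h2 = 0.6, seed = s + 300)
    Kp <- grm(p$genotypes)
    gvp <- p$truth$genetic_values
    set.seed(s)
    ya <- gvp + rnorm(200, 0, sqrt(0.4))
    yb <- -gvp + rnorm(200, 0, sqrt(0.4))
    he_genetic_correlation(Kp, ya, yb)
  }, 0)
  expect_lt(abs(median(rg_flip) + 1), 0.15)
  # independent genetic architectures on the same strain panel
  rg_indep <- vapply(1:10, function(s) {
    p <- synth_panel(n_strains = 200, reps_per_strain = 1, n_snps = 300,
                     n_causal = 40, h2 = 0.6, seed = s + 400)
    G <- p$genotypes$genotypes
    set.seed(s)
    idx2 <- sample(ncol(G), 40)
    gv2 <- as.numeric(scale(G[, idx2] %*% rnorm(40))) * sqrt(0.6)
    y2 <- gv2 + rnorm(200, 0, sqrt(0.4))
    he_genetic_correlation(grm(p$genotypes), p$phenotypes$trait, y2)
  }, 0)
  expect_lt(abs(median(rg_indep, na.rm = TRUE)), 0.2)
})
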