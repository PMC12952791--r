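test_that("aggregate phenotypes follow the stated bin conventions", {
  empty <- aggregate_phenotypes(ethogram(rep(0, 30 * 60 * 55)), fps = 30)
  expect_true(all(empty == 0))
  expect_length(empty, 9)

  # one 900-frame bout starting at frame 0 at 30 fps
  n <- 30 * 60 * 55
  e <- frames_from_bouts(bout_list(0, 899), n, fps = 30)
  agg <- aggregate_phenotypes(e, fps = 30)
  expect_equal(unname(agg["duration_T5"]), 0.5)
  expect_equal(unname(agg["nBouts_T5"]), 1)
  expect_equal(unname(agg["avgLen_T5"]), 30)

  # bout straddling the 5-minute boundary: starts minute 4, ends minute 6
  b <- bout_list(4 * 60 * 30, 6 * 60 * 30 - 1)  # 3600 frames = 120 s
  e2 <- frames_from_bouts(b, n, fps = 30)
  agg2 <- aggregate_phenotypes(e2, fps = 30)
  expect_equal(unname(agg2["nBouts_T5"]), 1)       # onset inside the bin
  expect_equal(unname(agg2["duration_T5"]), 1)     # only pre-boundary minute
  expect_equal(unname(agg2["avgLen_T5"]), 120)     # full bout length
  expect_equal(unname(agg2["duration_T20"]), 2)
})

test_that("durations nest monotonically across bins", {
  set.seed(50)
  for (rep in 1:10) {
    lab <- random_track(30 * 60 * 55, p_behavior = 0.05)
    agg <- aggregate_phenotypes(ethogram(lab), fps = 30)
    expect_lte(agg[["duration_T5"]], agg[["duration_T20"]])
    expect_lte(agg[["duration_T20"]], agg[["duration_T55"]])
    expect_lte(agg[["nBouts_T5"]], agg[["nBouts_T20"]])
  }
})

test_that("z-scoring uses strain means and the sample standard deviation", {
  t <- phenotype_table(animal = paste0("a", 1:4),
                       strain = c("s1", "s1", "s2", "s2"),
                       sex = c("M", "F", "M", "F"),
                       values = data.frame(ph = c(0.5, 1.5, 2.5, 3.5),
                                           flat = rep(4, 4)))
  z <- zscore_table(t)
  # strain means 1 and 3 -> z = +/- 1/sqrt(2) under the n-1 convention
  expect_equal(unname(z$z[, "ph"]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z$z[, "flat"]), c(0, 0))
  expect_true(z$degenerate[["flat"]])
  expect_false(z$degenerate[["ph"]])
  expect_false(any(z$mask[, "ph"]))

  expect_error(zscore_table(phenotype_table("a", "s1", "M",
                                            data.frame(x = 1))),
               "2 strains")

  # normalization property on a random table
  set.seed(51)
  n_strains <- 12
  tbl <- phenotype_table(animal = paste0("a", 1:(n_strains * 4)),
                         strain = rep(paste0("s", 1:n_strains), each = 4),
                         sex = rep(c("M", "F"), n_strains * 2),
                         values = data.frame(x = rnorm(n_strains * 4),
                                             y = runif(n_strains * 4)))
  zz <- zscore_table(tbl)
  expect_equal(unname(colMeans(zz$z)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(zz$z, 2, sd)), c(1, 1), tolerance = 1e-10)
})

test_that("sex effects: ties give p = 1, strong effects are detected, nulls controlled", {
  vals <- data.frame(ph = rep(c(1, 2, 3), 4))
  t <- phenotype_table(paste0("a", 1:12), rep("s1", 12),
                       rep(c("M", "F"), each = 6), vals)
  res <- sex_effect(t)
  expect_equal(res$p, 1, tolerance = 1e-9)
  expect_equal(res$effect, 0)

  # strong effect: M ~ N(10, 1), F ~ N(0, 1), n = 5 + 5
  set.seed(52)
  qs <- replicate(21, {
    v <- data.frame(ph = c(rnorm(5, 10), rnorm(5, 0)))
    tt <- phenotype_table(paste0("a", 1:10), rep("s1", 10),
                          rep(c("M", "F"), each = 5), v)
    sex_effect(tt)$q
  })
  expect_lt(median(qs), 0.05)

  # null: fraction of q < 0.05 at most alpha on average over many cells
  set.seed(53)
  frac <- replicate(5, {
    n_cells <- 100
    v <- as.data.frame(matrix(rnorm(10 * n_cells), 10, n_cells))
    tt <- phenotype_table(paste0("a", 1:10), rep("s1", 10),
                          rep(c("M", "F"), each = 5), v)
    mean(sex_effect(tt)$q < 0.05)
  })
  expect_lte(mean(frac), 0.05)

  # under-powered cells are skipped with a reason
  t2 <- phenotype_table(paste0("a", 1:3), rep("s1", 3), c("M", "M", "F"),
                        data.frame(ph = 1:3))
  expect_error(sex_effect(t2), "enough animals")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  set.seed(54)
  for (rep in 1:30) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("imbalance metrics follow their defining formulas", {
  even <- data.frame(strain = c("a", "b"), male = c(2, 2), female = c(2, 2))
  m <- imbalance_metrics(even)
  expect_equal(m$SI, 0)
  expect_equal(m$AGI, 0)

  ex <- data.frame(strain = c("a", "b"), male = c(3, 2), female = c(1, 2))
  m2 <- imbalance_metrics(ex)
  expect_equal(m2$SI, 0)
  expect_equal(unname(m2$GI), c(0.5, 0))
  expect_equal(m2$AGI, 0.25)

  allm <- imbalance_metrics(data.frame(male = c(4, 2), female = c(0, 2)))
  expect_equal(unname(allm$GI[1]), 1)
  expect_error(imbalance_metrics(data.frame(male = 0, female = 0)),
               "positive")

  # bounds on random panels
  set.seed(55)
  for (rep in 1:20) {
    k <- sample(2:10, 1)
    cnt <- data.frame(male = rpois(k, 4), female = rpois(k, 4))
    cnt <- cnt[rowSums(cnt) > 0, , drop = FALSE]
    if (nrow(cnt) < 2) next
    mm <- imbalance_metrics(cnt)
    expect_gte(mm$SI, 0); expect_lte(mm$SI, 1 - 1 / nrow(cnt))
    expect_true(all(mm$GI >= 0 & mm$GI <= 1))
    expect_gte(mm$AGI, 0); expect_lte(mm$AGI, 1)
  }
})
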