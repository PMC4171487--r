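# Ordered subset, variable threshold, standardisation and the adaptive
# permutation engine.

test_that("ordered subset statistic matches chi-square tail arithmetic", {
  os <- ordered_subset_statistic(3.841459, lr = 1)
  expect_equal(os$min_p, 0.05, tolerance = 1e-5)
  expect_equal(os$C, 3.841459)

  os2 <- ordered_subset_statistic(c(5.0, 0.1), lr = c(2, 1))
  expect_equal(os2$p_values[1], 0.02535, tolerance = 1e-3)
  expect_equal(os2$p_values[2], pchisq(5.1, 2, lower.tail = FALSE))
  expect_equal(os2$p_values[2], 0.07808, tolerance = 1e-4)
  expect_equal(os2$C, 5.0)
  expect_identical(os2$subset_size, 1L)

  os0 <- ordered_subset_statistic(c(0, 0, 0), lr = c(3, 2, 1))
  expect_equal(os0$C, 0)
  expect_equal(os0$min_p, 1)

  # no common variants
  osn <- ordered_subset_statistic(numeric(0), numeric(0))
  expect_equal(osn$C, 0)
  expect_equal(osn$min_p, 1)
})

test_that("ordered subset equals brute-force prefix enumeration", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(1:20, 1)
    X <- rchisq(n, 1)
    lr <- rnorm(n) * rbinom(n, 1, 0.8)   # include lr = 0 blocks
    os <- ordered_subset_statistic(X, lr)
    orc <- oracle_ordered_subset(X, lr)
    expect_equal(os$min_p, orc$min_p)
    expect_equal(os$C, orc$C)
    expect_equal(os$subset_size, orc$subset_size)
  }
})

test_that("lr ordering puts zero scores last, breaking ties by X then pos", {
  X <- c(1, 9, 4, 4)
  lr <- c(0, 2, 0, 0)
  os <- ordered_subset_statistic(X, lr, pos = c(10, 20, 30, 40))
  expect_identical(os$order, c(2L, 3L, 4L, 1L))  # lr!=0 first; X desc; pos
})

test_that("rare statistic sums and nests", {
  expect_equal(rare_statistic(c(1.2, 0.3, 2.0)), 3.5)
  expect_equal(rare_statistic(numeric(0)), 0)
  set.seed(4)
  maf <- runif(100, 0, 0.08)
  X <- rchisq(100, 1)
  cls <- classify_variants(maf)
  R <- vapply(cls$rare, function(ix) rare_statistic(X[ix]), 0)
  expect_true(all(diff(rev(R)) >= 0) || all(R[1] >= R))
  expect_true(R[["0.005"]] <= R[["0.01"]] && R[["0.01"]] <= R[["0.03"]] &&
              R[["0.03"]] <= R[["0.05"]])
})

test_that("combined statistic adds components with equal weight", {
  expect_equal(combined_statistic(3.5, 5.0), 8.5)
  expect_equal(combined_statistic(3.5, 0), 3.5)
  expect_equal(combined_statistic(0, 5.0), 5.0)
})

test_that("standardisation centres permuted statistics and reduces to a
           z-score for one threshold", {
  set.seed(12)
  perm <- matrix(rchisq(400, 3), 100, 4)
  obs <- c(5, 6, 7, 8)
  st <- standardize_and_maximize(obs, perm)
  zp <- (perm - matrix(st$means, 100, 4, byrow = TRUE)) /
    matrix(st$sds, 100, 4, byrow = TRUE)
  expect_equal(colMeans(zp), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(zp, 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_equal(st$M, max(st$std_observed))
  # one threshold
  st1 <- standardize_and_maximize(5, perm[, 1, drop = FALSE])
  expect_equal(st1$M, (5 - mean(perm[, 1])) / sd(perm[, 1]))
  # zero-SD threshold is uninformative
  perm0 <- cbind(perm[, 1], 2)
  st0 <- standardize_and_maximize(c(5, 2), perm0)
  expect_equal(st0$std_observed[2], 0)
  # identical thresholds give the same maximum as either alone
  st2 <- standardize_and_maximize(c(5, 5), cbind(perm[, 1], perm[, 1]))
  expect_equal(st2$M, st1$M)
})

test_that("reference permutation matches observed statistics under identity
           signs and has mean-zero flipped numerators", {
  set.seed(31)
  g <- random_trios(80, 12, q = 0.15)
  coh <- make_trio_cohort(g$fa, g$mo, g$ch)
  fs <- family_scores(coh)
  maf <- coh$variants$maf
  lr <- rnorm(length(maf)) * (maf > 0.05)
  ident <- matrix(1, 1, nrow(fs$D))
  pn <- permutation_null(fs$D, lr, maf, ident)
  expect_equal(unname(pn$permuted[1, ]), unname(pn$observed$M_t))
  # all -1 also reproduces the observed statistics (squared numerator)
  pn2 <- permutation_null(fs$D, lr, maf, -ident)
  expect_equal(unname(pn2$permuted[1, ]), unname(pn$observed$M_t))
  # random signs: flipped numerators have mean ~ 0 per variant
  set.seed(32)
  signs <- matrix(sample(c(-1, 1), 400 * 80, replace = TRUE), 400)
  num <- signs %*% fs$D
  expect_lt(max(abs(colMeans(num) / pmax(apply(num, 2, sd), 1e-9))), 0.25)
})

test_that("adaptive engine agrees with the reference permutation
           distribution on a small instance", {
  set.seed(41)
  g <- random_trios(120, 15, q = 0.2)
  coh <- make_trio_cohort(g$fa, g$mo, g$ch)
  fs <- family_scores(coh)
  maf <- coh$variants$maf
  lr <- rnorm(length(maf)) * (maf > 0.05)
  ctrl <- ovpdt_control(min_K = 2000, max_K = 2000, lr_bootstrap = 100)
  res <- ovpdt:::ovpdt_region(fs$D, coh$variants$chrom, maf, lr, ctrl,
                              pos = coh$variants$pos)
  # observed pieces equal the R computation
  cls <- classify_variants(maf)
  os <- ordered_subset_statistic(pdt_statistic(fs$D[, cls$common, drop = FALSE]),
                                 lr[cls$common], pos = cls$common)
  expect_equal(res$C, os$C)
  expect_equal(res$min_p, unname(os$min_p))
  X <- pdt_statistic(fs$D)
  expect_equal(res$R_t, unname(vapply(cls$rare, function(ix) sum(X[ix]), 0)))
  expect_equal(res$M_t, res$R_t + res$C)
  # p-value formula consistency
  expect_equal(res$p_value, (res$exceedances + 1) / (res$K + 1))
  # distributional agreement with the plain-R permutation path
  set.seed(99)
  signs <- matrix(sample(c(-1, 1), 2000 * 120, replace = TRUE), 2000)
  pn <- permutation_null(fs$D, lr, maf, signs, ctrl)
  st <- standardize_and_maximize(pn$observed$M_t, pn$permuted)
  p_ref <- (sum(st$perm_M > st$M) + 1) / (2000 + 1)
  # both are 2000-permutation p-values of the same statistic
  expect_lt(abs(res$p_value - p_ref),
            4 * sqrt(max(p_ref * (1 - p_ref), 0.001) / 2000) + 0.01)
})

test_that("engine is deterministic given the seed and respects the
           p-value floor", {
  coh <- simulate_cohort(ovpdt_scenario("Scen1", n_families = 60), seed = 5)
  ctrl <- ovpdt_control(min_K = 500, max_K = 1500, batch = 500,
                        lr_bootstrap = 100)
  f1 <- ovpdt(coh, control = ctrl, seed = 77)
  f2 <- ovpdt(coh, control = ctrl, seed = 77)
  expect_identical(f1$results, f2$results)
  f3 <- ovpdt(coh, control = ctrl, seed = 78)
  expect_false(identical(f1$results$p_value, f3$results$p_value))
  expect_gte(f1$results$p_value, 1 / (f1$results$K + 1))
  expect_gt(f1$results$p_value, 0)
  expect_lte(f1$results$p_value, 1)
})

test_that("results are invariant to the variant order of the input", {
  coh <- simulate_cohort(ovpdt_scenario("Scen1", n_families = 50), seed = 13)
  perm <- sample(nrow(coh$variants))
  coh2 <- new_cohort(coh$geno[, perm], coh$variants[perm, c("id", "chrom", "pos")],
                     coh$families, validate = FALSE)
  ctrl <- ovpdt_control(min_K = 500, max_K = 500, batch = 500,
                        lr_bootstrap = 200)
  f1 <- ovpdt(coh, control = ctrl, seed = 3)
  f2 <- ovpdt(coh2, control = ctrl, seed = 3)
  expect_equal(f1$results$p_value, f2$results$p_value)
  expect_equal(f1$results$C, f2$results$C)
  expect_equal(f1$results$M, f2$results$M)
})

test_that("regions without informative families are flagged untestable", {
  # all genotypes homozygous: no informative unit anywhere
  fa <- matrix(0L, 4, 3); mo <- matrix(2L, 4, 3); ch <- matrix(1L, 4, 3)
  coh <- make_trio_cohort(fa, mo, ch)
  fit <- ovpdt(coh, control = ovpdt_control(min_K = 100, max_K = 100,
                                            lr_bootstrap = 50), seed = 1)
  expect_equal(fit$results$p_value, 1)
  expect_false(fit$details[[1]]$engine$testable)
})
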