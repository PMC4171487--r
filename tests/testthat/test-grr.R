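# Genotypic relative risk estimation from parental mating types.

test_that("theoretical ratios match the enumeration oracle and are
           allele-frequency free", {
  for (q in c(0.1, 0.3, 0.45)) {
    for (rr in list(c(1, 1), c(2, 3), c(0.8, 0.6), c(1.5, 2))) {
      expect_equal(unname(grr_theoretical_ratios(rr[1], rr[2])),
                   unname(oracle_ratios(q, rr[1], rr[2])), tolerance = 1e-10)
    }
  }
  # frequency invariance asserted directly on the oracle
  expect_equal(oracle_ratios(0.1, 2, 3), oracle_ratios(0.4, 2, 3),
               tolerance = 1e-10)
  # mating-type probabilities themselves agree with the oracle
  expect_equal(unname(mating_type_probs(0.3, 2, 3)),
               unname(oracle_mating_probs(0.3, 2, 3)), tolerance = 1e-12)
})

test_that("mating-type tallies count qualifying families once", {
  fa <- matrix(c(1L, 0L, 1L), 3, 1)
  mo <- matrix(c(1L, 1L, 1L), 3, 1)
  ch <- matrix(c(1L, 0L, 1L), 3, 1)
  coh <- make_trio_cohort(fa, mo, ch)
  counts <- count_mating_types(coh, 1)
  expect_equal(unname(counts[c("1/1", "0/1")]), c(2L, 1L))
  expect_equal(sum(counts), 3L)
  # vectorised tally agrees with the per-variant loop
  set.seed(3)
  g <- random_trios(150, 6, 0.3)
  coh <- make_trio_cohort(g$fa, g$mo, g$ch)
  a <- ovpdt:::mating_counts_matrix(coh, seq_len(nrow(coh$variants)))
  b <- vapply(seq_len(nrow(coh$variants)),
              function(j) as.integer(count_mating_types(coh, j)), integer(6))
  expect_identical(unname(a), unname(b))
})

test_that("mating-type proportions match HWE probabilities under the null", {
  set.seed(8)
  g <- random_trios(2000, 1, q = 0.3)
  coh <- make_trio_cohort(g$fa, g$mo, g$ch)
  counts <- count_mating_types(coh, 1)
  probs <- mating_type_probs(0.3, 1, 1)
  n <- sum(counts)
  for (cell in names(probs)) {
    se <- sqrt(probs[cell] * (1 - probs[cell]) / n)
    expect_lt(abs(counts[cell] / n - probs[cell]), 3 * se + 1e-9)
  }
})

test_that("observed ratios flag estimability cell-wise", {
  counts <- c(`0/0` = 10, `0/1` = 20, `0/2` = 5, `1/1` = 15, `1/2` = 8,
              `2/2` = 2)
  obs <- grr_observed_ratios(counts)
  expect_true(all(obs$estimable))
  expect_equal(unname(obs$ratios[1]), 8^2 / (15 * 2))
  # no homozygous-minor parent: nothing estimable
  obs0 <- grr_observed_ratios(c(50, 30, 0, 12, 0, 0))
  expect_false(any(obs0$estimable))
  expect_true(all(is.na(obs0$ratios)))
  # all families in one cell
  obs1 <- grr_observed_ratios(c(100, 0, 0, 0, 0, 0))
  expect_false(any(obs1$estimable))
})

test_that("grid fit recovers the relative risk from exact proportions", {
  step <- log(grr_grid()$r1[2]) - log(grr_grid()$r1[1])
  for (r1 in c(0.8, 1, 1.5, 2, 3)) {
    for (q in c(0.1, 0.3)) {
      f <- fit_grr(mating_type_probs(q, r1, 2 * r1 - 1) * 1e6)
      expect_true(f$ok)
      expect_lt(abs(log(f$r1) - log(r1)), step + 1e-9)
    }
  }
  # C++ fit path agrees with the R reference on random counts
  grid <- grr_grid()
  set.seed(21)
  for (i in 1:200) {
    counts <- as.numeric(rmultinom(1, 800, mating_type_probs(runif(1, .05, .45),
                                                             exp(runif(1, -0.5, 1.2)),
                                                             1)))
    r_fit <- fit_grr(counts, grid)
    c_fit <- ovpdt:::cpp_grr_fit(counts, grid$r1, grid$ratios)
    if (r_fit$ok) expect_equal(r_fit$r1, c_fit$r1) else expect_true(is.na(c_fit$r1))
  }
  # hierarchical bootstrap scan agrees with the exhaustive scan almost always
  set.seed(22)
  agree <- mean(replicate(2000, {
    q <- runif(1, 0.02, 0.45); r1 <- exp(runif(1, log(0.6), log(4)))
    counts <- as.numeric(rmultinom(1, 500, mating_type_probs(q, r1, 2 * r1 - 1)))
    b <- ovpdt:::cpp_grr_fit_both(counts, grid$ratios)
    b[1] == b[2]
  }))
  expect_gt(agree, 0.995)
})

test_that("fit is unavailable without estimable ratios, and protective
           effects give r1 < 1", {
  f <- fit_grr(c(100, 40, 0, 5, 0, 0))
  expect_false(f$ok)
  expect_identical(f$n_estimable, 0L)
  fp <- fit_grr(mating_type_probs(0.3, 0.8, 0.6) * 1e6)
  expect_lt(fp$r1, 1)
})

test_that("bootstrap variance is seed-deterministic and scales as 1/n", {
  counts <- round(mating_type_probs(0.25, 1.5, 2) * 800)
  set.seed(101); v1 <- bootstrap_var_log_r1(counts, B = 400)
  set.seed(101); v2 <- bootstrap_var_log_r1(counts, B = 400)
  set.seed(202); v3 <- bootstrap_var_log_r1(counts, B = 400)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
  # doubling the information roughly halves the variance
  set.seed(303); vbig <- bootstrap_var_log_r1(counts * 2, B = 400)
  expect_lt(vbig, v1)
  expect_lt(abs(log2(v1 / vbig) - 1), 1)  # within a factor of two of halving
  # degenerate counts: no variance, lr falls back to zero
  expect_true(is.na(bootstrap_var_log_r1(c(100, 0, 0, 0, 0, 0), B = 100)))
})

test_that("normalised lr follows the formula with zero fallbacks", {
  expect_equal(normalized_lr(2, 0.04), log(2) / 0.2)
  expect_equal(normalized_lr(exp(0.6931), 0.04), 3.4655, tolerance = 1e-3)
  expect_equal(normalized_lr(1, 0.5), 0)
  expect_equal(normalized_lr(NA, 0.5), 0)
  expect_equal(normalized_lr(2, 0), 0)
  expect_equal(normalized_lr(2, NA), 0)
})

test_that("lr is invariant under transmission permutations", {
  set.seed(15)
  g <- random_trios(400, 5, q = 0.25)
  coh1 <- make_trio_cohort(g$fa, g$mo, g$ch)
  flip <- matrix(rbinom(400 * 5, 1, 0.5), 400, 5) == 1
  ch2 <- ifelse(flip, g$fa + g$mo - g$ch, g$ch)
  coh2 <- make_trio_cohort(g$fa, g$mo, ch2)
  ix1 <- seq_len(nrow(coh1$variants))
  set.seed(7); lr1 <- variant_lr(coh1, ix1, B = 300)
  set.seed(7); lr2 <- variant_lr(coh2, seq_len(nrow(coh2$variants)), B = 300)
  expect_identical(lr1$lr, lr2$lr)   # bit-identical: parents untouched
  expect_identical(lr1$r1, lr2$r1)
})

test_that("low-frequency variants are mostly unestimable at 1000 trios", {
  set.seed(33)
  unest <- mean(replicate(300, {
    counts <- rmultinom(1, 1000, mating_type_probs(0.01, 1, 1))
    !fit_grr(as.numeric(counts))$ok
  }))
  expect_gt(unest, 0.5)
})
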