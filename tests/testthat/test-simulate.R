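# Haplotype pools, disease model and cohort generation.

test_that("pools are reproducible and calibrated to the target spectrum", {
  set.seed(100)
  p1 <- build_pool(10, "EUR")
  set.seed(100)
  p2 <- build_pool(10, "EUR")
  expect_identical(p1$lo, p2$lo)
  expect_identical(p1$tip_index, p2$tip_index)
  expect_identical(p1$pos, p2$pos)

  set.seed(101)
  stats <- replicate(40, {
    p <- build_pool(10, "EUR")
    c(length(p$maf), sum(p$maf < 0.01))
  })
  m <- rowMeans(stats)
  expect_gt(m[1], 198 * 0.85)          # mean site count within 15%
  expect_lt(m[1], 198 * 1.15)
  expect_gt(m[2] / m[1], 0.78)         # rare fraction near 166/198
  expect_lt(m[2] / m[1], 0.90)
  # site frequencies are valid and folded
  expect_true(all(p1$maf > 0 & p1$maf <= 0.5))
  expect_true(all(p1$pos >= 1 & p1$pos <= 10000))
  expect_false(is.unsorted(p1$pos))
})

test_that("25 kb pools scale to the larger region", {
  set.seed(102)
  stats <- replicate(12, {
    p <- build_pool(25, "EUR")
    c(length(p$maf), sum(p$maf < 0.01))
  })
  m <- rowMeans(stats)
  expect_gt(m[1], 512 * 0.85)
  expect_lt(m[1], 512 * 1.15)
})

test_that("effect assignment follows the scenario", {
  set.seed(7)
  pool <- build_pool(10, "EUR")
  # null scenario: no effects
  eff0 <- assign_effects(pool, ovpdt_scenario("Scen2"))
  expect_true(all(eff0$beta == 0))
  # rare-only risk effects follow the MAF function
  eff1 <- assign_effects(pool, ovpdt_scenario("Scen11"))
  rare <- which(pool$maf < 0.01)
  expect_equal(length(eff1$causal), round(0.3 * length(rare)))
  expect_true(all(eff1$causal %in% rare))
  expect_equal(eff1$beta[eff1$causal],
               rare_log_or(pool$maf[eff1$causal]))
  # common effects drawn from the stated odds-ratio range
  eff2 <- assign_effects(pool, ovpdt_scenario("Scen13"))
  ors <- exp(eff2$beta[eff2$causal])
  expect_true(all(ors >= 1.05 & ors <= 1.3))
  # protective flips: stated fraction becomes reciprocal
  eff3 <- assign_effects(pool, ovpdt_scenario("Scen12"))
  n_prot <- sum(eff3$beta[eff3$causal] < 0)
  expect_equal(n_prot, round(0.3 * length(eff3$causal)))
  expect_true(all(abs(eff3$beta[eff3$causal]) > 0))
})

test_that("intercept calibration hits the target prevalence", {
  expect_equal(calibrate_intercept(NULL, beta = numeric(5)), qlogis(0.05))
  set.seed(14)
  pool <- build_pool(10, "EUR")
  eff <- assign_effects(pool, ovpdt_scenario("Scen15"))
  alpha <- calibrate_intercept(pool, eff$beta)
  expect_lt(alpha, qlogis(0.05))  # positive effects push the intercept down
  # realised prevalence in a fresh population
  h1 <- sample.int(pool$n_hap, 40000, TRUE)
  h2 <- sample.int(pool$n_hap, 40000, TRUE)
  causal <- which(eff$beta != 0)
  g <- ovpdt:::hap_carries(pool, h1, causal) + ovpdt:::hap_carries(pool, h2, causal)
  flip <- pool$derived_freq[causal] > 0.5
  g[, flip] <- 2 - g[, flip]
  prev <- mean(plogis(alpha + as.vector(g %*% eff$beta[causal])))
  expect_lt(abs(prev - 0.05), 0.005)
})

test_that("cohorts honour the family structure and affection pattern", {
  for (s in c("A", "AUU", "AA")) {
    sc <- ovpdt_scenario("Scen2", n_families = 12, structure = s)
    coh <- simulate_cohort(sc, seed = 4)
    pat <- ovpdt:::structure_pattern(s)
    expect_length(coh$families, 12L)
    for (f in coh$families) {
      expect_length(f$children, length(pat))
      expect_identical(f$affected, as.logical(pat))
    }
  }
})

test_that("null cohorts have exchangeable transmissions", {
  set.seed(18)
  dbars <- replicate(25, {
    coh <- simulate_cohort(ovpdt_scenario("Scen2", n_families = 120), seed = NULL)
    fs <- family_scores(coh)
    mean(colSums(fs$D) / pmax(sqrt(colSums(fs$D^2)), 1e-9))
  })
  # standardised per-variant transmission excess averages to zero
  expect_lt(abs(mean(dbars)), 3 * sd(dbars) / sqrt(length(dbars)) + 0.05)
})

test_that("risk effects inflate minor-allele transmission monotonically", {
  sc1 <- ovpdt_scenario("Scen11", n_families = 300)
  sc2 <- ovpdt_scenario("Scen11", n_families = 300,
                        log_or_fun = function(m) 2 * rare_log_or(m))
  mean_t <- function(sc, seed) {
    coh <- simulate_cohort(sc, seed = seed)
    eff <- attr(coh, "effects")[[1]]
    fs <- family_scores(coh)
    ids <- sprintf("v%05d", eff$causal)
    j <- match(ids, coh$variants$id)
    # risk variants only, oriented: positive beta means minor allele risk
    sgn <- sign(eff$beta[eff$causal])
    mean(colSums(fs$D[, j[!is.na(j)], drop = FALSE]) * sgn[!is.na(j)])
  }
  t1 <- mean(vapply(1:6, function(s) mean_t(sc1, s), 0))
  t2 <- mean(vapply(1:6, function(s) mean_t(sc2, s), 0))
  expect_gt(t1, 0)
  expect_gt(t2, t1)
})

test_that("two-population cohorts mix the stated family counts", {
  sc <- ovpdt_scenario("Scen9", n_families = 40)
  coh <- simulate_cohort(sc, seed = 6)
  expect_length(coh$families, 40L)
  eff <- attr(coh, "effects")
  expect_setequal(names(eff), c("EUR", "AFR"))
  expect_true(all(vapply(eff, function(e) all(e$beta == 0), TRUE)))
  # population-private sites: each subpopulation contributes variants the
  # other lacks entirely
  eur_rows <- unlist(lapply(coh$families[1:28], function(f)
    c(f$father, f$mother, f$children)))
  afr_rows <- setdiff(seq_len(nrow(coh$geno)), eur_rows)
  eur_absent <- colSums(coh$geno[eur_rows, , drop = FALSE]) == 0
  afr_absent <- colSums(coh$geno[afr_rows, , drop = FALSE]) == 0
  expect_gt(sum(eur_absent), 0)
  expect_gt(sum(afr_absent), 0)
})

test_that("scenario presets reflect the study table", {
  s2 <- ovpdt_scenario("Scen2")
  expect_equal(s2$n_families, 1000)
  expect_equal(s2$region_kb, 10)
  expect_equal(s2$structure, "A")
  s16 <- ovpdt_scenario("Scen16")
  expect_equal(s16$common_frac, 0.3)
  expect_equal(s16$rare_frac, 0.3)
  expect_equal(s16$protective_frac, 0.3)
  s19 <- ovpdt_scenario("Scen19")
  expect_equal(s19$region_kb, 25)
  expect_error(ovpdt_scenario("Scen99"), "unknown")
  # overrides apply
  expect_equal(ovpdt_scenario("Scen2", n_families = 50)$n_families, 50)
})
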