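#!/usr/bin/env Rscript
# Calibration of the coalescent pool parameters (POOL_PARAMS in R/simulate.R).
#
# Targets, for pools of 10,000 haplotypes: mean polymorphic-site counts of
# ~198 (10 kb) and ~512 (25 kb), with a rare (MAF < 0.01) fraction of
# ~166/198 = 0.838 in the 10 kb region (429/512 in 25 kb). The growth
# parameters set the shape of the site frequency spectrum (hence the rare
# fraction); theta then scales the site count linearly. Run after changing
# the demographic model to re-derive the constants; this script is for
# development and is not part of the test surface.

library(ovpdt)

probe <- function(theta, growth, tg, n = 80, n_hap = 10000L) {
  r <- replicate(n, {
    s <- ovpdt:::cpp_coalescent_pool(n_hap, theta, growth, tg)
    d <- s$hi - s$lo + 1L
    maf <- pmin(d, n_hap - d) / n_hap
    c(sites = length(maf), rare = sum(maf < 0.01))
  })
  rowMeans(r)
}

set.seed(11)
cat("-- rare-fraction sweep (theta = 200, shape only) --\n")
for (g in c(300, 400, 450, 500)) for (tg in c(0.004, 0.005, 0.006)) {
  r <- probe(200, g, tg, n = 25)
  cat(sprintf("growth=%4g tg=%.3f rare_frac=%.3f\n", g, tg, r["rare"] / r["sites"]))
}

cat("-- final constants --\n")
print(probe(63.9, 450, 0.005))    # EUR 10 kb: target 198 sites, 166 rare
print(probe(165.3, 450, 0.005))   # EUR 25 kb: target 512 sites, 429 rare
print(probe(66.0, 300, 0.005))    # AFR 10 kb: milder growth, higher diversity
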