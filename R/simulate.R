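# Simulation of family sequencing cohorts: calibrated coalescent haplotype
# pools, a logistic penetrance disease model at fixed prevalence, and
# ascertainment by nuclear-family affection pattern.

# Coalescent parameters per population, calibrated so that 10 kb pools of
# 10,000 haplotypes average ~198 polymorphic sites of which ~166 have
# MAF < 0.01 (and 25 kb pools ~512 = 429 + 83). The demographic model is a
# recent exponential expansion (relative size e^{-growth*t} backward in time
# until t_growth), a constant bottleneck size until t_anc, and a smaller
# ancient size (anc_scale x bottleneck) beyond; growth skews the spectrum
# towards rare variants while the short ancient epoch keeps the density of
# high-frequency (MAF > 0.05) variants near sequencing-data levels
# (~1.5/kb). theta is the regionwide mutation
# parameter, tuned last (slightly super-linear in region size to match both
# printed anchors). seg_rate_kb is the expected number of genealogy-changing
# recombination events per kb, rho/2 * E[tree length] with rho = 4*Ne*r per
# kb (Ne = 1e4, r = 1.3e-8/bp/gen) and mean marginal tree length ~6.2
# coalescent units under this demography. Calibration:
# scripts/calibrate_pool.R.
POOL_PARAMS <- list(
  EUR = list(growth = 350, t_growth = 0.005, t_anc = 0.10, anc_scale = 0.2,
             theta = c(`10` = 58.6, `25` = 151.5), seg_rate_kb = 1.7),
  AFR = list(growth = 250, t_growth = 0.005, t_anc = 0.06, anc_scale = 0.5,
             theta = c(`10` = 55.0, `25` = 140.0), seg_rate_kb = 1.7)
)

pool_theta <- function(pp, region_kb) {
  key <- as.character(region_kb)
  if (key %in% names(pp$theta)) unname(pp$theta[key])
  else unname(pp$theta["10"] / 10 * region_kb)
}

#' Default rare-variant effect-size function
#'
#' Log odds ratio of a rare risk variant as a decreasing function of its
#' minor allele frequency, \code{log OR = (log 5 / 4) * |log10 MAF|}: the
#' standard MAF-dependent effect model of the sequencing power-study
#' literature (OR = 5 at MAF 1e-4, ~2.2 at MAF 0.01).
#'
#' @param maf minor allele frequency (vectorised).
#' @return Log odds ratio(s).
#' @export
rare_log_or <- function(maf) (log(5) / 4) * abs(log10(maf))

#' Build a coalescent haplotype pool
#'
#' Simulate a pool of haplotypes for a 10 kb or 25 kb region under a
#' coalescent with recent exponential growth, calibrated per population so
#' the mean variant count and the rare/common split (MAF cut 0.01) match the
#' target sequencing-like spectrum. Ancestral recombination is approximated
#' by splitting the region into a Poisson number of segments with
#' independent genealogies (intensity from standard human recombination
#' parameters). Reproducible under \code{set.seed}.
#'
#' @param region_kb region size in kb (10 or 25).
#' @param population \code{"EUR"} or \code{"AFR"}.
#' @param n_hap pool size (haplotypes).
#' @return An object of class \code{ovpdt_pool}: site ranges in tip order,
#'   per-haplotype tip positions, site positions (bp), derived and minor
#'   allele frequencies.
#' @export
build_pool <- function(region_kb = 10, population = c("EUR", "AFR"),
                       n_hap = 10000L) {
  population <- match.arg(population)
  pp <- POOL_PARAMS[[population]]
  theta <- pool_theta(pp, region_kb)
  n_seg <- 1L + stats::rpois(1L, pp$seg_rate_kb * region_kb)
  breaks <- sort(stats::runif(n_seg - 1L))
  w <- diff(c(0, breaks, 1))
  sim <- cpp_coalescent_pool(as.integer(n_hap), theta * w, pp$growth,
                             pp$t_growth, pp$t_anc, pp$anc_scale)
  s <- length(sim$lo)
  if (s == 0L) stop("coalescent produced no polymorphic site; theta too small")
  region_bp <- region_kb * 1000
  bounds <- c(0, breaks, 1) * region_bp
  pos <- integer(s)
  for (i in seq_len(n_seg)) {
    ix <- which(sim$seg == i)
    if (!length(ix)) next
    span <- max(1L, floor(bounds[i + 1]) - ceiling(bounds[i]))
    pos[ix] <- ceiling(bounds[i]) +
      sort(sample.int(span, length(ix), replace = length(ix) > span))
  }
  d <- sim$hi - sim$lo + 1L
  structure(list(n_hap = as.integer(n_hap), lo = sim$lo, hi = sim$hi,
                 seg = sim$seg, tip_index = sim$tip_index,
                 pos = pos, derived_freq = d / n_hap,
                 maf = pmin(d, n_hap - d) / n_hap,
                 region_kb = region_kb, population = population),
            class = "ovpdt_pool")
}

#' @export
print.ovpdt_pool <- function(x, ...) {
  cat("Coalescent haplotype pool:", x$n_hap, "haplotypes,",
      length(x$pos), "sites,", max(x$seg), "segments,",
      x$region_kb, "kb,", x$population, "\n")
  cat("  rare (MAF<0.01):", sum(x$maf < 0.01),
      " common:", sum(x$maf >= 0.01), "\n")
  invisible(x)
}

# Dosages of the derived allele for a set of haplotype indices at given sites.
hap_carries <- function(pool, haps, sites) {
  vapply(sites, function(s) {
    ti <- pool$tip_index[haps, pool$seg[s]]
    ti >= pool$lo[s] & ti <= pool$hi[s]
  }, logical(length(haps)))
}

#' Scenario configurations for the simulation study
#'
#' Named presets \code{Scen1}-\code{Scen22} reproduce the type I error
#' (Scen1-Scen10) and power (Scen11-Scen22) configurations: region size 10 or
#' 25 kb, 500 or 1,000 families, family structure A (trio with one affected
#' child), AUU (one affected + two unaffected sibs) or AA (two affected
#' sibs), an optional 700/300 two-population mixture, and causal fractions by
#' variant class with an optional 30\% protective flip. Rare variants are
#' those with pool MAF < 0.01; 5\% disease prevalence throughout.
#'
#' @param name preset name \code{"Scen1"}..\code{"Scen22"}.
#' @param ... overrides of individual fields (e.g. \code{n_families}).
#' @return A list of class \code{ovpdt_scenario}.
#' @export
ovpdt_scenario <- function(name, ...) {
  presets <- list(
    Scen1  = list(region_kb = 10, n_families = 500,  structure = "A"),
    Scen2  = list(region_kb = 10, n_families = 1000, structure = "A"),
    Scen3  = list(region_kb = 10, n_families = 1000, structure = "AUU"),
    Scen4  = list(region_kb = 10, n_families = 1000, structure = "AA"),
    Scen5  = list(region_kb = 25, n_families = 500,  structure = "A"),
    Scen6  = list(region_kb = 25, n_families = 1000, structure = "A"),
    Scen7  = list(region_kb = 25, n_families = 1000, structure = "AUU"),
    Scen8  = list(region_kb = 25, n_families = 1000, structure = "AA"),
    Scen9  = list(region_kb = 10, n_families = 1000, structure = "A",
                  populations = c(EUR = 700, AFR = 300)),
    Scen10 = list(region_kb = 25, n_families = 1000, structure = "A",
                  populations = c(EUR = 700, AFR = 300)),
    Scen11 = list(region_kb = 10, rare_frac = 0.3),
    Scen12 = list(region_kb = 10, rare_frac = 0.3, protective_frac = 0.3),
    Scen13 = list(region_kb = 10, common_frac = 0.3),
    Scen14 = list(region_kb = 10, common_frac = 0.1, rare_frac = 0.1),
    Scen15 = list(region_kb = 10, common_frac = 0.3, rare_frac = 0.3),
    Scen16 = list(region_kb = 10, common_frac = 0.3, rare_frac = 0.3,
                  protective_frac = 0.3),
    Scen17 = list(region_kb = 25, rare_frac = 0.3),
    Scen18 = list(region_kb = 25, rare_frac = 0.3, protective_frac = 0.3),
    Scen19 = list(region_kb = 25, common_frac = 0.3),
    Scen20 = list(region_kb = 25, common_frac = 0.1, rare_frac = 0.1),
    Scen21 = list(region_kb = 25, common_frac = 0.3, rare_frac = 0.3),
    Scen22 = list(region_kb = 25, common_frac = 0.3, rare_frac = 0.3,
                  protective_frac = 0.3)
  )
  if (!name %in% names(presets)) stop("unknown scenario: ", name)
  base <- list(name = name, region_kb = 10, n_families = 1000,
               structure = "A", populations = c(EUR = 1),
               common_frac = 0, rare_frac = 0, protective_frac = 0,
               rare_class_cut = 0.01, prevalence = 0.05,
               common_or_range = c(1.05, 1.3), n_hap = 10000L,
               log_or_fun = rare_log_or)
  sc <- utils::modifyList(base, presets[[name]])
  sc <- utils::modifyList(sc, list(...))
  if (!identical(names(sc$populations), "EUR") || sc$populations[[1]] < 1)
    sc$populations <- round(sc$populations / sum(sc$populations) * sc$n_families)
  else
    sc$populations <- c(EUR = sc$n_families)
  class(sc) <- "ovpdt_scenario"
  sc
}

#' @export
print.ovpdt_scenario <- function(x, ...) {
  cat("Scenario", x$name, ":", x$region_kb, "kb,", x$n_families,
      x$structure, "families;",
      paste(names(x$populations), x$populations, collapse = " + "), "\n")
  cat("  causal: common", x$common_frac, "rare", x$rare_frac,
      "| protective", x$protective_frac, "\n")
  invisible(x)
}

#' Assign disease-model effects to pool sites
#'
#' Sample causal sites uniformly within the rare (pool MAF below
#' \code{rare_class_cut}) and common classes at the scenario's fractions.
#' Rare risk variants get a MAF-dependent log odds ratio; common risk
#' variants get an odds ratio drawn uniformly from the scenario's range. A
#' fraction of all causal sites is then flipped to protective by inverting
#' the odds ratio. Effects apply to the derived allele when it is the minor
#' allele (and to the other allele otherwise), keeping the stated MAF-effect
#' relationship.
#'
#' @param pool an \code{ovpdt_pool}.
#' @param scenario an \code{ovpdt_scenario}.
#' @return List with \code{beta} (per-site log OR of the minor pool allele,
#'   0 for non-causal) and \code{causal} (site indices).
#' @export
assign_effects <- function(pool, scenario) {
  s <- length(pool$maf)
  beta <- numeric(s)
  rare <- which(pool$maf < scenario$rare_class_cut)
  common <- setdiff(seq_len(s), rare)
  pick <- function(ix, frac) {
    n <- round(length(ix) * frac)
    if (n > 0 && length(ix) == 0L) stop("empty variant class with causal fraction > 0")
    if (n == 0L) integer(0) else sample(ix, n)
  }
  c_rare <- pick(rare, scenario$rare_frac)
  c_common <- pick(common, scenario$common_frac)
  if (length(c_rare))
    beta[c_rare] <- scenario$log_or_fun(pool$maf[c_rare])
  if (length(c_common))
    beta[c_common] <- log(stats::runif(length(c_common),
                                       scenario$common_or_range[1],
                                       scenario$common_or_range[2]))
  causal <- c(c_rare, c_common)
  if (scenario$protective_frac > 0 && length(causal)) {
    flip <- sample(causal, round(length(causal) * scenario$protective_frac))
    beta[flip] <- -beta[flip]
  }
  list(beta = beta, causal = sort(causal))
}

#' Calibrate the logistic intercept to the target prevalence
#'
#' Solve for the intercept alpha such that the population mean of
#' \code{plogis(alpha + sum(beta * g))}, over individuals formed from random
#' pool haplotype pairs, equals the target prevalence. With no effects the
#' closed form \code{qlogis(prevalence)} is returned; otherwise alpha is
#' found by root-finding on a Monte Carlo population.
#'
#' @param pool an \code{ovpdt_pool}.
#' @param beta per-site log odds ratios (derived-minor coding as produced by
#'   \code{\link{assign_effects}}).
#' @param prevalence target disease prevalence.
#' @param n_mc Monte Carlo population size.
#' @param tol acceptable absolute deviation of the realised prevalence.
#' @return The intercept alpha.
#' @export
calibrate_intercept <- function(pool, beta, prevalence = 0.05,
                                n_mc = 50000L, tol = 0.002) {
  causal <- which(beta != 0)
  if (length(causal) == 0L) return(stats::qlogis(prevalence))
  h1 <- sample.int(pool$n_hap, n_mc, replace = TRUE)
  h2 <- sample.int(pool$n_hap, n_mc, replace = TRUE)
  g <- hap_carries(pool, h1, causal) + hap_carries(pool, h2, causal)
  # effect is attached to the minor pool allele; recode columns where the
  # derived allele is the major one
  flip <- pool$derived_freq[causal] > 0.5
  if (any(flip)) g[, flip] <- 2 - g[, flip]
  score <- as.vector(g %*% beta[causal])
  f <- function(a) mean(stats::plogis(a + score)) - prevalence
  sol <- stats::uniroot(f, lower = stats::qlogis(prevalence) - 25,
                        upper = stats::qlogis(prevalence) + 5,
                        tol = 1e-10)
  if (abs(f(sol$root)) > tol)
    stop("prevalence calibration did not converge: residual ",
         signif(f(sol$root), 3))
  sol$root
}

# Affection pattern of the children for each family structure.
structure_pattern <- function(structure) {
  switch(structure,
         A = TRUE,
         AUU = c(TRUE, FALSE, FALSE),
         AA = c(TRUE, TRUE),
         stop("unknown family structure: ", structure))
}

#' Simulate an ascertained family cohort
#'
#' Generate a cohort under a scenario: fresh coalescent pool(s), causal
#' effects, a logistic penetrance model calibrated to the target prevalence,
#' parents drawn as random pool haplotype pairs, children by Mendelian
#' transmission (one haplotype per parent, no within-region recombination),
#' and whole-family rejection until the structure's affection pattern holds.
#' Two-population scenarios draw families from population-specific pools
#' whose variant sets are disjoint (population-private sites), a deliberately
#' strong form of stratification.
#'
#' @param scenario an \code{ovpdt_scenario}.
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling cap per family.
#' @return An \code{ovpdt_cohort}; the attribute \code{"effects"} records the
#'   simulated betas and causal sites per population.
#' @export
simulate_cohort <- function(scenario, seed = NULL, max_tries = 100000L) {
  stopifnot(inherits(scenario, "ovpdt_scenario"))
  if (!is.null(seed)) set.seed(seed)
  pops <- scenario$populations
  if (length(pops) > 1L && (scenario$common_frac > 0 || scenario$rare_frac > 0))
    stop("causal effects in two-population scenarios are not supported")
  pattern <- structure_pattern(scenario$structure)

  blocks <- list()
  effects <- list()
  for (pn in names(pops)) {
    pool <- build_pool(scenario$region_kb, pn, scenario$n_hap)
    eff <- assign_effects(pool, scenario)
    # attach effects to minor-allele dosage: convert to derived-allele coding
    beta_derived <- eff$beta
    flip <- pool$derived_freq > 0.5 & beta_derived != 0
    # dosage_minor = 2 - dosage_derived at flipped sites: slope negates,
    # constant shift is absorbed by the intercept calibration below
    alpha <- calibrate_intercept(pool, eff$beta, scenario$prevalence)
    alpha_adj <- alpha + sum(2 * eff$beta[flip])
    beta_derived[flip] <- -beta_derived[flip]
    fam <- cpp_simulate_families(pool$lo, pool$hi, pool$seg, pool$tip_index,
                                 pool$n_hap, beta_derived,
                                 which(beta_derived != 0) - 1L, alpha_adj,
                                 as.integer(pops[[pn]]), pattern,
                                 as.integer(max_tries))
    blocks[[pn]] <- list(pool = pool, geno = fam$geno)
    effects[[pn]] <- list(beta = eff$beta, causal = eff$causal,
                          alpha = alpha, maf = pool$maf)
  }

  n_children <- length(pattern)
  fam_size <- 2L + n_children
  # union variant table across populations (positions resampled on collision)
  all_pos <- integer(0)
  for (pn in names(blocks)) {
    pos <- blocks[[pn]]$pool$pos
    clash <- pos %in% all_pos
    while (any(clash)) {
      pos[clash] <- sample.int(scenario$region_kb * 1000L, sum(clash))
      clash <- pos %in% all_pos | duplicated(pos)
    }
    blocks[[pn]]$pos <- pos
    all_pos <- c(all_pos, pos)
  }
  o <- order(all_pos)
  total_fams <- sum(vapply(blocks, function(b) nrow(b$geno) / fam_size, 0))
  geno <- matrix(0L, total_fams * fam_size, length(all_pos))
  col_at <- 0L
  row_at <- 0L
  for (pn in names(blocks)) {
    b <- blocks[[pn]]
    nr <- nrow(b$geno)
    geno[row_at + seq_len(nr), col_at + seq_len(ncol(b$geno))] <- b$geno
    col_at <- col_at + ncol(b$geno)
    row_at <- row_at + nr
  }
  geno <- geno[, o, drop = FALSE]
  variants <- data.frame(
    id = sprintf("v%05d", seq_along(all_pos)),
    chrom = "1", pos = all_pos[o], stringsAsFactors = FALSE)

  ids <- character(nrow(geno))
  families <- vector("list", total_fams)
  for (i in seq_len(total_fams)) {
    base <- (i - 1L) * fam_size
    fid <- sprintf("F%04d", i)
    ids[base + 1L] <- paste0(fid, "_fa")
    ids[base + 2L] <- paste0(fid, "_mo")
    ids[base + 2L + seq_len(n_children)] <-
      paste0(fid, "_c", seq_len(n_children))
    families[[i]] <- list(fid = fid, father = base + 1L, mother = base + 2L,
                          children = base + 2L + seq_len(n_children),
                          affected = as.logical(pattern))
  }
  rownames(geno) <- ids
  coh <- new_cohort(geno, variants, families, validate = FALSE)
  attr(coh, "effects") <- effects
  attr(coh, "scenario") <- scenario$name
  coh
}
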