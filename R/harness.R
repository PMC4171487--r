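# Replicated simulation experiments: type I error and power.

# One replicate: simulate a cohort under the scenario and run the full test
# on the region formed by all its variants. Per-replicate seeds are derived
# from the experiment seed so results do not depend on execution order.
replicate_pvalue <- function(scenario, control, rep_seed) {
  coh <- simulate_cohort(scenario, seed = rep_seed)
  fit <- ovpdt(coh, control = control)
  fit$results$p_value[1]
}

derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 9973 * seq_len(n)) %% 2147483647
}

run_experiment <- function(scenario, n_replicates, alphas, seed, control,
                           progress = FALSE) {
  stopifnot(inherits(scenario, "ovpdt_scenario"), n_replicates >= 1L)
  seeds <- derive_seeds(seed, n_replicates)
  t0 <- proc.time()[["elapsed"]]
  p <- vapply(seq_len(n_replicates), function(i) {
    if (progress && i %% 50L == 0L)
      message("  replicate ", i, "/", n_replicates)
    replicate_pvalue(scenario, control, seeds[i])
  }, 0)
  elapsed <- proc.time()[["elapsed"]] - t0
  rates <- lapply(alphas, function(a) {
    k <- sum(p <= a)
    ci <- stats::binom.test(k, n_replicates)$conf.int
    list(alpha = a, rejections = k, rate = k / n_replicates,
         ci_lower = ci[1], ci_upper = ci[2])
  })
  structure(list(scenario = scenario$name, n_replicates = n_replicates,
                 seed = seed, rates = rates, p_values = p,
                 elapsed = elapsed, control = control),
            class = "ovpdt_experiment")
}

#' Type I error experiment
#'
#' Simulate replicate cohorts under a null scenario (no causal variants),
#' run the full OVPDT test on each, and report the empirical rejection rate
#' at each significance level together with its exact binomial 95\%
#' confidence interval.
#'
#' @param scenario a null \code{\link{ovpdt_scenario}} (Scen1-Scen10).
#' @param n_replicates number of simulation replicates.
#' @param alphas significance levels to report.
#' @param seed experiment seed; replicate seeds are derived from it, so
#'   results are independent of execution order.
#' @param control permutation settings; the default caps permutations at
#'   20,000, ample resolution for rejection decisions at these levels.
#' @param progress emit progress messages.
#' @return An \code{ovpdt_experiment} report.
#' @export
run_type1 <- function(scenario, n_replicates = 2000L,
                      alphas = c(0.05, 0.01), seed = 1L,
                      control = ovpdt_control(max_K = 20000L),
                      progress = FALSE) {
  if (scenario$common_frac > 0 || scenario$rare_frac > 0)
    stop("type I error experiments need a null scenario")
  run_experiment(scenario, n_replicates, alphas, seed, control, progress)
}

#' Power experiment
#'
#' As \code{\link{run_type1}} but under a scenario with causal effects;
#' reports the rejection rate (power) at the given level.
#'
#' @param scenario a power \code{\link{ovpdt_scenario}} (Scen11-Scen22).
#' @param n_replicates number of simulation replicates.
#' @param alpha significance level.
#' @param seed experiment seed.
#' @param control permutation settings; the default caps permutations at
#'   2,000 (p-value floor 1/2001), ample resolution to classify rejection at
#'   the 0.05 level.
#' @param progress emit progress messages.
#' @return An \code{ovpdt_experiment} report.
#' @export
run_power <- function(scenario, n_replicates = 250L, alpha = 0.05,
                      seed = 1L, control = ovpdt_control(max_K = 2000L),
                      progress = FALSE) {
  run_experiment(scenario, n_replicates, alpha, seed, control, progress)
}

#' @export
print.ovpdt_experiment <- function(x, ...) {
  cat("OVPDT experiment:", x$scenario, "-", x$n_replicates,
      "replicates (seed", paste0(x$seed, ")"), "\n")
  for (r in x$rates)
    cat(sprintf("  alpha = %-5g rate = %.4f  [%.4f, %.4f]\n",
                r$alpha, r$rate, r$ci_lower, r$ci_upper))
  cat(sprintf("  elapsed: %.1f s\n", x$elapsed))
  invisible(x)
}

#' Reference permutation null (plain R)
#'
#' Compute the permuted combined statistics for an explicit set of
#' family-level sign assignments, entirely in R. This mirrors the adaptive
#' engine's per-permutation computation with a fixed ordering of common
#' variants and fixed rare sets, and exists as an independently checkable
#' reference path; the adaptive engine is the production route.
#'
#' @param D families x variants score matrix.
#' @param lr per-variant normalised relative-risk scores (0 for non-common).
#' @param maf per-variant minor allele frequencies.
#' @param signs K x families matrix of +1/-1 sign assignments.
#' @param control an \code{\link{ovpdt_control}}.
#' @return List with \code{observed} (named: C, R_t, M_t) and \code{permuted}
#'   (K x T matrix of M_t), plus the fixed common ordering used.
#' @export
permutation_null <- function(D, lr, maf, signs, control = ovpdt_control()) {
  stopifnot(is.matrix(signs), ncol(signs) == nrow(D))
  cls <- classify_variants(maf, control$common_cut, control$thresholds)
  common <- cls$common
  os_obs <- ordered_subset_statistic(pdt_statistic(D[, common, drop = FALSE]),
                                     lr[common], pos = common,
                                     gate = control$gate)
  ord <- common[os_obs$order]
  eval_one <- function(X) {
    C <- 0; min_p <- 1
    if (length(ord)) {
      s <- cumsum(X[ord])
      p <- stats::pchisq(s, df = seq_along(s), lower.tail = FALSE)
      k <- which.min(p)
      min_p <- p[k]
      if (min_p <= control$gate) C <- s[k]
    }
    R_t <- vapply(cls$rare, function(ix) rare_statistic(X[ix]), 0)
    list(C = C, M_t = combined_statistic(R_t, C), R_t = R_t, min_p = min_p)
  }
  obs <- eval_one(pdt_statistic(D))
  permuted <- t(apply(signs, 1, function(s) eval_one(apply_sign_flips(D, s))$M_t))
  if (length(control$thresholds) == 1L) permuted <- t(permuted)
  colnames(permuted) <- names(cls$rare)
  list(observed = obs, permuted = permuted, order = ord)
}
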