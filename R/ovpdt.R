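# The OVPDT region statistic and its adaptive sign-flip permutation test.

#' Ordered-subset common-variant statistic
#'
#' Common variants are ranked by the absolute normalised relative-risk score
#' (largest first; ties take the larger PDT statistic, then the earlier
#' position; variants with \code{lr = 0} rank last). Prefix sums of the
#' ordered PDT statistics are scanned and each prefix of size i is assigned
#' the upper-tail probability of a chi-square with i degrees of freedom,
#' treating the i variants as independent. The common statistic C is the
#' prefix sum attaining the minimum p-value when that minimum is at most
#' 0.05, and 0 otherwise.
#'
#' @param X per-variant PDT statistics of the common variants.
#' @param lr matching normalised relative-risk scores.
#' @param pos optional position/order tie-breaker (defaults to input order).
#' @param gate significance gate for the minimum p-value (default 0.05).
#' @return List with \code{order} (indices into \code{X}), \code{prefix_sums},
#'   \code{p_values}, \code{min_p}, \code{subset_size} and \code{C}.
#' @export
ordered_subset_statistic <- function(X, lr, pos = seq_along(X), gate = 0.05) {
  stopifnot(length(X) == length(lr), all(X >= 0))
  if (length(X) == 0L)
    return(list(order = integer(0), prefix_sums = numeric(0),
                p_values = numeric(0), min_p = 1, subset_size = 0L, C = 0))
  ord <- order(-abs(lr), -X, pos)
  s <- cumsum(X[ord])
  p <- stats::pchisq(s, df = seq_along(s), lower.tail = FALSE)
  k <- which.min(p)  # first minimum: smallest subset on ties
  C <- if (p[k] <= gate) s[k] else 0
  list(order = ord, prefix_sums = s, p_values = p, min_p = p[k],
       subset_size = if (p[k] <= gate) k else 0L, C = C)
}

#' Variable-threshold rare-variant statistic
#'
#' Sum of the single-variant PDT statistics over the rare set at one MAF
#' threshold; 0 for an empty set.
#'
#' @param X PDT statistics of the variants with MAF below the threshold.
#' @return The burden statistic \eqn{R_t}.
#' @export
rare_statistic <- function(X) {
  if (length(X) == 0L) return(0)
  sum(X)
}

#' Combined common and rare statistic
#'
#' Equal-weight combination \eqn{M_t = R_t + C} at one rare-variant
#' threshold.
#'
#' @param R_t rare-variant statistic at threshold t.
#' @param C ordered-subset common-variant statistic.
#' @return The combined statistic.
#' @export
combined_statistic <- function(R_t, C) R_t + C

#' Standardise combined statistics and take the maximum
#'
#' Each threshold's combined statistic has its own null distribution, so the
#' observed and permuted values at a threshold are standardised by the mean
#' and standard deviation of that threshold's permuted statistics. The region
#' statistic M is the maximum standardised value over thresholds, and each
#' permutation is reduced the same way to give the permutation null of M.
#' A threshold whose permuted values are constant (zero SD) is uninformative
#' and standardises to 0.
#'
#' @param observed length-T vector of observed combined statistics.
#' @param permuted K x T matrix of permuted combined statistics.
#' @return List with \code{std_observed}, \code{M}, \code{perm_M},
#'   \code{means}, \code{sds}.
#' @export
standardize_and_maximize <- function(observed, permuted) {
  stopifnot(is.matrix(permuted), ncol(permuted) == length(observed),
            nrow(permuted) >= 2L)
  mu <- colMeans(permuted)
  sd <- apply(permuted, 2, stats::sd)
  z <- ifelse(sd > 0, (observed - mu) / sd, 0)
  zp <- sweep(permuted, 2, mu)
  zp <- sweep(zp, 2, ifelse(sd > 0, sd, Inf), "/")
  list(std_observed = z, M = max(z), perm_M = apply(zp, 1, max),
       means = mu, sds = sd)
}

#' Permutation settings for the OVPDT test
#'
#' The adaptive sign-flip permutation runs in batches; after each batch the
#' standardisation means/SDs are recomputed from all permutations so far and
#' exceedances are recounted over the full history. Permutation stops once at
#' least \code{target_exceedances} permuted statistics exceed the observed one
#' and at least \code{min_K} permutations have been run, or at \code{max_K}.
#' The defaults (36 exceedances, 2,000 minimum) bound the standard error of
#' small p-values near the significance threshold.
#'
#' @param min_K minimum number of permutations.
#' @param target_exceedances exceedance count that permits early stopping.
#' @param max_K hard cap on permutations.
#' @param batch batch size between stopping checks.
#' @param common_cut common-variant MAF cutoff.
#' @param thresholds rare-variant MAF thresholds.
#' @param gate significance gate for the ordered-subset minimum p-value.
#' @param lr_bootstrap bootstrap resamples for the variance of log r1.
#' @return A list of class \code{ovpdt_control}.
#' @export
ovpdt_control <- function(min_K = 2000L, target_exceedances = 36L,
                          max_K = 1e6L, batch = 1000L,
                          common_cut = 0.05,
                          thresholds = c(0.05, 0.03, 0.01, 0.005),
                          gate = 0.05, lr_bootstrap = 1000L) {
  stopifnot(min_K >= 1L, target_exceedances >= 1L, max_K >= min_K, batch >= 1L)
  structure(list(min_K = as.integer(min_K),
                 target_exceedances = as.integer(target_exceedances),
                 max_K = as.integer(max_K), batch = as.integer(batch),
                 common_cut = common_cut, thresholds = thresholds,
                 gate = gate, lr_bootstrap = as.integer(lr_bootstrap)),
            class = "ovpdt_control")
}

# Run the full test for one region given precomputed pieces. Internal; the
# user-facing entry is ovpdt().
ovpdt_region <- function(D, chrom, maf, lr, control, pos = seq_along(maf)) {
  cls <- classify_variants(maf, control$common_cut, control$thresholds)
  denom <- colSums(D^2)
  if (all(denom == 0)) {
    return(list(testable = FALSE, p_value = 1, K = 0L, exceedances = 0L,
                C = 0, min_p = 1, subset_size = 0L, M = NA_real_,
                R_t = rep(0, length(control$thresholds)),
                M_t = rep(0, length(control$thresholds)),
                std_M_t = rep(0, length(control$thresholds)),
                best_t = NA_real_, n_common = length(cls$common),
                n_rare = lengths(cls$rare)))
  }
  common <- cls$common
  ord <- if (length(common))
    common[ordered_subset_statistic(pdt_statistic(D[, common, drop = FALSE]),
                                    lr[common], pos = pos[common],
                                    gate = control$gate)$order]
  else integer(0)
  rare_sets <- lapply(cls$rare, function(ix) as.integer(ix - 1L))
  eng <- cpp_perm_engine(D, as.integer(match(chrom, unique(chrom)) - 1L),
                         length(unique(chrom)), as.integer(ord - 1L),
                         rare_sets, control$gate, control$min_K,
                         control$target_exceedances, control$max_K,
                         control$batch)
  c(eng, list(testable = TRUE, n_common = length(common),
              n_rare = lengths(cls$rare)))
}

#' Fit the OVPDT region association test
#'
#' The main entry point. For each region: estimate parental MAFs, split
#' variants into common (MAF > 0.05) and variable-threshold rare sets,
#' compute family-level PDT scores, estimate normalised relative-risk scores
#' for the common variants from parental mating types, and evaluate the
#' combined ordered-subset / variable-threshold statistic with an adaptive
#' sign-flip permutation p-value. Sign flips are drawn per family and per
#' chromosome and applied jointly to all variants on the chromosome, so LD
#' and linkage are preserved; the relative-risk scores depend on parental
#' genotypes only and are never recomputed under permutation.
#'
#' @param cohort an \code{ovpdt_cohort}.
#' @param regions named list of variant-id vectors (see
#'   \code{\link{read_regions}}); \code{NULL} tests all variants as one
#'   region.
#' @param control an \code{\link{ovpdt_control}}.
#' @param seed optional integer seed for the permutation and bootstrap RNG.
#' @return An object of class \code{ovpdt}: a list with \code{results} (one
#'   row per region) and \code{details} (per-region diagnostics).
#' @examples
#' sc <- ovpdt_scenario("Scen1", n_families = 60)
#' coh <- simulate_cohort(sc, seed = 7)
#' fit <- ovpdt(coh, control = ovpdt_control(min_K = 200, max_K = 2000),
#'              seed = 1)
#' fit
#' @export
ovpdt <- function(cohort, regions = NULL, control = ovpdt_control(),
                  seed = NULL) {
  stopifnot(inherits(cohort, "ovpdt_cohort"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(regions))
    regions <- list(all = cohort$variants$id)

  fs <- family_scores(cohort)
  maf_all <- cohort$variants$maf
  rows <- list()
  details <- list()
  for (rn in names(regions)) {
    ix <- match(regions[[rn]], cohort$variants$id)
    ix <- ix[!is.na(ix)]
    if (length(ix) == 0L) {
      warning("region ", rn, " has no variants in the cohort; skipped")
      next
    }
    maf <- maf_all[ix]
    D <- fs$D[, ix, drop = FALSE]
    cls <- classify_variants(maf, control$common_cut, control$thresholds)
    lr <- numeric(length(ix))
    lr_info <- NULL
    if (length(cls$common)) {
      lr_info <- variant_lr(cohort, ix[cls$common], B = control$lr_bootstrap)
      lr[cls$common] <- lr_info$lr
    }
    res <- ovpdt_region(D, cohort$variants$chrom[ix], maf, lr, control,
                        pos = cohort$variants$pos[ix])
    n_rare <- as.list(res$n_rare)
    names(n_rare) <- paste0("n_rare_", names(cls$rare))
    rows[[rn]] <- data.frame(
      region = rn, n_variants = length(ix), n_common = res$n_common,
      n_rare,
      C = res$C, min_p = res$min_p, subset_size = res$subset_size,
      best_t = if (res$testable) control$thresholds[res$best_t] else NA_real_,
      M = res$M, K = res$K, exceedances = res$exceedances,
      p_value = res$p_value, stringsAsFactors = FALSE)
    details[[rn]] <- list(variants = cohort$variants$id[ix], maf = maf,
                          X = pdt_statistic(D), lr = lr, lr_fit = lr_info,
                          engine = res)
  }
  if (length(rows) == 0L) stop("no testable region")
  out <- list(results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              details = details, control = control,
              n_families = length(cohort$families))
  class(out) <- "ovpdt"
  out
}

#' Write an OVPDT results table
#'
#' Tab-separated serialisation of the per-region results.
#'
#' @param fit an \code{ovpdt} object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "ovpdt"))
  utils::write.table(fit$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.ovpdt <- function(x, ...) {
  cat("OVPDT family-based association test\n")
  cat(" ", x$n_families, "families;", nrow(x$results), "region(s);",
      "thresholds:", paste(x$control$thresholds, collapse = ", "), "\n\n")
  df <- x$results[, c("region", "n_variants", "n_common", "C", "subset_size",
                      "best_t", "M", "K", "p_value")]
  df$C <- signif(df$C, 4); df$M <- signif(df$M, 4)
  df$p_value <- signif(df$p_value, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ovpdt <- function(object, ...) {
  res <- object$results
  cat("Regions tested:", nrow(res), "\n")
  cat("Smallest p-value:", format(min(res$p_value), digits = 4),
      "(", res$region[which.min(res$p_value)], ")\n")
  cat("Regions with p <= 0.05:", sum(res$p_value <= 0.05), "\n")
  invisible(object$results)
}

#' Plot method for OVPDT fits
#'
#' For a single region, shows the ordered-subset p-value profile across
#' prefix sizes; for several regions, a QQ plot of region p-values against
#' the uniform distribution.
#'
#' @param x an \code{ovpdt} object.
#' @param region region name (defaults to the first).
#' @param ... passed to the underlying plot call.
#' @export
plot.ovpdt <- function(x, region = NULL, ...) {
  if (nrow(x$results) > 1L && is.null(region)) {
    p <- sort(x$results$p_value)
    n <- length(p)
    graphics::plot(-log10(stats::ppoints(n)), -log10(p),
                   xlab = "-log10 expected", ylab = "-log10 observed",
                   main = "OVPDT region p-values", ...)
    graphics::abline(0, 1, lty = 2)
    return(invisible(x))
  }
  region <- region %||% x$results$region[1]
  d <- x$details[[region]]
  common <- which(d$maf > x$control$common_cut)
  if (length(common) == 0L) {
    graphics::plot.new()
    graphics::title(main = paste(region, ": no common variants"))
    return(invisible(x))
  }
  os <- ordered_subset_statistic(d$X[common], d$lr[common], pos = common,
                                 gate = x$control$gate)
  graphics::plot(seq_along(os$p_values), -log10(os$p_values), type = "b",
                 xlab = "ordered subset size", ylab = "-log10 p",
                 main = paste0(region, ": ordered-subset scan"), ...)
  graphics::abline(h = -log10(x$control$gate), lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
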