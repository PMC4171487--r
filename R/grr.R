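# Genotypic relative risks from parental mating types.
#
# Under Hardy-Weinberg equilibrium and ascertainment on at least one affected
# child, the probability of an (unordered) parental genotype pair is
# proportional to the HWE mating frequency times the mean penetrance of a
# child of that mating. Writing r1 = f1/f0 and r2 = f2/f0 for the genotypic
# relative risks, four combinations of these probabilities are free of the
# population allele frequency and depend only on (r1, r2); they are the basis
# for estimating r1 from parents alone.

# Cell order used throughout for mating-type counts/probabilities:
MATING_CELLS <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")

#' Mating-type probabilities conditional on an affected child
#'
#' Unnormalised probabilities of the six unordered parental genotype pairs
#' given an affected child, under HWE at minor allele frequency \code{q} and
#' genotypic relative risks \code{r1}, \code{r2}. Used by
#' \code{\link{grr_theoretical_ratios}} and as the building block of the
#' enumeration checks.
#'
#' @param q minor allele frequency.
#' @param r1,r2 genotypic relative risks f1/f0, f2/f0.
#' @return Named probability vector over the six mating types (normalised).
#' @export
mating_type_probs <- function(q, r1, r2) {
  p <- 1 - q
  # mean penetrance (in units of f0) of a child from each mating
  mean_pen <- c(1, (1 + r1) / 2, r1, (1 + 2 * r1 + r2) / 4, (r1 + r2) / 2, r2)
  hwe <- c(p^4, 4 * p^3 * q, 2 * p^2 * q^2, 4 * p^2 * q^2, 4 * p * q^3, q^4)
  mu <- hwe * mean_pen
  stats::setNames(mu / sum(mu), MATING_CELLS)
}

#' Allele-frequency-free mating-type ratios
#'
#' Four combinations of conditional mating-type probabilities that cancel the
#' population allele frequency and depend only on the genotypic relative
#' risks: \eqn{\rho_1 = \mu_{12}^2/(\mu_{11}\mu_{22})},
#' \eqn{\rho_2 = \mu_{02}^2/(\mu_{00}\mu_{22})},
#' \eqn{\rho_3 = \mu_{01}\mu_{12}/(\mu_{02}\mu_{11})} and
#' \eqn{\rho_4 = \mu_{01}\mu_{12}/(\mu_{00}\mu_{22})}. The space of such
#' frequency-free combinations is exactly four-dimensional and these four
#' span it. Every ratio involves a mating type with a homozygous-minor
#' parent, so none is estimable for low-frequency variants: at realistic
#' sample sizes estimation generally succeeds above MAF ~0.1 and generally
#' fails below MAF ~0.05, which restricts the relative-risk ordering to
#' common variants.
#'
#' @param r1,r2 genotypic relative risks (vectorised over \code{r1}).
#' @return A length-4 vector (or 4-row matrix) of ratio values.
#' @export
grr_theoretical_ratios <- function(r1, r2) {
  denom <- 1 + 2 * r1 + r2
  rbind(rho1 = 4 * (r1 + r2)^2 / (denom * r2),
        rho2 = 4 * r1^2 / r2,
        rho3 = 2 * (1 + r1) * (r1 + r2) / (r1 * denom),
        rho4 = 4 * (1 + r1) * (r1 + r2) / r2)[, , drop = TRUE]
}

#' Tally parental mating types
#'
#' Count, for one variant, the parental genotype pairs of families with at
#' least one affected child and both parents genotyped at the site.
#'
#' @param cohort an \code{ovpdt_cohort}.
#' @param variant variant index or id.
#' @return Named integer vector over the six unordered mating types.
#' @export
count_mating_types <- function(cohort, variant) {
  j <- if (is.character(variant)) match(variant, cohort$variants$id) else variant
  stopifnot(!is.na(j))
  counts <- stats::setNames(integer(6), MATING_CELLS)
  for (fam in cohort$families) {
    if (!any(fam$affected)) next
    if (is.na(fam$father) || is.na(fam$mother)) next
    f <- cohort$geno[fam$father, j]
    m <- cohort$geno[fam$mother, j]
    if (is.na(f) || is.na(m)) next
    cell <- paste(min(f, m), max(f, m), sep = "/")
    counts[cell] <- counts[cell] + 1L
  }
  counts
}

#' Observed mating-type ratios
#'
#' Empirical counterparts of \code{\link{grr_theoretical_ratios}} computed
#' from mating-type counts. A ratio is estimable only when all cells in its
#' numerator and denominator are positive.
#'
#' @param counts named 6-vector from \code{\link{count_mating_types}}.
#' @return List with \code{ratios} (length 4, \code{NA} when not estimable)
#'   and \code{estimable} (logical flags).
#' @export
grr_observed_ratios <- function(counts) {
  stopifnot(length(counts) == 6L)
  cells <- as.numeric(counts)  # scaling cancels: every ratio is balanced
  names(cells) <- MATING_CELLS
  num <- list(c("1/2", "1/2"), c("0/2", "0/2"), c("0/1", "1/2"), c("0/1", "1/2"))
  den <- list(c("1/1", "2/2"), c("0/0", "2/2"), c("0/2", "1/1"), c("0/0", "2/2"))
  ratios <- rep(NA_real_, 4L)
  estimable <- logical(4L)
  for (k in 1:4) {
    cn <- cells[num[[k]]]; cd <- cells[den[[k]]]
    if (all(cn > 0) && all(cd > 0)) {
      ratios[k] <- prod(cn) / prod(cd)
      estimable[k] <- TRUE
    }
  }
  names(ratios) <- names(estimable) <- c("rho1", "rho2", "rho3", "rho4")
  list(ratios = ratios, estimable = estimable)
}

#' Grid for the relative-risk search
#'
#' Multiplicative (log-scale) grid over the open interval (0.5, 20) for the
#' heterozygote relative risk r1, with the homozygote risk tied by the
#' additive-penetrance constraint \code{r2 = 2*r1 - 1} (so that
#' f1 = (f0 + f2)/2). The lower end is clipped so r2 stays positive.
#'
#' @param step log-scale step size.
#' @return List with \code{r1}, \code{r2} and the 4 x G matrix of theoretical
#'   ratios at each grid point.
#' @export
grr_grid <- function(step = 0.005) {
  r1 <- exp(seq(log(0.5) + step, log(20) - 1e-9, by = step))
  r2 <- 2 * r1 - 1
  list(r1 = r1, r2 = r2, ratios = grr_theoretical_ratios(r1, r2))
}

# cached default grid (deterministic, cheap to build once per session)
grid_cache <- new.env(parent = emptyenv())
default_grid <- function() {
  if (is.null(grid_cache$g)) grid_cache$g <- grr_grid()
  grid_cache$g
}

#' Fit genotypic relative risks to mating-type counts
#'
#' Heuristic search for r1 over a log-scale grid on (0.5, 20) under the
#' additive constraint r2 = 2*r1 - 1. The fitted value minimises the sum of
#' Euclidean (absolute) distances between the theoretical and the estimable
#' observed ratios; unestimable ratios are excluded from the sum. Ties take
#' the smallest r1. With no estimable ratio the fit is flagged absent.
#'
#' @param counts named 6-vector of mating-type counts.
#' @param grid search grid from \code{\link{grr_grid}}.
#' @return List with \code{r1}, \code{r2}, \code{n_estimable},
#'   \code{estimable} flags and \code{ok}.
#' @export
fit_grr <- function(counts, grid = default_grid()) {
  obs <- grr_observed_ratios(counts)
  est <- obs$estimable
  if (!any(est))
    return(list(r1 = NA_real_, r2 = NA_real_, n_estimable = 0L,
                estimable = est, ok = FALSE))
  th <- grid$ratios[est, , drop = FALSE]
  dist <- colSums(abs(th - obs$ratios[est]))
  k <- which.min(dist)  # which.min takes the first (smallest r1) on ties
  list(r1 = grid$r1[k], r2 = grid$r2[k], n_estimable = sum(est),
       estimable = est, ok = TRUE)
}

#' Bootstrap variance of log r1
#'
#' Resample the mating-type counts (multinomial over the six cells, same
#' total) \code{B} times, refit r1 on each resample, and return the sample
#' variance of log r1 over resamples in which a fit exists. Fewer than 10
#' successful resamples make the variance unreliable and return \code{NA}
#' (the normalised score is then 0). Deterministic given the RNG seed.
#'
#' @param counts named 6-vector of mating-type counts.
#' @param B number of resamples (default 1000).
#' @param grid search grid from \code{\link{grr_grid}}.
#' @return Variance of log r1 across successful resamples, or \code{NA}.
#' @export
bootstrap_var_log_r1 <- function(counts, B = 1000L, grid = default_grid()) {
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  cpp_grr_bootstrap(as.numeric(counts), as.integer(B), grid$r1, grid$ratios)
}

#' Normalised log relative risk
#'
#' The ordering score for a common variant: \code{lr = log(r1) /
#' sqrt(var_log_r1)}. Risk alleles score positive, protective alleles
#' negative; ordering uses the absolute value. Missing or zero variance, or an
#' absent fit, gives \code{lr = 0}, which ranks the variant last.
#'
#' @param r1 fitted heterozygote relative risk.
#' @param var_log_r1 bootstrap variance of log r1.
#' @return The normalised score (0 when not estimable).
#' @export
normalized_lr <- function(r1, var_log_r1) {
  if (is.na(r1) || is.na(var_log_r1) || var_log_r1 <= 0) return(0)
  log(r1) / sqrt(var_log_r1)
}

# Vectorised mating-type tally for many variants at once: 6 x V matrix.
# Families with >= 1 affected child and both parents genotyped at the site.
mating_counts_matrix <- function(cohort, variants) {
  qual <- Filter(function(f) any(f$affected) && !is.na(f$father) &&
                   !is.na(f$mother), cohort$families)
  fa <- vapply(qual, `[[`, 0L, "father")
  mo <- vapply(qual, `[[`, 0L, "mother")
  f <- cohort$geno[fa, variants, drop = FALSE]
  m <- cohort$geno[mo, variants, drop = FALSE]
  lo <- pmin(f, m)
  hi <- pmax(f, m)
  cell <- match(lo * 10L + hi, c(0L, 1L, 2L, 11L, 12L, 22L))
  colv <- rep(seq_along(variants), each = nrow(f))
  ok <- !is.na(cell)
  counts <- matrix(tabulate(cell[ok] + 6L * (colv[ok] - 1L),
                            nbins = 6L * length(variants)),
                   nrow = 6L)
  rownames(counts) <- MATING_CELLS
  counts
}

#' Ordering scores for the common variants of a cohort
#'
#' For each requested variant: tally parental mating types, fit the genotypic
#' relative risks, bootstrap the variance of log r1 and form the normalised
#' score lr. The computation uses parental genotypes only, so the scores are
#' invariant under transmitted/non-transmitted permutations and are computed
#' once per region.
#'
#' @param cohort an \code{ovpdt_cohort}.
#' @param variants indices of the variants to score (typically the common
#'   set).
#' @param B bootstrap resamples per variant.
#' @return data.frame with \code{r1}, \code{r2}, \code{var_log_r1}, \code{lr}
#'   and \code{n_estimable} per variant.
#' @export
variant_lr <- function(cohort, variants, B = 1000L) {
  if (length(variants) == 0L)
    return(data.frame(r1 = numeric(0), r2 = numeric(0),
                      var_log_r1 = numeric(0), lr = numeric(0),
                      n_estimable = integer(0)))
  counts <- mating_counts_matrix(cohort, variants)
  storage.mode(counts) <- "double"
  grid <- default_grid()
  res <- cpp_grr_lr(counts, as.integer(B), grid$r1, grid$ratios)
  out <- as.data.frame(res)
  rownames(out) <- cohort$variants$id[variants]
  out
}
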