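# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-derivations (enumeration, brute force) kept separate
# from the package's own code paths.

# Enumeration oracle for parental mating-type probabilities conditional on an
# affected child: per-parent transmitted-allele enumeration under HWE at
# minor allele frequency q with penetrances (f0, f0*r1, f0*r2).
oracle_mating_probs <- function(q, r1, r2) {
  p <- 1 - q
  gf <- c(p^2, 2 * p * q, q^2)
  pen <- c(1, r1, r2)
  transmit <- function(g) switch(g + 1, c(1, 0), c(0.5, 0.5), c(0, 1))
  mu <- stats::setNames(numeric(6), c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2"))
  for (i in 0:2) for (j in i:2) {
    ta <- transmit(i); tb <- transmit(j)
    child <- c(ta[1] * tb[1], ta[1] * tb[2] + ta[2] * tb[1], ta[2] * tb[2])
    w <- (if (i == j) 1 else 2) * gf[i + 1] * gf[j + 1]
    mu[paste(i, j, sep = "/")] <- w * sum(child * pen)
  }
  mu / sum(mu)
}

# ratio combinations recomputed directly from the oracle probabilities
oracle_ratios <- function(q, r1, r2) {
  mu <- oracle_mating_probs(q, r1, r2)
  c(mu[["1/2"]]^2 / (mu[["1/1"]] * mu[["2/2"]]),
    mu[["0/2"]]^2 / (mu[["0/0"]] * mu[["2/2"]]),
    mu[["0/1"]] * mu[["1/2"]] / (mu[["0/2"]] * mu[["1/1"]]),
    mu[["0/1"]] * mu[["1/2"]] / (mu[["0/0"]] * mu[["2/2"]]))
}

# Brute-force transmission permutation for a trio cohort: swapping the
# transmitted and non-transmitted parental alleles replaces each child
# genotype by (father + mother - child); the triad score is recomputed from
# scratch on the re-permuted genotypes.
oracle_flip_trios <- function(fa, mo, ch, flip) {
  ch2 <- ifelse(flip, fa + mo - ch, ch)
  D <- 2 * ch2 - fa - mo
  den <- sum(D^2)
  if (den == 0) 0 else sum(D)^2 / den
}

# Minimal trio cohort from parallel dosage matrices (families x variants).
make_trio_cohort <- function(fa, mo, ch, pos = NULL, validate = TRUE) {
  stopifnot(identical(dim(fa), dim(mo)), identical(dim(fa), dim(ch)))
  nf <- nrow(fa); nv <- ncol(fa)
  geno <- matrix(NA_integer_, 3 * nf, nv)
  geno[seq(1, 3 * nf, 3), ] <- as.integer(fa)
  geno[seq(2, 3 * nf, 3), ] <- as.integer(mo)
  geno[seq(3, 3 * nf, 3), ] <- as.integer(ch)
  rownames(geno) <- paste0("i", seq_len(3 * nf))
  fams <- lapply(seq_len(nf), function(i)
    list(fid = sprintf("F%03d", i), father = 3L * i - 2L, mother = 3L * i - 1L,
         children = 3L * i, affected = TRUE))
  variants <- data.frame(id = sprintf("v%03d", seq_len(nv)), chrom = "1",
                         pos = if (is.null(pos)) seq_len(nv) * 10L else pos,
                         stringsAsFactors = FALSE)
  new_cohort(geno, variants, fams, validate = validate)
}

# Random Mendelian trio genotypes at HWE frequency q (no ascertainment).
random_trios <- function(nf, nv, q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fa <- matrix(rbinom(nf * nv, 2, q), nf, nv)
  mo <- matrix(rbinom(nf * nv, 2, q), nf, nv)
  tf <- matrix(rbinom(nf * nv, 1, 0.5), nf, nv)
  tm <- matrix(rbinom(nf * nv, 1, 0.5), nf, nv)
  ch <- ((fa == 2) + (fa == 1) * tf) + ((mo == 2) + (mo == 1) * tm)
  list(fa = fa, mo = mo, ch = ch)
}

# brute-force ordered-subset evaluation: explicit loop over every prefix
oracle_ordered_subset <- function(X, lr, pos = seq_along(X), gate = 0.05) {
  ord <- order(-abs(lr), -X, pos)
  best_p <- 1; best_s <- 0; best_k <- 0
  s <- 0
  for (i in seq_along(ord)) {
    s <- s + X[ord[i]]
    p <- pchisq(s, df = i, lower.tail = FALSE)
    if (p < best_p) { best_p <- p; best_s <- s; best_k <- i }
  }
  list(min_p = best_p, C = if (best_p <= gate) best_s else 0,
       subset_size = if (best_p <= gate) best_k else 0)
}
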