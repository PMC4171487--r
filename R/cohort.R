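#' Construct a nuclear-family cohort
#'
#' Assemble genotypes and pedigree structure into the container used by all
#' analysis functions. Genotypes are stored as minor-allele dosage, where the
#' minor allele is the less frequent allele among the parents; sites that are
#' monomorphic in the parents are dropped. Mendelian-inconsistent sites are
#' zeroed (set missing) for the offending family and the minor allele
#' frequency is re-estimated from the remaining parental genotypes.
#'
#' @param geno integer matrix, individuals x variants, allele dosage in
#'   \code{0:2} (\code{NA} = missing). Row names identify individuals.
#' @param variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   and optionally \code{minor}, \code{major} allele labels.
#' @param families list; each element a list with \code{fid}, \code{father},
#'   \code{mother} (row indices into \code{geno}, or \code{NA}),
#'   \code{children} (row indices) and \code{affected} (logical, one per
#'   child).
#' @param validate run Mendelian-consistency checks (default \code{TRUE};
#'   internally generated cohorts skip them).
#' @return An object of class \code{ovpdt_cohort}.
#' @export
new_cohort <- function(geno, variants, families, validate = TRUE) {
  stopifnot(is.matrix(geno), nrow(variants) == ncol(geno))
  for (fam in families) {
    if (length(fam$children) < 1L)
      stop("family ", fam$fid, " has no children")
    if (length(fam$affected) != length(fam$children))
      stop("family ", fam$fid, ": affected flags do not match children")
  }
  ori1 <- orient_minor(geno, families)
  geno <- ori1$geno

  n_mendel <- 0L
  if (validate) {
    for (fam in families) {
      if (is.na(fam$father) || is.na(fam$mother)) next
      f <- geno[fam$father, ]
      m <- geno[fam$mother, ]
      cmin <- (f == 2L) + (m == 2L)
      cmax <- (f >= 1L) + (m >= 1L)
      bad <- rep(FALSE, ncol(geno))
      for (ch in fam$children) {
        cg <- geno[ch, ]
        bad <- bad | (!is.na(cg) & !is.na(cmin) & (cg < cmin | cg > cmax))
      }
      if (any(bad)) {
        n_mendel <- n_mendel + sum(bad)
        rows <- c(fam$father, fam$mother, fam$children)
        geno[rows, bad] <- NA_integer_
      }
    }
    if (n_mendel > 0L)
      warning(n_mendel, " Mendelian-inconsistent family-site pairs zeroed")
  }

  ori <- orient_minor(geno, families)
  geno <- ori$geno
  variants$maf <- ori$maf
  net_flip <- xor(ori1$flipped, ori$flipped)
  if (!is.null(variants$minor) && any(net_flip)) {
    tmp <- variants$minor[net_flip]
    variants$minor[net_flip] <- variants$major[net_flip]
    variants$major[net_flip] <- tmp
  }

  keep <- which(!is.na(variants$maf) & variants$maf > 0)
  # canonical variant order: results do not depend on the input file order
  keep <- keep[order(variants$chrom[keep], variants$pos[keep])]
  geno <- geno[, keep, drop = FALSE]
  variants <- variants[keep, , drop = FALSE]
  rownames(variants) <- NULL

  structure(list(geno = geno, variants = variants, families = families,
                 n_mendel_zeroed = n_mendel),
            class = "ovpdt_cohort")
}

# Recode dosages so the coded allele is the parental minor allele; returns the
# (possibly flipped) matrix, the parental MAF per variant, and flip flags.
orient_minor <- function(geno, families) {
  pidx <- parent_rows(families)
  pg <- geno[pidx, , drop = FALSE]
  n_ok <- colSums(!is.na(pg))
  freq <- ifelse(n_ok > 0, colSums(pg, na.rm = TRUE) / (2 * n_ok), NA_real_)
  flipped <- !is.na(freq) & freq > 0.5
  if (any(flipped)) {
    geno[, flipped] <- 2L - geno[, flipped]
    freq[flipped] <- 1 - freq[flipped]
  }
  list(geno = geno, maf = freq, flipped = flipped)
}

parent_rows <- function(families) {
  idx <- unlist(lapply(families, function(f) c(f$father, f$mother)))
  unique(idx[!is.na(idx)])
}

#' Parental minor allele frequencies
#'
#' Estimate the minor allele frequency of every variant from the parental
#' genotypes only: minor-allele count among non-missing parents divided by
#' twice the number of non-missing parents. Each parent is counted once.
#'
#' @param cohort an \code{ovpdt_cohort}.
#' @return Numeric vector of frequencies in \code{[0, 0.5]} (\code{NA} when no
#'   parent is genotyped).
#' @export
estimate_maf <- function(cohort) {
  stopifnot(inherits(cohort, "ovpdt_cohort"))
  orient_minor(cohort$geno, cohort$families)$maf
}

#' Partition variants into common and rare sets
#'
#' Common variants have MAF strictly above \code{common_cut}; the rare set at
#' threshold \code{t} holds variants with MAF strictly below \code{t}.
#' Variants with MAF exactly at \code{common_cut} belong to neither set (the
#' inequalities are strict on both sides).
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param common_cut common-variant cutoff (default 0.05).
#' @param thresholds variable rare-variant thresholds, descending.
#' @return List with \code{common} (indices) and \code{rare} (list of index
#'   vectors, one per threshold, named by threshold).
#' @export
classify_variants <- function(maf, common_cut = 0.05,
                              thresholds = c(0.05, 0.03, 0.01, 0.005)) {
  common <- which(!is.na(maf) & maf > common_cut)
  rare <- lapply(thresholds, function(t) which(!is.na(maf) & maf < t))
  names(rare) <- as.character(thresholds)
  list(common = common, rare = rare, thresholds = thresholds)
}

#' @export
print.ovpdt_cohort <- function(x, ...) {
  nk <- vapply(x$families, function(f) length(f$children), 0L)
  cat("Nuclear-family cohort:", length(x$families), "families,",
      nrow(x$variants), "variants\n")
  cat("  children per family:", paste(range(nk), collapse = "-"),
      "| affected:", sum(vapply(x$families, function(f) sum(f$affected), 0L)),
      "\n")
  cat("  parental MAF range:",
      paste(signif(range(x$variants$maf), 3), collapse = " - "), "\n")
  invisible(x)
}

#' @export
summary.ovpdt_cohort <- function(object, ...) {
  cls <- classify_variants(object$variants$maf)
  out <- list(
    n_families = length(object$families),
    n_variants = nrow(object$variants),
    n_common = length(cls$common),
    n_rare = vapply(cls$rare, length, 0L),
    maf = summary(object$variants$maf)
  )
  class(out) <- "summary.ovpdt_cohort"
  out
}

#' @export
print.summary.ovpdt_cohort <- function(x, ...) {
  cat("Families:", x$n_families, " Variants:", x$n_variants, "\n")
  cat("Common (MAF > 0.05):", x$n_common, "\n")
  cat("Rare per threshold:",
      paste(names(x$n_rare), x$n_rare, sep = "=", collapse = ", "), "\n")
  print(x$maf)
  invisible(x)
}
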