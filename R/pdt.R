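#' Triad transmission score
#'
#' Score a parent-parent-affected-child triad at a biallelic site as the number
#' of minor alleles transmitted by the two parents minus the number not
#' transmitted. With genotypes coded as minor-allele dosage the score has the
#' closed form \code{2*child - father - mother}, which equals the
#' transmitted-minus-untransmitted count for every Mendelian-consistent,
#' phase-unresolved configuration (both parents together transmit
#' \code{child} minor alleles and retain \code{father + mother - child}).
#'
#' @param father,mother,child minor-allele dosages in \code{0:2} (vectorised).
#' @return Integer score(s) in \code{-2:2}; \code{NA} propagates.
#' @examples
#' triad_score(1, 0, 1)  # +1: het father transmitted the minor allele
#' triad_score(1, 1, 2)  # +2
#' @export
triad_score <- function(father, mother, child) {
  2L * as.integer(child) - as.integer(father) - as.integer(mother)
}

#' Discordant sib pair score
#'
#' Difference in minor-allele dosage between an affected and an unaffected
#' sibling.
#'
#' @param affected,unaffected minor-allele dosages in \code{0:2} (vectorised).
#' @return Integer score(s) in \code{-2:2}.
#' @export
sibpair_score <- function(affected, unaffected) {
  as.integer(affected) - as.integer(unaffected)
}

# Score one family at all variants. geno: individuals x variants dosage matrix.
# Returns the per-variant average D_i over informative units, together with
# unit counts. A triad is informative when at least one parent is heterozygous
# and all three genotypes are present; a sibship contributes its affected x
# unaffected cross pairs only when at least one such pair is discordant.
score_family <- function(geno, family) {
  nv <- ncol(geno)
  num <- numeric(nv)
  n_units <- numeric(nv)

  has_parents <- !is.na(family$father) && !is.na(family$mother)
  aff <- family$children[family$affected]
  unaff <- family$children[!family$affected]

  if (has_parents && length(aff)) {
    f <- geno[family$father, ]
    m <- geno[family$mother, ]
    par_het <- !is.na(f) & !is.na(m) & (f == 1L | m == 1L)
    for (ch in aff) {
      c_g <- geno[ch, ]
      ok <- par_het & !is.na(c_g)
      tt <- 2L * c_g - f - m
      num[ok] <- num[ok] + tt[ok]
      n_units[ok] <- n_units[ok] + 1
    }
  }

  if (length(aff) && length(unaff)) {
    # sibship informativeness per variant: some affected/unaffected pair differs
    s_num <- numeric(nv)
    n_pairs <- numeric(nv)
    discordant <- logical(nv)
    for (a in aff) {
      a_g <- geno[a, ]
      for (u in unaff) {
        u_g <- geno[u, ]
        ok <- !is.na(a_g) & !is.na(u_g)
        s_num[ok] <- s_num[ok] + (a_g[ok] - u_g[ok])
        n_pairs[ok] <- n_pairs[ok] + 1
        discordant <- discordant | (ok & a_g != u_g)
      }
    }
    num[discordant] <- num[discordant] + s_num[discordant]
    n_units[discordant] <- n_units[discordant] + n_pairs[discordant]
  }

  D <- ifelse(n_units > 0, num / pmax(n_units, 1), 0)
  list(D = D, n_units = n_units)
}

#' Family-level PDT scores
#'
#' Compute the matrix of per-family, per-variant PDT scores \eqn{D_i}: the
#' average of triad transmission scores and discordant-sib-pair scores over the
#' informative units of each nuclear family. Families with no informative unit
#' at a variant score 0 there. Cohorts in which every family has both parents,
#' the same number of children with the same affection pattern and no missing
#' genotypes (the simulator's output) go through a matrix fast path that the
#' tests pin against the generic per-family route.
#'
#' @param cohort an \code{ovpdt_cohort}.
#' @return A list with \code{D} (families x variants numeric matrix) and
#'   \code{n_units} (matrix of informative unit counts).
#' @export
family_scores <- function(cohort) {
  stopifnot(inherits(cohort, "ovpdt_cohort"))
  nf <- length(cohort$families)
  nv <- nrow(cohort$variants)
  out <- family_scores_uniform(cohort)
  if (!is.null(out)) return(out)
  D <- matrix(0, nf, nv)
  n_units <- matrix(0, nf, nv)
  for (i in seq_len(nf)) {
    sc <- score_family(cohort$geno, cohort$families[[i]])
    D[i, ] <- sc$D
    n_units[i, ] <- sc$n_units
  }
  rownames(D) <- vapply(cohort$families, `[[`, "", "fid")
  colnames(D) <- cohort$variants$id
  list(D = D, n_units = n_units)
}

# Matrix fast path for complete, uniform-structure cohorts; NULL when the
# cohort does not qualify.
family_scores_uniform <- function(cohort) {
  fams <- cohort$families
  if (anyNA(cohort$geno)) return(NULL)
  nk <- lengths(lapply(fams, `[[`, "children"))
  if (length(unique(nk)) != 1L) return(NULL)
  if (any(vapply(fams, function(f) is.na(f$father) || is.na(f$mother), TRUE)))
    return(NULL)
  pat <- vapply(fams, function(f) paste(as.integer(f$affected), collapse = ""),
                "")
  if (length(unique(pat)) != 1L) return(NULL)
  affected <- fams[[1]]$affected

  g <- cohort$geno
  Fm <- g[vapply(fams, `[[`, 0L, "father"), , drop = FALSE]
  Mm <- g[vapply(fams, `[[`, 0L, "mother"), , drop = FALSE]
  kid <- lapply(seq_len(nk[1]), function(k)
    g[vapply(fams, function(f) f$children[k], 0L), , drop = FALSE])
  aff <- which(affected)
  unaff <- which(!affected)

  par_het <- (Fm == 1L) + (Mm == 1L) > 0
  t_sum <- matrix(0, nrow(Fm), ncol(Fm))
  for (k in aff) t_sum <- t_sum + (2L * kid[[k]] - Fm - Mm)
  t_sum <- t_sum * par_het
  n_T <- length(aff) * par_het

  s_sum <- matrix(0, nrow(Fm), ncol(Fm))
  disc <- matrix(FALSE, nrow(Fm), ncol(Fm))
  if (length(aff) && length(unaff)) {
    for (a in aff) for (u in unaff) {
      s_sum <- s_sum + (kid[[a]] - kid[[u]])
      disc <- disc | (kid[[a]] != kid[[u]])
    }
  }
  s_sum <- s_sum * disc
  n_S <- (length(aff) * length(unaff)) * disc

  n_units <- n_T + n_S
  D <- ifelse(n_units > 0, (t_sum + s_sum) / pmax(n_units, 1), 0)
  rownames(D) <- vapply(fams, `[[`, "", "fid")
  colnames(D) <- cohort$variants$id
  list(D = D, n_units = n_units)
}

#' Single-variant PDT statistic
#'
#' The PDT chi-square statistic \eqn{X = (\sum_i D_i)^2 / \sum_i D_i^2} over
#' families, which follows a 1-df chi-square distribution under the null of no
#' linkage or no association. Degenerate denominators (no informative family)
#' give \code{X = 0} by convention. The statistic is unchanged when the minor
#' allele is relabelled from risk to protective.
#'
#' @param D numeric vector of per-family scores, or a families x variants
#'   matrix (one statistic per column).
#' @return Nonnegative statistic(s).
#' @export
pdt_statistic <- function(D) {
  if (is.matrix(D)) {
    num <- colSums(D)^2
    den <- colSums(D^2)
    ifelse(den > 0, num / den, 0)
  } else {
    den <- sum(D^2)
    if (den > 0) sum(D)^2 / den else 0
  }
}

#' Sign-flipped PDT statistics
#'
#' Recompute per-variant PDT statistics after flipping the sign of each
#' family's score, the effect of permuting transmitted and non-transmitted
#' parental alleles within that family. Denominators are sign-invariant, so
#' only the numerator changes.
#'
#' @param D families x variants score matrix.
#' @param signs per-family vector of \code{+1}/\code{-1}.
#' @return Per-variant statistics under the flipped configuration.
#' @export
apply_sign_flips <- function(D, signs) {
  stopifnot(length(signs) == nrow(D), all(signs %in% c(-1, 1)))
  num <- as.vector(crossprod(signs, D))^2
  den <- colSums(D^2)
  ifelse(den > 0, num / den, 0)
}
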