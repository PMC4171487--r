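# Readers and writers: linkage PED/MAP, VCF + FAM, region set files.

# Build the family list from a 6-column pedigree table. Children are grouped
# into nuclear families by (family id, father id, mother id); a parent id of
# "0" or a parent absent from the genotype table leaves that slot NA, and such
# children are excluded from triad scoring downstream. Phenotype coding is
# 2 = affected, 1 = unaffected; anything else drops the child.
build_families <- function(ped, ids) {
  rowof <- stats::setNames(seq_along(ids), ids)
  is_child <- ped$father != "0" | ped$mother != "0"
  kids <- ped[is_child & ped$pheno %in% c(1, 2), , drop = FALSE]
  if (nrow(kids) == 0L) stop("pedigree contains no phenotyped children")
  key <- paste(kids$fid, kids$father, kids$mother, sep = "\r")
  families <- lapply(split(seq_len(nrow(kids)), key), function(i) {
    k <- kids[i, , drop = FALSE]
    fa <- rowof[as.character(k$father[1])]
    mo <- rowof[as.character(k$mother[1])]
    list(fid = as.character(k$fid[1]),
         father = if (is.na(fa)) NA_integer_ else unname(fa),
         mother = if (is.na(mo)) NA_integer_ else unname(mo),
         children = unname(rowof[as.character(k$iid)]),
         affected = k$pheno == 2)
  })
  unname(families[order(vapply(families, `[[`, "", "fid"))])
}

#' Read a cohort from linkage PED/MAP or VCF + FAM files
#'
#' Two input layouts are supported: a linkage-format pedigree file with two
#' allele columns per marker plus a MAP file, or a VCF of genotypes plus a
#' 6-column FAM/PED pedigree. Multi-allelic sites and sites monomorphic in the
#' parents are excluded; the minor allele is the less frequent parental
#' allele. Children without two genotyped parents stay in the cohort but are
#' non-informative for triad scoring.
#'
#' @param ped path to a linkage PED file (with \code{map}), or a 6-column
#'   FAM/PED pedigree (with \code{vcf}).
#' @param map path to the MAP file (linkage layout).
#' @param vcf path to an uncompressed or bgzipped VCF (VCF layout).
#' @return An \code{ovpdt_cohort}.
#' @export
read_cohort <- function(ped, map = NULL, vcf = NULL) {
  if (!is.null(vcf)) read_vcf_cohort(vcf, ped) else read_ped_cohort(ped, map)
}

read_ped_cohort <- function(ped, map) {
  if (is.null(map)) stop("linkage input needs both 'ped' and 'map' files")
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("malformed MAP file: expected 4 columns")
  variants <- data.frame(id = as.character(mp[[2]]), chrom = as.character(mp[[1]]),
                         pos = as.integer(mp[[4]]), stringsAsFactors = FALSE)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(variants)
  bad <- which(lengths(toks) != want)
  if (length(bad))
    stop("malformed PED file: line ", bad[1], " has ", lengths(toks)[bad[1]],
         " fields, expected ", want)
  tab <- do.call(rbind, toks)
  pedinfo <- data.frame(fid = tab[, 1], iid = tab[, 2], father = tab[, 3],
                        mother = tab[, 4], sex = tab[, 5],
                        pheno = suppressWarnings(as.numeric(tab[, 6])),
                        stringsAsFactors = FALSE)
  al <- tab[, -(1:6), drop = FALSE]
  a1 <- al[, seq(1, ncol(al), by = 2), drop = FALSE]
  a2 <- al[, seq(2, ncol(al), by = 2), drop = FALSE]
  nv <- nrow(variants)
  geno <- matrix(NA_integer_, nrow(tab), nv)
  keep <- rep(TRUE, nv)
  minor <- major <- character(nv)
  for (j in seq_len(nv)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L) { keep[j] <- FALSE; next }
    if (length(alleles) == 0L) { keep[j] <- FALSE; next }
    ref <- alleles[1]
    g <- (a1[, j] == ref) + (a2[, j] == ref)
    g[a1[, j] == "0" | a2[, j] == "0"] <- NA_integer_
    geno[, j] <- as.integer(g)
    minor[j] <- ref
    major[j] <- if (length(alleles) == 2L) alleles[2] else ref
  }
  variants$minor <- minor
  variants$major <- major
  ids <- pedinfo$iid
  rownames(geno) <- ids
  fams <- build_families(pedinfo, ids)
  new_cohort(geno[, keep, drop = FALSE], variants[keep, , drop = FALSE], fams)
}

read_vcf_cohort <- function(vcf, fam) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  variants <- data.frame(id = fix[keep, "ID"], chrom = fix[keep, "CHROM"],
                         pos = as.integer(fix[keep, "POS"]),
                         minor = fix[keep, "ALT"], major = fix[keep, "REF"],
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  dos <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L, "1/0" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  geno <- t(matrix(dos[gt], nrow(gt), ncol(gt)))
  rownames(geno) <- samples
  fm <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fm) < 6L) stop("malformed FAM file: expected 6 columns")
  pedinfo <- data.frame(fid = as.character(fm[[1]]), iid = as.character(fm[[2]]),
                        father = as.character(fm[[3]]), mother = as.character(fm[[4]]),
                        sex = fm[[5]], pheno = suppressWarnings(as.numeric(fm[[6]])),
                        stringsAsFactors = FALSE)
  missing_ids <- setdiff(pedinfo$iid, samples)
  pedinfo <- pedinfo[pedinfo$iid %in% samples, , drop = FALSE]
  geno <- geno[pedinfo$iid, , drop = FALSE]
  fams <- build_families(pedinfo, pedinfo$iid)
  new_cohort(geno, variants, fams)
}

#' Read a region definition file
#'
#' Each line maps a region name to either a variant id
#' (\code{region<TAB>variant_id}, one pair per line, setID style) or a 1-based
#' inclusive interval (\code{region<TAB>chrom:start-end}) resolved against the
#' cohort.
#'
#' @param path set file path.
#' @param cohort an \code{ovpdt_cohort} used to resolve ids and intervals.
#' @return Named list of variant-id character vectors; regions whose entries
#'   match nothing are dropped with a warning.
#' @export
read_regions <- function(path, cohort) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) stop("malformed set file: line ", bad[1])
  nm <- vapply(toks, `[`, "", 1L)
  val <- vapply(toks, `[`, "", 2L)
  v <- cohort$variants
  out <- lapply(split(val, nm), function(entries) {
    ids <- character(0)
    for (e in entries) {
      if (grepl("^[^:]+:[0-9]+-[0-9]+$", e)) {
        ch <- sub(":.*", "", e)
        rng <- as.integer(strsplit(sub(".*:", "", e), "-")[[1]])
        ids <- c(ids, v$id[v$chrom == ch & v$pos >= rng[1] & v$pos <= rng[2]])
      } else if (e %in% v$id) {
        ids <- c(ids, e)
      }
    }
    unique(ids)
  })
  empty <- lengths(out) == 0L
  if (any(empty)) {
    warning("regions with no matching variants skipped: ",
            paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  if (length(out) == 0L) stop("no region resolved against the cohort")
  out
}

#' Write a cohort as VCF + FAM
#'
#' Serialise a cohort to an uncompressed VCF (genotypes as unphased GT) and a
#' 6-column FAM pedigree, the layout \code{\link{read_cohort}} accepts.
#'
#' @param cohort an \code{ovpdt_cohort}.
#' @param vcf,fam output paths.
#' @return Invisibly, the VCF path.
#' @export
write_cohort_vcf <- function(cohort, vcf, fam) {
  v <- cohort$variants
  ids <- rownames(cohort$geno)
  gt <- c("0/0", "0/1", "1/1")
  gmat <- matrix("./.", nrow(cohort$geno), ncol(cohort$geno))
  ok <- !is.na(cohort$geno)
  gmat[ok] <- gt[cohort$geno[ok] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  major <- if (is.null(v$major)) rep("A", nrow(v)) else v$major
  minor <- if (is.null(v$minor)) rep("T", nrow(v)) else v$minor
  body <- paste(v$chrom, v$pos, v$id, major, minor, ".", "PASS", ".", "GT",
                apply(gmat, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf)

  rows <- list()
  for (f in cohort$families) {
    fa_id <- if (is.na(f$father)) "0" else ids[f$father]
    mo_id <- if (is.na(f$mother)) "0" else ids[f$mother]
    if (!is.na(f$father))
      rows[[length(rows) + 1L]] <- c(f$fid, fa_id, "0", "0", "1", "1")
    if (!is.na(f$mother))
      rows[[length(rows) + 1L]] <- c(f$fid, mo_id, "0", "0", "2", "1")
    for (k in seq_along(f$children))
      rows[[length(rows) + 1L]] <- c(f$fid, ids[f$children[k]], fa_id, mo_id,
                                     "0", if (f$affected[k]) "2" else "1")
  }
  tab <- do.call(rbind, rows)
  tab <- tab[!duplicated(tab[, 2]), , drop = FALSE]
  writeLines(apply(tab, 1, paste, collapse = "\t"), fam)
  invisible(vcf)
}
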