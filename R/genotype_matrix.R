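#' Construct a genotype matrix
#'
#' The package's central container: diploid biallelic genotypes for a set of
#' samples at a set of loci, with optional per-call allele depths. Genotypes
#' are coded as alternate-allele dosage: 0 (ref-hom), 1 (het), 2 (alt-hom),
#' `NA` (missing call).
#'
#' @param geno integer matrix, samples in rows, loci in columns, entries in
#'   \{0, 1, 2, NA\}. Must carry row and column names (sample and locus ids).
#' @param ad_ref,ad_alt optional non-negative integer matrices of the same
#'   shape giving per-call reference/alternate read depths. Default all zero.
#' @param loci optional data frame of per-locus metadata with one row per
#'   column of `geno`: at least `chrom`, `pos`, `ref`, `alt`. A minimal
#'   synthetic scaffold (one contig, consecutive positions, A/G alleles) is
#'   built when omitted.
#' @param has_depth logical; whether `ad_ref`/`ad_alt` carry real depth
#'   information. Depth-based filters are skipped when `FALSE`.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `geno`, `ad_ref`, `ad_alt`, `loci`, `has_depth`.
#' @export
genotype_matrix <- function(geno, ad_ref = NULL, ad_alt = NULL, loci = NULL,
                            has_depth = !is.null(ad_ref)) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("`geno` must have sample rownames and locus colnames")
  stopifnot(all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
  storage.mode(geno) <- "integer"
  zero <- function(m) if (is.null(m)) {
    z <- matrix(0L, nrow(geno), ncol(geno), dimnames = dimnames(geno)); z
  } else {
    m <- as.matrix(m); storage.mode(m) <- "integer"
    stopifnot(identical(dim(m), dim(geno)), all(m >= 0L, na.rm = TRUE))
    dimnames(m) <- dimnames(geno); m
  }
  if (is.null(loci)) {
    loci <- data.frame(
      locus = colnames(geno), chrom = "chrS", pos = seq_len(ncol(geno)),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
  } else {
    loci <- as.data.frame(loci)
    stopifnot(nrow(loci) == ncol(geno))
    if (is.null(loci$locus)) loci$locus <- colnames(geno)
  }
  structure(
    list(geno = geno, ad_ref = zero(ad_ref), ad_alt = zero(ad_alt),
         loci = loci, has_depth = isTRUE(has_depth)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing%s)\n",
              nrow(x$geno), ncol(x$geno),
              100 * mean(is.na(x$geno)),
              if (x$has_depth) ", with depths" else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

sample_ids <- function(gm) rownames(gm$geno)
locus_ids <- function(gm) colnames(gm$geno)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a [genotype_matrix()]
#' @param samples,loci character vectors of ids to keep (default: all)
#' @return a `genotype_matrix`
#' @export
subset_gm <- function(gm, samples = NULL, loci = NULL) {
  s <- if (is.null(samples)) rownames(gm$geno) else samples
  l <- if (is.null(loci)) colnames(gm$geno) else loci
  missing_s <- setdiff(s, rownames(gm$geno))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  missing_l <- setdiff(l, colnames(gm$geno))
  if (length(missing_l))
    stop("unknown locus ids: ", paste(utils::head(missing_l, 5), collapse = ", "))
  idx <- match(l, colnames(gm$geno))
  genotype_matrix(gm$geno[s, l, drop = FALSE],
                  gm$ad_ref[s, l, drop = FALSE],
                  gm$ad_alt[s, l, drop = FALSE],
                  loci = gm$loci[idx, , drop = FALSE],
                  has_depth = gm$has_depth)
}

# Set calls whose summed allele depth is below `min_depth` to missing.
# No-op on matrices without depth information.
mask_low_depth <- function(gm, min_depth) {
  if (!gm$has_depth || min_depth <= 0) return(gm)
  low <- (gm$ad_ref + gm$ad_alt) < min_depth
  gm$geno[low] <- NA_integer_
  gm
}
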