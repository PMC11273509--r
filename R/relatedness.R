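#' Method-of-moments IBD estimates (PI_HAT) for sample pairs
#'
#' The genome-wide method-of-moments estimator behind PLINK's `--genome`:
#' for each pair, the observed counts of loci identical-by-state at 0, 1
#' and 2 alleles are compared with their expectations under IBD state 0, 1
#' and 2 given the allele frequencies, and solved sequentially for the
#' estimated IBD-state probabilities P0, P1, P2. Estimates are projected
#' onto the probability simplex (each in \[0, 1\], summing to 1) and
#' `PI_HAT = P2 + P1 / 2`. Expected values: ~1 for duplicates/identical
#' twins, ~0.5 for parent-offspring, ~0.25 for half-siblings, ~0 for
#' unrelated pairs.
#'
#' @param gm a [genotype_matrix()]; monomorphic loci (frequency 0 or 1)
#'   are skipped.
#' @param freqs per-locus alternate-allele frequencies: a numeric vector
#'   named by locus, or a `snp_panel` with an `alt_freq` column. Founder
#'   estimated frequencies are the usual choice.
#' @param pairs two-column character matrix/data frame of sample id pairs;
#'   default all unordered pairs in `gm`.
#' @param min_loci warn when a pair has fewer informative co-called loci.
#' @return data frame: `id1`, `id2`, `n_loci`, `ibs0`, `ibs1`, `ibs2`,
#'   `P0`, `P1`, `P2`, `PI_HAT`.
#' @export
ibd_pihat <- function(gm, freqs, pairs = NULL, min_loci = 50) {
  if (inherits(freqs, "snp_panel")) {
    f <- freqs$alt_freq
    names(f) <- freqs$locus
    freqs <- f
  }
  if (is.null(names(freqs))) {
    stopifnot(length(freqs) == ncol(gm$geno))
    names(freqs) <- colnames(gm$geno)
  }
  loci <- intersect(colnames(gm$geno), names(freqs))
  q <- freqs[loci]                       # alt-allele frequency
  poly <- q > 0 & q < 1
  loci <- loci[poly]; q <- q[poly]
  if (!length(loci)) stop("no polymorphic loci available")
  p <- 1 - q
  geno <- gm$geno[, loci, drop = FALSE]
  if (is.null(pairs)) {
    ids <- rownames(geno)
    pairs <- t(utils::combn(ids, 2))
  }
  pairs <- as.matrix(pairs)
  # per-locus expected IBS-class probabilities given IBD state
  e00 <- 2 * p^2 * q^2                       # P(IBS0 | IBD0)
  e10 <- 4 * p^3 * q + 4 * p * q^3           # P(IBS1 | IBD0)
  e20 <- p^4 + q^4 + 4 * p^2 * q^2           # P(IBS2 | IBD0)
  e11 <- 2 * p^2 * q + 2 * p * q^2           # P(IBS1 | IBD1)
  e21 <- p^3 + q^3 + p^2 * q + p * q^2       # P(IBS2 | IBD1)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g1 <- geno[pairs[k, 1], ]; g2 <- geno[pairs[k, 2], ]
    ok <- !is.na(g1) & !is.na(g2)
    L <- sum(ok)
    if (L < min_loci)
      warning(sprintf("pair %s-%s: only %d informative loci",
                      pairs[k, 1], pairs[k, 2], L))
    d <- abs(g1[ok] - g2[ok])
    n0 <- sum(d == 2); n1 <- sum(d == 1); n2 <- sum(d == 0)
    E00 <- sum(e00[ok]); E10 <- sum(e10[ok]); E20 <- sum(e20[ok])
    E11 <- sum(e11[ok]); E21 <- sum(e21[ok])
    P0 <- n0 / E00
    P1 <- (n1 - P0 * E10) / E11
    P2 <- (n2 - P0 * E20 - P1 * E21) / L
    pr <- pmin(pmax(c(P0, P1, P2), 0), 1)
    pr <- pr / sum(pr)
    out[[k]] <- data.frame(
      id1 = pairs[k, 1], id2 = pairs[k, 2], n_loci = L,
      ibs0 = n0, ibs1 = n1, ibs2 = n2,
      P0 = pr[1], P1 = pr[2], P2 = pr[3],
      PI_HAT = pr[3] + pr[2] / 2, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Centered-IBS (VanRaden-style) kinship matrix
#'
#' Genotypes are mean-imputed per locus and centered by twice the
#' estimated allele frequency; the cross-product is normalised by the
#' summed per-locus binomial variance. The unscaled matrix is on the
#' kinship-coefficient scale (parent-offspring off-diagonal about 0.25);
#' `times_two = TRUE` doubles it to the expected-covariance (numerator
#' relationship) scale, where parent-offspring pairs sit near 0.5.
#'
#' @param gm a [genotype_matrix()]; loci with all calls missing are
#'   dropped.
#' @param times_two double the matrix to expected covariances?
#' @return symmetric numeric matrix with sample ids as dimnames and
#'   attributes `method = "centered_ibs"` and `scaled` (logical).
#' @export
centered_ibs_kinship <- function(gm, times_two = TRUE) {
  g <- gm$geno
  all_missing <- colSums(!is.na(g)) == 0
  g <- g[, !all_missing, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0))
    g[is.na(g[, j]), j] <- mu[j]
  p_hat <- mu / 2
  denom <- 4 * sum(p_hat * (1 - p_hat))
  if (denom == 0) stop("all loci monomorphic; kinship undefined")
  z <- sweep(g, 2, mu)
  k <- tcrossprod(z) / denom
  if (times_two) k <- 2 * k
  structure(k, method = "centered_ibs", scaled = times_two)
}

#' Pairwise allele-sharing p-distance matrix
#'
#' Per pair of samples, the distance is the mean over co-called loci of a
#' per-locus score: 0 for identical genotypes, 0.5 when the genotypes
#' share exactly one allele (het versus either homozygote), 1 for
#' opposite homozygotes. Loci missing in either sample are ignored
#' pairwise; a pair with zero co-called loci is an error.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return symmetric numeric matrix of distances in \[0, 1\] with zero
#'   diagonal.
#' @export
p_distance <- function(gm) {
  g <- gm$geno
  n <- nrow(g)
  if (n < 2) stop("need at least two samples")
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok))
        stop(sprintf("no co-called loci for pair %s-%s",
                     rownames(g)[i], rownames(g)[j]))
      d[i, j] <- d[j, i] <- mean(abs(g[i, ok] - g[j, ok]) / 2)
    }
  }
  d
}
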