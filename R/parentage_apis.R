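#' Parentage assignment from Mendelian transmission probabilities
#'
#' For each offspring, every candidate sire x dam pair is scored by the
#' mean, over co-typed panel loci, of the Mendelian probability of the
#' offspring genotype given the pair's genotypes (a locus incompatible
#' with the pair contributes 0 to the mean, so a handful of genotyping
#' errors lowers the score without vetoing the pair). Pairs are ranked
#' per offspring; `mendel1..3` are the top three scores and `delta1 =
#' mendel1 - mendel2`, `delta2 = mendel2 - mendel3`. The first-ranked
#' sire is taken as the most probable sire. An offspring's assignment is
#' accepted when its `delta1` clears a threshold set from the empirical
#' `delta1` distribution so that a proportion `accepted_error_rate` of
#' assignments (the least-separated ones) is rejected — an approximation
#' to calibrating the expected assignment error rate.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a parentage `snp_panel`.
#' @param offspring_ids,sire_ids,dam_ids sample id vectors; both parent
#'   sets must be non-empty.
#' @param accepted_error_rate target assignment error rate in \[0, 1\].
#' @return data frame of class `apis_scores`: `offspring`, `sire`, `dam`,
#'   `mendel1`, `mendel2`, `mendel3`, `delta1`, `delta2`, `n_loci`,
#'   `accepted`; attribute `delta1_threshold`.
#' @export
assign_apis <- function(gm, panel, offspring_ids, sire_ids, dam_ids,
                        accepted_error_rate = 0.05) {
  if (!length(sire_ids) || !length(dam_ids))
    stop("both parent sets must be non-empty")
  loci <- panel$locus
  og <- gm$geno[offspring_ids, loci, drop = FALSE]
  sg <- gm$geno[sire_ids, loci, drop = FALSE]
  dg <- gm$geno[dam_ids, loci, drop = FALSE]
  pairs <- expand.grid(si = seq_along(sire_ids), di = seq_along(dam_ids))
  res <- vector("list", length(offspring_ids))
  for (oi in seq_along(offspring_ids)) {
    go <- og[oi, ]
    scores <- numeric(nrow(pairs))
    nl <- integer(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      gs <- sg[pairs$si[k], ]; gd <- dg[pairs$di[k], ]
      ok <- !is.na(go) & !is.na(gs) & !is.na(gd)
      nl[k] <- sum(ok)
      scores[k] <- if (nl[k]) mean(trans_pair(go[ok], gs[ok], gd[ok]))
                   else NA_real_
    }
    ord <- order(scores, decreasing = TRUE, na.last = TRUE)
    top <- ord[seq_len(min(3, length(ord)))]
    m <- scores[top]
    length(m) <- 3
    res[[oi]] <- data.frame(
      offspring = offspring_ids[oi],
      sire = sire_ids[pairs$si[top[1]]], dam = dam_ids[pairs$di[top[1]]],
      mendel1 = m[1], mendel2 = m[2], mendel3 = m[3],
      delta1 = m[1] - m[2], delta2 = m[2] - m[3],
      n_loci = nl[top[1]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  thr <- stats::quantile(out$delta1, probs = accepted_error_rate,
                         na.rm = TRUE, names = FALSE)
  out$accepted <- !is.na(out$delta1) & out$delta1 > thr
  structure(out, class = c("apis_scores", "data.frame"),
            delta1_threshold = thr)
}

#' Exclusion-based parentage assignment (Mendelian incompatibility counts)
#'
#' For each offspring and each candidate sire x dam pair, counts the panel
#' loci at which the offspring genotype has zero probability under
#' Mendelian transmission from the pair (e.g. offspring alt-hom with a
#' ref-hom parent, or offspring het with both parents the same
#' homozygote). Pairs are ranked by ascending incompatibility count; the
#' first-ranked pair is the proposed parentage. Per-candidate single
#' mismatches (offspring and candidate opposing homozygotes) are also
#' reported.
#'
#' @inheritParams assign_apis
#' @return list of class `exclusion_result` with `best` (data frame:
#'   `offspring`, `sire`, `dam`, `n_incompatible`, `n_loci`), `pairs`
#'   (all pair counts, long format) and `single` (offspring x candidate
#'   matrix of single-parent mismatch counts).
#' @export
assign_exclusion <- function(gm, panel, offspring_ids, sire_ids, dam_ids) {
  if (!length(sire_ids) || !length(dam_ids))
    stop("both parent sets must be non-empty")
  loci <- panel$locus
  og <- gm$geno[offspring_ids, loci, drop = FALSE]
  sg <- gm$geno[sire_ids, loci, drop = FALSE]
  dg <- gm$geno[dam_ids, loci, drop = FALSE]
  pairs <- expand.grid(si = seq_along(sire_ids), di = seq_along(dam_ids))
  best <- vector("list", length(offspring_ids))
  allp <- vector("list", length(offspring_ids))
  cand <- rbind(sg, dg)
  single <- matrix(0L, length(offspring_ids), nrow(cand),
                   dimnames = list(offspring_ids, rownames(cand)))
  for (oi in seq_along(offspring_ids)) {
    go <- og[oi, ]
    # single-candidate: loci where offspring and candidate share no allele
    for (ci in seq_len(nrow(cand))) {
      gc_v <- cand[ci, ]
      ok <- !is.na(go) & !is.na(gc_v)
      single[oi, ci] <- sum(abs(go[ok] - gc_v[ok]) == 2L)
    }
    counts <- integer(nrow(pairs))
    nl <- integer(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      gs <- sg[pairs$si[k], ]; gd <- dg[pairs$di[k], ]
      ok <- !is.na(go) & !is.na(gs) & !is.na(gd)
      nl[k] <- sum(ok)
      counts[k] <- sum(trans_pair(go[ok], gs[ok], gd[ok]) == 0)
    }
    ord <- order(counts, nl * -1L)
    b <- ord[1]
    best[[oi]] <- data.frame(
      offspring = offspring_ids[oi], sire = sire_ids[pairs$si[b]],
      dam = dam_ids[pairs$di[b]], n_incompatible = counts[b],
      n_loci = nl[b], stringsAsFactors = FALSE)
    allp[[oi]] <- data.frame(
      offspring = offspring_ids[oi], sire = sire_ids[pairs$si],
      dam = dam_ids[pairs$di], n_incompatible = counts, n_loci = nl,
      rank = rank(counts, ties.method = "min"),
      stringsAsFactors = FALSE)
  }
  structure(list(best = do.call(rbind, best), pairs = do.call(rbind, allp),
                 single = single),
            class = "exclusion_result")
}

#' Consensus of two parentage assignment results
#'
#' Intersects two per-offspring sire assignments: an (offspring, sire)
#' pair is kept when both methods propose it. Emits Venn-style counts of
#' the agreement structure.
#'
#' @param assign_a,assign_b data frames with columns `offspring` and
#'   `sire` (e.g. from [assign_likelihood()] and [assign_apis()]).
#' @return list with `agreed` (data frame of shared assignments),
#'   `disagreed` (offspring with conflicting sires, side by side) and
#'   `venn` (named counts: `n_a`, `n_b`, `n_agree`, `n_disagree`,
#'   `n_only_a`, `n_only_b`).
#' @export
consensus_assignments <- function(assign_a, assign_b) {
  a <- data.frame(offspring = assign_a$offspring,
                  sire_a = assign_a$sire, stringsAsFactors = FALSE)
  b <- data.frame(offspring = assign_b$offspring,
                  sire_b = assign_b$sire, stringsAsFactors = FALSE)
  m <- merge(a, b, by = "offspring", all = TRUE)
  both <- !is.na(m$sire_a) & !is.na(m$sire_b)
  agree <- both & m$sire_a == m$sire_b
  list(
    agreed = data.frame(offspring = m$offspring[agree],
                        sire = m$sire_a[agree], stringsAsFactors = FALSE),
    disagreed = m[both & !agree, , drop = FALSE],
    venn = c(n_a = sum(!is.na(m$sire_a)), n_b = sum(!is.na(m$sire_b)),
             n_agree = sum(agree), n_disagree = sum(both & !agree),
             n_only_a = sum(!is.na(m$sire_a) & is.na(m$sire_b)),
             n_only_b = sum(is.na(m$sire_a) & !is.na(m$sire_b))))
}
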