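#' Default hard-filter thresholds for candidate SNPs
#'
#' GATK-style site filters tuned for RAD-seq herd data. A record is
#' removed when it violates any rule; inequalities are applied exactly as
#' written (strict), so a record sitting exactly on a boundary is kept.
#' `AN_min` defaults to the cohort sample count at filter time, i.e. a
#' site must have at least half of its genotype calls present.
#'
#' @param QUAL_min,DP_min,DP_max,MQ_min,QD_min,FS_max,BaseQRankSum_min,ReadPosRankSum_min,MQRankSum_min,SOR_max,MQ0_max,AN_min numeric thresholds; set any to `NA` to disable that rule.
#' @return named list of thresholds.
#' @export
hard_filter_defaults <- function(QUAL_min = 250, DP_min = 1500,
                                 DP_max = 6000, MQ_min = 50, QD_min = 4,
                                 FS_max = 15, BaseQRankSum_min = -4,
                                 ReadPosRankSum_min = -3.5,
                                 MQRankSum_min = -10, SOR_max = 4,
                                 MQ0_max = 30, AN_min = NA) {
  list(QUAL_min = QUAL_min, DP_min = DP_min, DP_max = DP_max,
       MQ_min = MQ_min, QD_min = QD_min, FS_max = FS_max,
       BaseQRankSum_min = BaseQRankSum_min,
       ReadPosRankSum_min = ReadPosRankSum_min,
       MQRankSum_min = MQRankSum_min, SOR_max = SOR_max,
       MQ0_max = MQ0_max, AN_min = AN_min)
}

#' Hard-filter variant records on site quality metrics
#'
#' Removes records violating any of the threshold rules: `QUAL <
#' QUAL_min`, `DP < DP_min`, `DP > DP_max`, `MQ < MQ_min`, `QD < QD_min`,
#' `FS > FS_max`, `BaseQRankSum < BaseQRankSum_min`, `ReadPosRankSum <
#' ReadPosRankSum_min`, `MQRankSum < MQRankSum_min`, `SOR > SOR_max`,
#' `MQ0 >= MQ0_max`, `AN < AN_min`. All inequalities are strict as
#' written (note `MQ0` uses >=). A record lacking a metric is not removed
#' by that metric's rule, matching the usual convention for rank-sum
#' annotations that are undefined at homozygous sites.
#'
#' @param records data frame of variant records as returned by
#'   [read_vcf()]`$records`.
#' @param thresholds list from [hard_filter_defaults()].
#' @param n_samples cohort size, used for the default `AN_min =
#'   n_samples`; ignored when `thresholds$AN_min` is set.
#' @return list with `retained` (the surviving records), `removed`,
#'   and `rejections` (named integer vector: per-rule violation counts;
#'   a record failing several rules counts in each).
#' @export
hard_filter <- function(records, thresholds = hard_filter_defaults(),
                        n_samples = NULL) {
  th <- thresholds
  if (is.na(th$AN_min) && !is.null(n_samples)) th$AN_min <- n_samples
  viol <- function(x, rule) {
    v <- rule(x)
    v[is.na(v)] <- FALSE  # absent metric: rule does not fire
    v
  }
  rules <- list(
    QUAL = viol(records$QUAL, function(x) x < th$QUAL_min),
    DP_low = viol(records$DP, function(x) x < th$DP_min),
    DP_high = viol(records$DP, function(x) x > th$DP_max),
    MQ = viol(records$MQ, function(x) x < th$MQ_min),
    QD = viol(records$QD, function(x) x < th$QD_min),
    FS = viol(records$FS, function(x) x > th$FS_max),
    BaseQRankSum = viol(records$BaseQRankSum,
                        function(x) x < th$BaseQRankSum_min),
    ReadPosRankSum = viol(records$ReadPosRankSum,
                          function(x) x < th$ReadPosRankSum_min),
    MQRankSum = viol(records$MQRankSum, function(x) x < th$MQRankSum_min),
    SOR = viol(records$SOR, function(x) x > th$SOR_max),
    MQ0 = viol(records$MQ0, function(x) x >= th$MQ0_max),
    AN = if (is.na(th$AN_min)) rep(FALSE, nrow(records))
         else viol(records$AN, function(x) x < th$AN_min))
  # disabled rules (NA thresholds) never fire
  for (nm in names(rules)) rules[[nm]][is.na(rules[[nm]])] <- FALSE
  any_viol <- Reduce(`|`, rules)
  list(retained = records[!any_viol, , drop = FALSE],
       removed = records[any_viol, , drop = FALSE],
       rejections = vapply(rules, sum, integer(1)))
}

# allele counts (ref, alt) within a sample group at each locus
group_allele_counts <- function(geno, ids) {
  sub <- geno[ids, , drop = FALSE]
  alt <- colSums(sub, na.rm = TRUE)
  called <- colSums(!is.na(sub))
  cbind(ref = 2 * called - alt, alt = alt, called = called)
}

#' Select the generation-classification SNP panel
#'
#' Retains loci where the founder sires are (nearly) fixed for one allele
#' and the founder dams (nearly) fixed for the other. "Nearly" is a slack
#' of `slack` allele copies below complete fixation: with 24 sires and 28
#' dams and `slack = 5`, the modal-allele count must fall in \[43, 48\]
#' among sires and \[51, 56\] among dams. The two modal alleles must
#' differ; loci where a group's modal allele is tied are excluded as
#' non-diagnostic. Calls with summed allele depth below `min_allele_depth`
#' are set missing first (when the matrix carries depths), and by default
#' a locus is dropped if any founder call is missing.
#'
#' @param gm a [genotype_matrix()].
#' @param sire_ids,dam_ids disjoint character vectors of founder sample ids.
#' @param slack non-negative integer, allele copies of slack below
#'   fixation (`slack = 0` demands strict fixation).
#' @param min_allele_depth minimum summed allele depth for a call to count.
#' @param drop_missing_founder drop loci with any missing founder call?
#' @return an object of class `snp_panel` (`kind = "generation"`): data
#'   frame with `locus`, `chrom`, `pos`, `sire_allele`, `dam_allele`
#'   (each `"ref"` or `"alt"`).
#' @export
select_generation_panel <- function(gm, sire_ids, dam_ids, slack = 5,
                                    min_allele_depth = 6,
                                    drop_missing_founder = TRUE) {
  if (!length(sire_ids) || !length(dam_ids))
    stop("founder id sets must be non-empty")
  if (length(intersect(sire_ids, dam_ids)))
    stop("sire and dam id sets must be disjoint")
  gm <- mask_low_depth(gm, min_allele_depth)
  multi <- if (!is.null(gm$loci$alt))
    grepl(",", gm$loci$alt, fixed = TRUE) else rep(FALSE, ncol(gm$geno))
  sc <- group_allele_counts(gm$geno, sire_ids)
  dc <- group_allele_counts(gm$geno, dam_ids)
  modal <- function(cnt) {
    tie <- cnt[, "ref"] == cnt[, "alt"]
    allele <- ifelse(cnt[, "alt"] > cnt[, "ref"], "alt", "ref")
    allele[tie] <- NA
    list(allele = allele, count = pmax(cnt[, "ref"], cnt[, "alt"]))
  }
  sm <- modal(sc); dm <- modal(dc)
  in_window <- function(count, n_founders)
    count >= 2 * n_founders - slack & count <= 2 * n_founders
  keep <- !multi &
    !is.na(sm$allele) & !is.na(dm$allele) &
    sm$allele != dm$allele &
    in_window(sm$count, length(sire_ids)) &
    in_window(dm$count, length(dam_ids))
  if (drop_missing_founder)
    keep <- keep & sc[, "called"] == length(sire_ids) &
      dc[, "called"] == length(dam_ids)
  keep[is.na(keep)] <- FALSE
  idx <- which(keep)
  panel <- data.frame(locus = colnames(gm$geno)[idx],
                      chrom = gm$loci$chrom[idx], pos = gm$loci$pos[idx],
                      sire_allele = sm$allele[idx],
                      dam_allele = dm$allele[idx],
                      stringsAsFactors = FALSE)
  structure(panel, class = c("snp_panel", "data.frame"),
            kind = "generation")
}

#' Select the parentage-assignment SNP panel
#'
#' Multiallelic loci are excluded first. The remaining filters are
#' computed on the paternal (sire) samples: minor allele frequency
#' `> maf_min`, observed heterozygosity `> het_min`, missing-data
#' proportion `< miss_max`, and Hardy-Weinberg exact p-value
#' `> hwe_p_min` (all strict). Finally, across all samples, calls with
#' summed allele depth `< min_allele_depth` are set missing and loci with
#' missing proportion `> miss_max_final` are excluded. Alternate-allele
#' frequencies recorded in the panel are estimated from the sire calls of
#' the retained data.
#'
#' @param gm a [genotype_matrix()].
#' @param sire_ids character vector of founder sire ids.
#' @param maf_min,het_min,miss_max,hwe_p_min,min_allele_depth,miss_max_final filter thresholds.
#' @return an object of class `snp_panel` (`kind = "parentage"`): data
#'   frame with `locus`, `chrom`, `pos`, `alt_freq`, `maf`, `het_obs`,
#'   `hwe_p`.
#' @export
select_parentage_panel <- function(gm, sire_ids, maf_min = 0.25,
                                   het_min = 0.2, miss_max = 0.7,
                                   hwe_p_min = 0.01, min_allele_depth = 6,
                                   miss_max_final = 0.8) {
  if (!ncol(gm$geno)) stop("empty genotype matrix")
  if (!length(sire_ids)) stop("sire id set must be non-empty")
  gm <- mask_low_depth(gm, min_allele_depth)
  multi <- if (!is.null(gm$loci$alt))
    grepl(",", gm$loci$alt, fixed = TRUE) else rep(FALSE, ncol(gm$geno))
  sg <- gm$geno[sire_ids, , drop = FALSE]
  n_called <- colSums(!is.na(sg))
  miss <- 1 - n_called / length(sire_ids)
  alt_freq <- ifelse(n_called > 0, colSums(sg, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(alt_freq, 1 - alt_freq)
  het_obs <- ifelse(n_called > 0, colSums(sg == 1L, na.rm = TRUE) / n_called, NA)
  hwe_p <- vapply(seq_len(ncol(sg)), function(j) {
    g <- sg[, j]
    hwe_exact_test(sum(g == 1L, na.rm = TRUE), sum(g == 0L, na.rm = TRUE),
                   sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  miss_all <- colMeans(is.na(gm$geno))
  keep <- !multi & n_called > 0 &
    maf > maf_min & het_obs > het_min & miss < miss_max &
    hwe_p > hwe_p_min & miss_all <= miss_max_final
  keep[is.na(keep)] <- FALSE
  idx <- which(keep)
  panel <- data.frame(locus = colnames(gm$geno)[idx],
                      chrom = gm$loci$chrom[idx], pos = gm$loci$pos[idx],
                      alt_freq = alt_freq[idx], maf = maf[idx],
                      het_obs = het_obs[idx], hwe_p = hwe_p[idx],
                      stringsAsFactors = FALSE)
  structure(panel, class = c("snp_panel", "data.frame"),
            kind = "parentage")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel (%s): %d loci\n", attr(x, "kind"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 6))
  invisible(x)
}

#' Write / read a SNP panel as TSV
#'
#' @param panel a `snp_panel`.
#' @param path file path.
#' @return `path` (write) or the `snp_panel` (read).
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crosskin snp_panel kind=%s", attr(panel, "kind")),
             con)
  utils::write.table(panel, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub(".*kind=", "", first)
  x <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         stringsAsFactors = FALSE)
  structure(x, class = c("snp_panel", "data.frame"), kind = kind)
}
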