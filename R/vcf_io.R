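#' Write a genotype matrix to a VCF v4.2 file
#'
#' One record per locus, FORMAT `GT:AD:DP`, 1-based positions. Missing
#' calls are written as `./.` (with their observed allele depths, if any).
#' Output is plain text and byte-deterministic for a given matrix, so
#' identical simulation seeds give identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param info optional character vector (length = n loci) of INFO strings;
#'   default `"."`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, info = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  loci <- gm$loci
  if (is.null(info)) info <- rep(".", nrow(loci))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=crosskin",
    sprintf("##contig=<ID=%s>", unique(loci$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$geno)), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gm$geno))) {
    g <- gm$geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    ad <- paste0(gm$ad_ref[, j], ",", gm$ad_alt[, j])
    dp <- gm$ad_ref[, j] + gm$ad_alt[, j]
    calls <- paste(gt, ad, dp, sep = ":")
    writeLines(paste(c(loci$chrom[j], loci$pos[j], loci$locus[j],
                       loci$ref[j], loci$alt[j], ".", ".", info[j],
                       "GT:AD:DP", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a pedigree truth table to TSV
#'
#' Columns: `sample_id`, `role`, `generation`, `sire_id`, `dam_id`,
#' `cross_type`; missing parents written as `NA`.
#'
#' @param pedigree data frame as produced by the simulation functions.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(sample_id = pedigree$id, role = pedigree$role,
                    generation = pedigree$generation,
                    sire_id = pedigree$sire, dam_id = pedigree$dam,
                    cross_type = pedigree$cross_type)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV written by [write_pedigree()]
#' @param path file path.
#' @return data frame with columns `id`, `role`, `generation`, `sire`,
#'   `dam`, `cross_type`.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  data.frame(id = as.character(x$sample_id), role = x$role,
             generation = as.character(x$generation),
             sire = as.character(x$sire_id), dam = as.character(x$dam_id),
             cross_type = x$cross_type, stringsAsFactors = FALSE)
}

#' Read a multi-sample VCF into variant records and a genotype matrix
#'
#' Parsing is delegated to \pkg{vcfR}; this function extracts the site
#' metrics used by [hard_filter()] and recodes per-sample calls as
#' alt-allele dosage. Multiallelic records are retained in the record table
#' (with all their alternate alleles) but their genotype calls are set
#' missing in the matrix — panel selection excludes them explicitly.
#' Missing GT fields become `NA`; an absent AD field becomes depths (0,0).
#'
#' @param path path to a VCF v4.2 file (plain or bgzipped).
#' @return list with `records` (data frame: `chrom`, `pos`, `locus`,
#'   `ref`, `alt`, `n_alt`, `QUAL` and the INFO metrics `DP`, `MQ`, `QD`,
#'   `FS`, `SOR`, `AN`, `MQ0`, `BaseQRankSum`, `ReadPosRankSum`,
#'   `MQRankSum`, all `NA` when absent) and `genotypes`
#'   (a [genotype_matrix()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_alt <- lengths(strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",",
                            fixed = TRUE))
  ids <- fix$ID
  if (any(is.na(ids) | ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, ":", fix$POS), ids)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    suppressWarnings(as.numeric(x))
  }
  records <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), locus = ids,
    ref = fix$REF, alt = fix$ALT, n_alt = n_alt,
    QUAL = suppressWarnings(as.numeric(fix$QUAL)),
    DP = info_num("DP"), MQ = info_num("MQ"), QD = info_num("QD"),
    FS = info_num("FS"), SOR = info_num("SOR"), AN = info_num("AN"),
    MQ0 = info_num("MQ0"), BaseQRankSum = info_num("BaseQRankSum"),
    ReadPosRankSum = info_num("ReadPosRankSum"),
    MQRankSum = info_num("MQRankSum"),
    stringsAsFactors = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)
  # dosage coding; any allele index > 1 (multiallelic call) -> NA
  code_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- t(apply(gt, 1, code_gt))
  if (nrow(gt) == 1) geno <- matrix(geno, nrow = 1)
  ad_split <- function(ad_str, field) {
    out <- matrix(0L, nrow(gt), ncol(gt))
    ok <- !is.na(ad_str)
    parts <- strsplit(ad_str[ok], ",", fixed = TRUE)
    vals <- vapply(parts, function(p) {
      v <- suppressWarnings(as.integer(p[field]))
      if (is.na(v)) 0L else v
    }, integer(1))
    out[ok] <- vals
    out
  }
  ad_ref <- ad_split(ad, 1L)
  ad_alt <- ad_split(ad, 2L)
  geno <- t(geno); ad_ref <- t(ad_ref); ad_alt <- t(ad_alt)
  dimnames(geno) <- list(samples, ids)
  dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(geno)
  loci <- data.frame(locus = ids, chrom = records$chrom, pos = records$pos,
                     ref = records$ref, alt = records$alt,
                     stringsAsFactors = FALSE)
  has_depth <- any(ad_ref + ad_alt > 0)
  list(records = records,
       genotypes = genotype_matrix(geno, ad_ref, ad_alt, loci = loci,
                                   has_depth = has_depth))
}
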