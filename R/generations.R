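#' Heterozygous / paternal / maternal locus ratios per offspring
#'
#' At each generation-panel locus with a non-missing call, an offspring is
#' counted as: heterozygous (H); homozygous for the sire-diagnostic allele
#' (paternal genotype locus, PGL); or homozygous for the dam-diagnostic
#' allele (maternal genotype locus, MGL). Each ratio is the count divided
#' by the number of panel loci successfully genotyped in that animal. For
#' a biallelic panel every called genotype falls in exactly one class, so
#' the three ratios sum to one.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a generation-kind `snp_panel` from
#'   [select_generation_panel()].
#' @param offspring_ids character vector of sample ids to score.
#' @return data frame with `sample_id`, `n_genotyped`, `het_ratio`,
#'   `paternal_ratio`, `maternal_ratio`.
#' @export
compute_ratios <- function(gm, panel, offspring_ids) {
  if (!identical(attr(panel, "kind"), "generation"))
    stop("`panel` must be a generation panel")
  missing_loci <- setdiff(panel$locus, colnames(gm$geno))
  if (length(missing_loci))
    stop("panel loci absent from matrix: ",
         paste(utils::head(missing_loci, 5), collapse = ", "))
  sub <- gm$geno[offspring_ids, panel$locus, drop = FALSE]
  # dosage of the sire-diagnostic homozygote at each panel locus
  sire_hom <- ifelse(panel$sire_allele == "alt", 2L, 0L)
  dam_hom <- ifelse(panel$dam_allele == "alt", 2L, 0L)
  n_gt <- rowSums(!is.na(sub))
  if (any(n_gt == 0))
    stop("no genotyped panel loci for: ",
         paste(offspring_ids[n_gt == 0], collapse = ", "))
  n_het <- rowSums(sub == 1L, na.rm = TRUE)
  n_pgl <- rowSums(sub == matrix(sire_hom, nrow(sub), ncol(sub),
                                 byrow = TRUE), na.rm = TRUE)
  n_mgl <- rowSums(sub == matrix(dam_hom, nrow(sub), ncol(sub),
                                 byrow = TRUE), na.rm = TRUE)
  data.frame(sample_id = offspring_ids, n_genotyped = n_gt,
             het_ratio = n_het / n_gt, paternal_ratio = n_pgl / n_gt,
             maternal_ratio = n_mgl / n_gt, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify offspring into F1 and F2 subclasses
#'
#' Decision rule: heterozygous ratio > 0.5 is F1; otherwise the animal is
#' F2, subdivided by its parental-allele ratios into MSF2 (paternal ratio
#' > 0.5, strong paternal character), MDF2 (maternal ratio > 0.5), LSF2
#' (paternal > maternal, slight paternal) and LDF2 (maternal > paternal).
#' An exact paternal = maternal tie is labelled LSF2 and flagged in the
#' `tie` column.
#'
#' @param ratios data frame from [compute_ratios()].
#' @return the input with added `label` (factor with levels F1, MSF2,
#'   MDF2, LSF2, LDF2) and logical `tie` columns.
#' @export
classify_generation <- function(ratios) {
  h <- ratios$het_ratio; p <- ratios$paternal_ratio
  m <- ratios$maternal_ratio
  lab <- ifelse(h > 0.5, "F1",
         ifelse(p > 0.5, "MSF2",
         ifelse(m > 0.5, "MDF2",
         ifelse(p >= m, "LSF2", "LDF2"))))
  ratios$label <- factor(lab, levels = c("F1", "MSF2", "MDF2", "LSF2",
                                         "LDF2"))
  ratios$tie <- h <= 0.5 & p <= 0.5 & m <= 0.5 & p == m
  ratios
}

#' Compare generation labels with pedigree truth or farm records
#'
#' Accuracy is reported at two granularities: F1-versus-F2 (labels
#' collapsed to generation) always, and 5-way whenever the truth provides
#' subclass labels. Truth can be a simulation pedigree (columns `id`,
#' `generation`) or a known-records table with columns `id` and `label`.
#'
#' @param labels data frame from [classify_generation()].
#' @param truth pedigree or records data frame.
#' @return list with `n_evaluated`, `accuracy_generation`,
#'   `accuracy_5way` (`NA` when truth has no subclass labels),
#'   `confusion` (predicted x true generation table).
#' @export
evaluate_against_truth <- function(labels, truth) {
  ids <- intersect(labels$sample_id, truth$id)
  if (!length(ids)) stop("no overlapping sample ids between labels and truth")
  pred <- labels[match(ids, labels$sample_id), ]
  tr <- truth[match(ids, truth$id), ]
  pred_gen <- ifelse(pred$label == "F1", "F1", "F2")
  acc5 <- NA_real_
  if (!is.null(tr$label))
    acc5 <- mean(as.character(pred$label) == as.character(tr$label))
  true_gen <- as.character(tr$generation)
  list(n_evaluated = length(ids),
       accuracy_generation = mean(pred_gen == true_gen),
       accuracy_5way = acc5,
       confusion = table(predicted = pred_gen, true = true_gen))
}

#' Scatter plot of paternal versus maternal ratios
#'
#' The classic diagnostic figure for this workflow: each offspring plotted
#' at (paternal ratio, maternal ratio), coloured by assigned subclass. F1
#' animals cluster near the origin (mostly heterozygous), backcross F2
#' along the paternal axis, intercross F2 in between.
#'
#' @param labelled data frame from [classify_generation()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the labelled data.
#' @export
plot_ratios <- function(labelled, ...) {
  cols <- c(F1 = "#1b9e77", MSF2 = "#d95f02", MDF2 = "#7570b3",
            LSF2 = "#e7298a", LDF2 = "#66a61e")
  graphics::plot(labelled$paternal_ratio, labelled$maternal_ratio,
                 col = cols[as.character(labelled$label)], pch = 19,
                 xlab = "paternal ratio", ylab = "maternal ratio",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(labelled)
}
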