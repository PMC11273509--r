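#' Simulation configuration for a two-breed crossbred herd
#'
#' Defines a herd emulating a commercial two-breed crossbreeding program:
#' purebred founder sires and dams from divergent breeds, F1 offspring
#' (sire x dam), and F2 offspring produced either by backcrossing an F1 to a
#' founder sire or by intercrossing two F1 animals. Defaults mirror a herd
#' of 24 sires, 28 dams and 923 offspring (615 F1, 308 F2; the F2 split
#' into 224 backcross and 84 intercross reflects the relative abundance of
#' paternal- versus maternal-leaning F2 subclasses in such herds).
#'
#' A fraction `frac_fixed_divergent` of loci is fixed for opposite alleles
#' in the two founder breeds (the diagnostic loci a generation panel
#' targets); the remaining loci get breed-specific allele frequencies drawn
#' from `sire_freq` / `dam_freq`, and founder genotypes are drawn from
#' Hardy-Weinberg proportions at those frequencies.
#'
#' @param n_sires,n_dams numbers of purebred founder males/females.
#' @param n_f1 number of F1 offspring (each: random sire x random dam).
#' @param n_f2_backcross number of F2 from F1 dam x founder sire.
#' @param n_f2_intercross number of F2 from F1 x F1 matings.
#' @param n_loci number of unlinked autosomal biallelic loci.
#' @param frac_fixed_divergent proportion of loci fixed for opposite
#'   alleles between the founder breeds, in `[0, 1]`.
#' @param sire_freq,dam_freq allele-frequency distributions for
#'   non-divergent loci: a list `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "beta", shape1=, shape2=)`.
#' @param mean_depth mean sequencing depth (reads per call) of the
#'   observation model.
#' @param genotype_error_rate per-read allele flip probability.
#' @param missing_rate probability that a call is dropped outright
#'   (in addition to depth-0 dropout).
#' @param seed integer seed controlling all simulation randomness.
#'
#' @return a list of class `sim_config`.
#' @seealso [simulate_herd()], [simulate_founders()]
#' @export
sim_config <- function(n_sires = 24, n_dams = 28, n_f1 = 615,
                       n_f2_backcross = 224, n_f2_intercross = 84,
                       n_loci = 2000, frac_fixed_divergent = 0.3,
                       sire_freq = list(dist = "uniform", min = 0.05, max = 0.95),
                       dam_freq = list(dist = "uniform", min = 0.05, max = 0.95),
                       mean_depth = 20, genotype_error_rate = 0.001,
                       missing_rate = 0.05, seed = 1L) {
  cfg <- list(n_sires = n_sires, n_dams = n_dams, n_f1 = n_f1,
              n_f2_backcross = n_f2_backcross,
              n_f2_intercross = n_f2_intercross, n_loci = n_loci,
              frac_fixed_divergent = frac_fixed_divergent,
              sire_freq = sire_freq, dam_freq = dam_freq,
              mean_depth = mean_depth,
              genotype_error_rate = genotype_error_rate,
              missing_rate = missing_rate, seed = as.integer(seed))
  counts <- c("n_sires", "n_dams", "n_f1", "n_f2_backcross",
              "n_f2_intercross", "n_loci")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0)
      stop("`", nm, "` must be a single non-negative count")
  probs <- c("frac_fixed_divergent", "genotype_error_rate", "missing_rate")
  for (nm in probs)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("`", nm, "` must be a probability in [0, 1]")
  if (cfg$mean_depth < 0) stop("`mean_depth` must be non-negative")
  if (cfg$n_f2_backcross > 0 && (cfg$n_f1 == 0 || cfg$n_sires == 0))
    stop("backcross F2 require at least one F1 and one founder sire")
  if (cfg$n_f2_intercross > 0 && cfg$n_f1 < 2)
    stop("intercross F2 require at least two F1")
  if (cfg$n_f1 > 0 && (cfg$n_sires == 0 || cfg$n_dams == 0))
    stop("F1 require at least one sire and one dam")
  class(cfg) <- "sim_config"
  cfg
}

draw_freq <- function(spec, n) {
  switch(spec$dist,
    uniform = stats::runif(n, spec$min, spec$max),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    stop("unknown frequency distribution: ", spec$dist))
}

#' Simulate founder genotypes for two divergent breeds
#'
#' Draws true (error-free, complete) genotypes for the founder sires and
#' dams. At divergent loci one breed is fixed alt-hom and the other
#' ref-hom; the orientation is chosen per locus and recorded in
#' `genotypes$loci$sire_allele` (`"alt"` when sires carry the alternate
#' allele). Non-divergent loci are drawn from Hardy-Weinberg proportions at
#' breed-specific frequencies.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()] whose `loci` table
#'   carries `divergent` and `sire_allele` columns), `pedigree` (founder
#'   rows of a pedigree truth table), and `true_freq` (per-locus true alt
#'   frequency in each breed).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  n_div <- round(config$frac_fixed_divergent * L)
  divergent <- rep(c(TRUE, FALSE), c(n_div, L - n_div))
  # orientation: TRUE -> sires fixed for alt allele at this divergent locus
  sire_alt <- stats::runif(L) < 0.5
  sire_p <- draw_freq(config$sire_freq, L)  # alt-allele freq in sire breed
  dam_p <- draw_freq(config$dam_freq, L)
  sire_p[divergent] <- ifelse(sire_alt[divergent], 1, 0)
  dam_p[divergent] <- ifelse(sire_alt[divergent], 0, 1)

  sids <- sprintf("S%02d", seq_len(config$n_sires))
  dids <- sprintf("D%02d", seq_len(config$n_dams))
  ids <- c(sids, dids)
  geno <- matrix(NA_integer_, length(ids), L,
                 dimnames = list(ids, sprintf("L%05d", seq_len(L))))
  for (i in seq_along(sids))
    geno[sids[i], ] <- stats::rbinom(L, 2L, sire_p)
  for (i in seq_along(dids))
    geno[dids[i], ] <- stats::rbinom(L, 2L, dam_p)

  loci <- data.frame(locus = colnames(geno), chrom = "chrS",
                     pos = seq_len(L), ref = "A", alt = "G",
                     divergent = divergent,
                     sire_allele = ifelse(sire_alt, "alt", "ref"),
                     stringsAsFactors = FALSE)
  ped <- data.frame(
    id = ids,
    role = rep(c("sire", "dam"), c(length(sids), length(dids))),
    generation = "P", sire = NA_character_, dam = NA_character_,
    cross_type = "none", stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(geno, loci = loci, has_depth = FALSE),
       pedigree = ped,
       true_freq = data.frame(locus = loci$locus, sire_p = sire_p,
                              dam_p = dam_p))
}

# One offspring genotype vector from two parental genotype vectors:
# one allele drawn uniformly from each parent, independently per locus.
mendelian_offspring <- function(g_sire, g_dam) {
  stats::rbinom(length(g_sire), 1L, g_sire / 2) +
    stats::rbinom(length(g_dam), 1L, g_dam / 2)
}

#' Simulate offspring genotypes from a mating plan
#'
#' Each offspring receives, at every locus independently, one allele drawn
#' uniformly from each parent's two alleles (Mendelian transmission at
#' unlinked loci). With fixed-divergent founders this reproduces the
#' textbook expectations: every F1 is heterozygous; a backcross to a
#' founder is on average 50 percent heterozygous / 50 percent homozygous;
#' an F1 x F1 intercross segregates 1:2:1.
#'
#' @param parents a [genotype_matrix()] containing every parent referenced
#'   by `plan` (true genotypes, no missing calls).
#' @param plan data frame with columns `id`, `sire`, `dam`, `generation`,
#'   `cross_type` — one row per offspring to generate.
#' @param seed integer seed.
#' @return list with `genotypes` (offspring-only [genotype_matrix()]) and
#'   `pedigree` (the plan, as pedigree truth rows with `role = "offspring"`).
#' @export
simulate_cross <- function(parents, plan, seed = 1L) {
  stopifnot(inherits(parents, "genotype_matrix"))
  plan <- as.data.frame(plan)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(plan)))
    stop("`plan` must have columns id, sire, dam")
  miss <- setdiff(unique(c(plan$sire, plan$dam)), rownames(parents$geno))
  if (length(miss))
    stop("plan references parents missing from `parents`: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (anyNA(parents$geno[unique(c(plan$sire, plan$dam)), , drop = FALSE]))
    stop("parent genotypes must be complete (no missing calls)")
  set.seed(seed)
  geno <- matrix(NA_integer_, nrow(plan), ncol(parents$geno),
                 dimnames = list(plan$id, colnames(parents$geno)))
  for (i in seq_len(nrow(plan)))
    geno[i, ] <- mendelian_offspring(parents$geno[plan$sire[i], ],
                                     parents$geno[plan$dam[i], ])
  ped <- data.frame(
    id = plan$id, role = "offspring",
    generation = if (is.null(plan$generation)) NA_character_ else plan$generation,
    sire = plan$sire, dam = plan$dam,
    cross_type = if (is.null(plan$cross_type)) NA_character_ else plan$cross_type,
    stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(geno, loci = parents$loci,
                                   has_depth = FALSE),
       pedigree = ped)
}

#' Simulate a complete crossbred herd with observation noise
#'
#' Convenience wrapper running [simulate_founders()], building the F1,
#' backcross-F2 and intercross-F2 mating plans (random parent choices),
#' generating true genotypes with [simulate_cross()], and optionally
#' passing everything through [apply_observation_model()].
#'
#' @param config a [sim_config()].
#' @param observe logical: apply the depth/error/missingness observation
#'   model? With `FALSE` the true, complete genotypes are returned.
#' @return list with `genotypes` (all samples), `truth` (error-free
#'   genotypes), `pedigree` (full truth table), `true_freq`, and `config`.
#' @export
simulate_herd <- function(config = sim_config(), observe = TRUE) {
  fnd <- simulate_founders(config)
  sids <- fnd$pedigree$id[fnd$pedigree$role == "sire"]
  dids <- fnd$pedigree$id[fnd$pedigree$role == "dam"]
  set.seed(config$seed + 1L)
  plans <- list()
  if (config$n_f1 > 0) {
    plans$f1 <- data.frame(
      id = sprintf("F1_%04d", seq_len(config$n_f1)),
      sire = sample(sids, config$n_f1, replace = TRUE),
      dam = sample(dids, config$n_f1, replace = TRUE),
      generation = "F1", cross_type = "sire_x_dam",
      stringsAsFactors = FALSE)
  }
  truth_geno <- fnd$genotypes
  ped <- fnd$pedigree
  bind_gm <- function(a, b)
    genotype_matrix(rbind(a$geno, b$geno), loci = a$loci, has_depth = FALSE)
  if (!is.null(plans$f1)) {
    f1 <- simulate_cross(truth_geno, plans$f1, seed = config$seed + 2L)
    truth_geno <- bind_gm(truth_geno, f1$genotypes)
    ped <- rbind(ped, f1$pedigree)
    f1_ids <- plans$f1$id
    if (config$n_f2_backcross > 0) {
      bc <- data.frame(
        id = sprintf("F2B_%04d", seq_len(config$n_f2_backcross)),
        sire = sample(sids, config$n_f2_backcross, replace = TRUE),
        dam = sample(f1_ids, config$n_f2_backcross, replace = TRUE),
        generation = "F2", cross_type = "backcross",
        stringsAsFactors = FALSE)
      r <- simulate_cross(truth_geno, bc, seed = config$seed + 3L)
      truth_geno <- bind_gm(truth_geno, r$genotypes)
      ped <- rbind(ped, r$pedigree)
    }
    if (config$n_f2_intercross > 0) {
      pick2 <- t(replicate(config$n_f2_intercross,
                           sample(f1_ids, 2L, replace = FALSE)))
      ic <- data.frame(
        id = sprintf("F2I_%04d", seq_len(config$n_f2_intercross)),
        sire = pick2[, 1], dam = pick2[, 2],
        generation = "F2", cross_type = "intercross",
        stringsAsFactors = FALSE)
      r <- simulate_cross(truth_geno, ic, seed = config$seed + 4L)
      truth_geno <- bind_gm(truth_geno, r$genotypes)
      ped <- rbind(ped, r$pedigree)
    }
  }
  out <- truth_geno
  if (observe)
    out <- apply_observation_model(truth_geno, config)
  list(genotypes = out, truth = truth_geno, pedigree = ped,
       true_freq = fnd$true_freq, config = config)
}

#' Apply a RAD-like observation model to true genotypes
#'
#' Per call: sequencing depth is Poisson(`mean_depth`) (or a constant when
#' `fixed_depth` is given); each read is drawn from the true genotype's two
#' alleles with a per-read flip probability `genotype_error_rate`; the
#' reported genotype is the naive call from the sampled reads (both alleles
#' seen at least once: heterozygote; otherwise the homozygote of the
#' observed allele). A call is set missing when depth is 0 or with
#' probability `missing_rate`.
#'
#' @param truth a complete (no missing) [genotype_matrix()].
#' @param config a [sim_config()] supplying `mean_depth`,
#'   `genotype_error_rate`, `missing_rate`, `seed`.
#' @param fixed_depth optional single depth used for every call instead of
#'   Poisson sampling (useful for calibration checks at a known depth).
#' @return an observed [genotype_matrix()] with `has_depth = TRUE`.
#' @export
apply_observation_model <- function(truth, config, fixed_depth = NULL) {
  stopifnot(inherits(truth, "genotype_matrix"))
  if (anyNA(truth$geno)) stop("`truth` must have no missing calls")
  set.seed(config$seed + 10L)
  n <- length(truth$geno)
  depth <- if (is.null(fixed_depth)) stats::rpois(n, config$mean_depth)
           else rep(as.integer(fixed_depth), n)
  e <- config$genotype_error_rate
  # probability a sampled read shows the alt allele, given true dosage g
  p_alt <- (truth$geno / 2) * (1 - e) + (1 - truth$geno / 2) * e
  n_alt <- stats::rbinom(n, depth, as.vector(p_alt))
  n_ref <- depth - n_alt
  called <- ifelse(n_alt > 0L & n_ref > 0L, 1L, ifelse(n_alt > 0L, 2L, 0L))
  drop <- depth == 0L | stats::runif(n) < config$missing_rate
  called[drop] <- NA_integer_
  gm <- truth
  gm$geno <- matrix(called, nrow(truth$geno), dimnames = dimnames(truth$geno))
  gm$ad_ref <- matrix(as.integer(n_ref), nrow(truth$geno),
                      dimnames = dimnames(truth$geno))
  gm$ad_alt <- matrix(as.integer(n_alt), nrow(truth$geno),
                      dimnames = dimnames(truth$geno))
  gm$has_depth <- TRUE
  gm
}
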