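make_parentage_panel <- function(q, loci = sprintf("L%05d", seq_along(q))) {
  structure(data.frame(locus = loci, chrom = "chrS", pos = seq_along(q),
                       alt_freq = q, maf = pmin(q, 1 - q),
                       het_obs = NA_real_, hwe_p = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("snp_panel", "data.frame"), kind = "parentage")
}

# simulated paternity study: known sires/dams, F1 with recorded truth
sim_paternity <- function(n_sires, n_dams, n_off, L, error_rate = 0,
                          mean_depth = 30, missing_rate = 0, seed = 1,
                          fmin = 0.2, fmax = 0.8) {
  cfg <- sim_config(n_sires = n_sires, n_dams = n_dams, n_f1 = n_off,
                    n_f2_backcross = 0, n_f2_intercross = 0, n_loci = L,
                    frac_fixed_divergent = 0,
                    sire_freq = list(dist = "uniform", min = fmin, max = fmax),
                    dam_freq = list(dist = "uniform", min = fmin, max = fmax),
                    mean_depth = mean_depth,
                    genotype_error_rate = error_rate,
                    missing_rate = missing_rate, seed = seed)
  h <- simulate_herd(cfg, observe = error_rate > 0 || missing_rate > 0)
  ped <- h$pedigree
  list(gm = h$genotypes, truth = h$truth, ped = ped,
       sires = ped$id[ped$role == "sire"],
       dams = ped$id[ped$role == "dam"],
       off = ped$id[ped$role == "offspring"],
       true_sire = ped$sire[ped$role == "offspring"],
       true_dam = ped$dam[ped$role == "offspring"])
}

test_that("per-locus likelihood ratios match hand-derived transmission values", {
  # het offspring, hom-alt candidate, q = 0.5: T = p = 0.5, HWE = 2pq = 0.5
  expect_equal(locus_likelihood_ratio(1L, 2L, NULL, 0.5, 0), 1)
  # impossible transmission at zero error: ratio 0
  expect_equal(locus_likelihood_ratio(0L, 2L, NULL, 0.5, 0), 0)
  # error rate 1: no information, ratio 1 regardless of configuration
  for (go in 0:2) for (gc in 0:2)
    expect_equal(locus_likelihood_ratio(go, gc, NULL, 0.3, 1), 1)
  # missing genotypes give a neutral ratio
  expect_equal(locus_likelihood_ratio(NA, 2L, NULL, 0.5, 0), 1)
  # hom-alt offspring from hom-alt candidate: T = q, ratio = q / q^2 = 1/q
  expect_equal(locus_likelihood_ratio(2L, 2L, NULL, 0.25, 0), 4)
  expect_error(locus_likelihood_ratio(1L, 1L, NULL, 0, 0), "allele_freq")
})

test_that("summed-LOD ranking equals the exhaustive joint-likelihood oracle", {
  # oracle computed by explicit gamete enumeration, independent of the
  # package's closed-form transmission expressions
  oracle_locus <- function(go, gc, q, e) {
    gametes <- switch(gc + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
    t_prob <- 0
    for (a in gametes) for (b in 0:1) {
      pb <- if (b == 1L) q else 1 - q
      if (a + b == go) t_prob <- t_prob + 0.5 * pb
    }
    hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)[go + 1L]
    (1 - e) * t_prob + e * hw
  }
  set.seed(201)
  for (rep in 1:40) {
    L <- sample(1:5, 1)
    nc <- sample(2:4, 1)
    q <- round(runif(L, 0.1, 0.9), 2)
    e <- sample(c(0.001, 0.01, 0.1), 1)
    off <- sample(0:2, L, replace = TRUE)
    cand <- matrix(sample(0:2, L * nc, replace = TRUE), nc, L)
    geno <- rbind(off, cand)
    rownames(geno) <- c("off", paste0("c", 1:nc))
    colnames(geno) <- sprintf("L%05d", 1:L)
    panel <- make_parentage_panel(q, colnames(geno))
    lik <- assign_likelihood(gm_from(geno), panel, "off",
                             paste0("c", 1:nc),
                             params = likelihood_sim_params(
                               prop_loci_typed = 1, min_typed_loci = 1,
                               n_simulated_offspring = 10,
                               n_candidate_fathers = 3),
                             error_rate = e, seed = 1,
                             criticals = list(strict = Inf, relaxed = Inf))
    lods <- attr(lik, "lod_matrix")["off", ]
    oracle_loglik <- vapply(seq_len(nc), function(ci)
      sum(log(vapply(seq_len(L), function(l)
        oracle_locus(off[l], cand[ci, l], q[l], e), numeric(1)))),
      numeric(1))
    # LOD and oracle log-likelihood differ by a candidate-independent
    # constant, so their pairwise differences must agree exactly
    centered_lod <- lods - max(lods)
    centered_orc <- oracle_loglik - max(oracle_loglik)
    expect_equal(unname(centered_lod), centered_orc, tolerance = 1e-9)
  }
})

test_that("Delta critical values behave as expected in limiting cases", {
  q <- seq(0.2, 0.8, length.out = 100)
  # all fathers sampled, no error, informative panel: every best candidate
  # is the father, so even Delta* = 0 meets the 95% level
  p_easy <- likelihood_sim_params(prop_loci_typed = 1,
                                  genotyping_error_rate = 0,
                                  n_simulated_offspring = 150,
                                  n_candidate_fathers = 8,
                                  prop_fathers_sampled = 1,
                                  min_typed_loci = 5)
  cr <- simulate_delta_criticals(q, p_easy, seed = 5)
  expect_equal(cr$strict, 0)
  expect_equal(cr$success_rate, 1)
  # determinism under seed
  cr2 <- simulate_delta_criticals(q, p_easy, seed = 5)
  expect_identical(cr, cr2)
  # higher genotyping error on a sparse panel demands a larger Delta*
  q10 <- seq(0.3, 0.7, length.out = 10)
  p_lo <- likelihood_sim_params(prop_loci_typed = 1,
                                genotyping_error_rate = 0.01,
                                n_simulated_offspring = 2000,
                                n_candidate_fathers = 10,
                                prop_fathers_sampled = 0.9,
                                min_typed_loci = 2)
  p_hi <- utils::modifyList(p_lo, list(genotyping_error_rate = 0.5))
  class(p_hi) <- "likelihood_sim_params"
  c_lo <- simulate_delta_criticals(q10, p_lo, seed = 7)
  c_hi <- simulate_delta_criticals(q10, p_hi, seed = 7)
  # at 50% genotyping error a 10-locus panel cannot certify 95%
  # confidence at any Delta, so the strict critical value is unattainable
  # (infinite) and in particular exceeds the low-error one
  expect_gt(c_hi$strict, c_lo$strict)
  expect_true(is.finite(c_lo$strict))
})

test_that("likelihood assignment handles single and missing-candidate cases", {
  set.seed(11)
  L <- 50
  q <- runif(L, 0.3, 0.7)
  sire <- rbinom(L, 2L, q)
  off <- rbinom(L, 1L, sire / 2) + rbinom(L, 1L, q)
  blank <- rep(NA_integer_, L)
  geno <- rbind(off = off, S1 = sire, ghost = blank)
  colnames(geno) <- sprintf("L%05d", 1:L)
  panel <- make_parentage_panel(q, colnames(geno))
  res <- assign_likelihood(gm_from(geno), panel, "off", "S1",
                           error_rate = 0,
                           params = likelihood_sim_params(min_typed_loci = 1),
                           criticals = list(strict = Inf, relaxed = 0))
  # single candidate: Delta equals the LOD of the true parent, positive
  expect_equal(res$Delta, res$LOD)
  expect_gt(res$LOD, 0)
  # offspring with all loci missing is unassigned
  res2 <- assign_likelihood(gm_from(geno), panel, "ghost", "S1",
                            error_rate = 0,
                            params = likelihood_sim_params(min_typed_loci = 1),
                            criticals = list(strict = Inf, relaxed = 0))
  expect_true(is.na(res2$sire))
  expect_equal(res2$confidence, "none")
})

test_that("likelihood and APIS recover true sires on a noisy panel; exclusion is exact on clean data", {
  st <- sim_paternity(10, 10, 100, 500, error_rate = 0.01,
                      missing_rate = 0.02, seed = 31)
  panel <- select_parentage_panel(st$gm, st$sires, maf_min = 0.1,
                                  het_min = 0.1)
  expect_gt(nrow(panel), 300)
  lik <- assign_likelihood(st$gm, panel, st$off, st$sires,
                           params = likelihood_sim_params(
                             n_simulated_offspring = 200,
                             n_candidate_fathers = 10),
                           seed = 2)
  expect_gte(mean(lik$sire == st$true_sire, na.rm = TRUE), 0.95)
  apis <- assign_apis(st$gm, panel, st$off, st$sires, st$dams)
  expect_gte(mean(apis$sire == st$true_sire), 0.95)
  # exclusion on error-free truth: true pair has zero incompatibilities
  # and is ranked first for every offspring
  excl <- assign_exclusion(st$truth, panel, st$off[1:40], st$sires, st$dams)
  expect_true(all(excl$best$n_incompatible == 0))
  true_rows <- merge(excl$pairs,
                     data.frame(offspring = st$off[1:40],
                                sire = st$true_sire[1:40],
                                dam = st$true_dam[1:40]))
  expect_true(all(true_rows$n_incompatible == 0))
  expect_true(all(true_rows$rank == 1))
})

test_that("APIS transmission scores match hand enumerations and are order-invariant", {
  # offspring het, sire hom-alt, dam hom-ref everywhere: certainty
  L <- 20
  loci <- sprintf("L%05d", 1:L)
  geno <- rbind(off = rep(1L, L), S = rep(2L, L), D = rep(0L, L),
                S2 = rep(0L, L), D2 = rep(2L, L))
  colnames(geno) <- loci
  panel <- make_parentage_panel(rep(0.5, L), loci)
  r <- assign_apis(gm_from(geno), panel, "off", c("S", "S2"), c("D", "D2"))
  expect_equal(r$mendel1, 1)
  expect_equal(r$sire, "S")
  expect_equal(r$dam, "D")
  # offspring hom-alt, sire hom-alt, dam het: per-locus probability 0.5
  geno2 <- rbind(off = rep(2L, L), S = rep(2L, L), D = rep(1L, L))
  colnames(geno2) <- loci
  r2 <- assign_apis(gm_from(geno2), panel, "off", "S", "D")
  expect_equal(r2$mendel1, 0.5)
  # scores in [0,1]; locus permutation leaves ranking untouched
  st <- sim_paternity(5, 5, 20, 120, seed = 41)
  panel3 <- make_parentage_panel(runif(120, 0.2, 0.8),
                                 colnames(st$gm$geno))
  a <- assign_apis(st$gm, panel3, st$off, st$sires, st$dams)
  perm <- sample(nrow(panel3))
  b <- assign_apis(st$gm, panel3[perm, ], st$off, st$sires, st$dams)
  expect_true(all(a$mendel1 >= a$mendel2 & a$mendel2 >= a$mendel3))
  expect_true(all(a$mendel1 <= 1 & a$mendel3 >= 0))
  expect_true(all(a$delta1 >= 0 & a$delta2 >= 0))
  expect_equal(a$sire, b$sire)
  expect_equal(a$mendel1, b$mendel1)
})

test_that("true-pair incompatibility counts match the genotype-replacement oracle", {
  set.seed(51)
  L <- 300; n <- 200; e <- 0.05
  q <- runif(L, 0.2, 0.8)
  loci <- sprintf("L%05d", 1:L)
  gs <- rbinom(L, 2L, q); gd <- rbinom(L, 2L, q)
  # expected incompatibilities when a fraction e of offspring calls is
  # replaced by a uniform random genotype
  t2 <- function(go, a, b) {
    pa <- a / 2; pb <- b / 2
    c((1 - pa) * (1 - pb), pa * (1 - pb) + pb * (1 - pa), pa * pb)[go + 1]
  }
  p_incomp <- vapply(seq_len(L), function(l)
    mean(vapply(0:2, function(g) t2(g, gs[l], gd[l]) == 0, logical(1))),
    numeric(1))
  expected <- e * sum(p_incomp)
  counts <- integer(n)
  geno <- matrix(NA_integer_, n + 2, L,
                 dimnames = list(c("S", "D", sprintf("o%03d", 1:n)), loci))
  geno["S", ] <- gs; geno["D", ] <- gd
  for (i in 1:n) {
    go <- rbinom(L, 1L, gs / 2) + rbinom(L, 1L, gd / 2)
    flip <- runif(L) < e
    go[flip] <- sample(0:2, sum(flip), replace = TRUE)
    geno[i + 2, ] <- go
  }
  panel <- make_parentage_panel(q, loci)
  excl <- assign_exclusion(gm_from(geno), panel, sprintf("o%03d", 1:n),
                           "S", "D")
  obs <- excl$pairs$n_incompatible
  se <- stats::sd(obs) / sqrt(n)
  expect_lt(abs(mean(obs) - expected), 4 * se + 0.05)
  # single-candidate mismatches: opposing homozygotes only
  opp <- which(gs == 2L)[1]
  off1 <- geno[3, ]
  manual <- sum(abs(geno[3, ] - gs) == 2, na.rm = TRUE)
  expect_equal(unname(excl$single["o001", "S"]), manual)
})

test_that("assignment accuracy is monotone in panel size on nested panels", {
  st <- sim_paternity(8, 8, 60, 1000, error_rate = 0.05, mean_depth = 8,
                      missing_rate = 0.05, seed = 61)
  q <- st$ped  # silence lints
  full <- select_parentage_panel(st$gm, st$sires, maf_min = 0.05,
                                 het_min = 0.05, min_allele_depth = 0)
  acc <- vapply(c(100, 500, nrow(full)), function(k) {
    panel <- full[seq_len(min(k, nrow(full))), ]
    lik <- assign_likelihood(st$gm, panel, st$off, st$sires,
                             params = likelihood_sim_params(min_typed_loci = 5),
                             error_rate = 0.05,
                             criticals = list(strict = Inf, relaxed = 0))
    mean(lik$sire == st$true_sire, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], 0.9)
})

test_that("consensus intersects assignments and reports Venn counts", {
  a <- data.frame(offspring = c("o1", "o2", "o3"),
                  sire = c("S1", "S2", "S3"), stringsAsFactors = FALSE)
  expect_equal(consensus_assignments(a, a)$agreed$offspring, a$offspring)
  b <- data.frame(offspring = c("o1", "o2", "o3"),
                  sire = c("S9", "S8", "S7"), stringsAsFactors = FALSE)
  cons <- consensus_assignments(a, b)
  expect_equal(nrow(cons$agreed), 0L)
  expect_equal(unname(cons$venn["n_disagree"]), 3L)
  # on simulated data the intersection is at least as accurate as either engine
  st <- sim_paternity(8, 8, 60, 400, error_rate = 0.02, seed = 71,
                      missing_rate = 0.02)
  panel <- select_parentage_panel(st$gm, st$sires, maf_min = 0.1,
                                  het_min = 0.1)
  lik <- assign_likelihood(st$gm, panel, st$off, st$sires,
                           criticals = list(strict = Inf, relaxed = 0),
                           params = likelihood_sim_params(min_typed_loci = 5))
  apis <- assign_apis(st$gm, panel, st$off, st$sires, st$dams)
  cons <- consensus_assignments(lik, apis)
  acc_of <- function(df) mean(df$sire ==
    st$true_sire[match(df$offspring, st$off)])
  expect_gte(acc_of(cons$agreed), max(acc_of(lik), acc_of(apis)) - 1e-12)
})
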