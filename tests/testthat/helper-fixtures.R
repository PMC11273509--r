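# Shared fixture builders for the test suite. Everything is generated in
# code at test time; sizes are kept small so the whole suite runs in a
# few minutes.

# genotype_matrix from a bare integer matrix (samples x loci)
gm_from <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%04d", seq_len(ncol(m)))
  genotype_matrix(m, ...)
}

# small fully-divergent herd config: every locus diagnostic, no noise
divergent_config <- function(n_sires = 6, n_dams = 7, n_f1 = 20,
                             n_f2_backcross = 0, n_f2_intercross = 0,
                             n_loci = 200, seed = 101, ...) {
  sim_config(n_sires = n_sires, n_dams = n_dams, n_f1 = n_f1,
             n_f2_backcross = n_f2_backcross,
             n_f2_intercross = n_f2_intercross, n_loci = n_loci,
             frac_fixed_divergent = 1, genotype_error_rate = 0,
             missing_rate = 0, seed = seed, ...)
}

# HWE genotypes for unrelated individuals at given alt frequencies
hwe_genotypes <- function(n, q) {
  t(vapply(seq_len(n), function(i) stats::rbinom(length(q), 2L, q),
           integer(length(q))))
}

# variant-record row with all metrics passing the default hard filter
passing_record <- function(...) {
  rec <- data.frame(chrom = "chr1", pos = 100L, locus = "v1", ref = "A",
                    alt = "G", n_alt = 1L, QUAL = 300, DP = 3000, MQ = 60,
                    QD = 10, FS = 1, SOR = 1, AN = 50, MQ0 = 0,
                    BaseQRankSum = 0, ReadPosRankSum = 0, MQRankSum = 0,
                    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}
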