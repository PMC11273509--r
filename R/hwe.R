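#' Exact test for Hardy-Weinberg equilibrium at a biallelic locus
#'
#' Conditional exact test (Wigginton/Cutler/Abecasis style): given the
#' observed allele counts, the probability of each possible heterozygote
#' count is computed by the exact recurrence, and the two-sided p-value is
#' the summed probability of all configurations no more likely than the
#' observed one.
#'
#' @param n_het observed number of heterozygotes.
#' @param n_hom_ref,n_hom_alt observed numbers of the two homozygotes.
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_het, n_hom_ref, n_hom_alt) {
  stopifnot(n_het >= 0, n_hom_ref >= 0, n_hom_alt >= 0)
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0) return(1)
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # rare-allele count
  # possible heterozygote counts share the parity of `rare`
  het_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- numeric(length(het_vals))
  # start at midpoint and apply the recurrence in both directions
  mid_i <- which.min(abs(het_vals - rare * (2 * n - rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(het_vals)) {
    for (i in mid_i:(length(het_vals) - 1)) {
      h <- het_vals[i]
      hr <- (rare - h) / 2          # rare homozygotes
      hc <- (2 * n - rare - h) / 2  # common homozygotes
      # P(h+2) = P(h) * 4 * hr * hc / ((h+2)*(h+1))
      probs[i + 1] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- het_vals[i]
      hr <- (rare - h) / 2
      hc <- (2 * n - rare - h) / 2
      # P(h-2) = P(h) * h*(h-1) / (4*(hr+1)*(hc+1))
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, het_vals)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}
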