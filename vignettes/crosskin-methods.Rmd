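---
title: "Methods: generation classification and parentage assignment in crossbred herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generation classification and parentage assignment in crossbred herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosskin)
```

## The crossbreeding design and its genetic signal

`crosskin` targets herds built from two divergent founder breeds:
purebred sires of breed A mated to purebred dams of breed B give F1;
F1 females backcrossed to founder sires, or F1 mated among themselves,
give F2. At any locus where the breeds are fixed for opposite alleles,
Mendelian transmission makes the generations separable:

* every F1 is heterozygous;
* a backcross F2 is heterozygous or sire-homozygous, each with
  probability 1/2 per locus;
* an intercross F2 segregates 1:2:1 (so 25 % recessive homozygotes and
  a 3:1 dominant : recessive phenotype ratio).

All downstream statistics are built on this signal. Loci are treated
as unlinked and autosomal: the diagnostic panel is genome-wide and
sparse, so ignoring linkage keeps the per-locus expectations exact at
the cost of slightly understating the variance of ratio statistics for
physically close loci. Sex chromosomes and mitochondria are out of
scope.

## Panel selection

**Generation panel.** A locus is diagnostic when sires are (nearly)
fixed for one allele and dams for the other. With $n_s$ sires the
modal-allele count among sires must fall in $[2n_s - s, 2n_s]$, and
analogously for dams, with the two modal alleles distinct. The slack
default $s = 5$ admits a few discordant allele copies caused by
genotyping error or residual polymorphism (with 24 sires and 28 dams
the windows are 43–48 and 51–56); $s = 0$ demands strict fixation. A
tie for the modal allele means the locus cannot name a diagnostic
allele and it is excluded. Calls with summed allele depth below 6 are
set missing before counting, and a locus is dropped when any founder
call is missing — the windows are defined against complete founder
counts, and tolerating missing founders would silently widen them.
Both behaviours are arguments.

**Parentage panel.** Filters are computed on the sire samples:
minor allele frequency > 0.25, observed heterozygosity > 0.2,
missingness < 0.7, and a two-sided Hardy–Weinberg exact test p > 0.01,
followed by a final depth/missingness screen across all samples.
Observed (not expected) heterozygosity is used because it is what the
genotype calls directly provide; the MAF filter already constrains the
frequency spectrum. The HWE test is the conditional exact test on
heterozygote counts, computed by the standard stable recurrence; the
test suite checks it against full enumeration of the Levene
distribution. All inequalities in both panels — and in the site hard
filter — are applied exactly as written (strict), so threshold-equal
records pass; boundary semantics are asserted in the tests.

## Generation classification

For each offspring, over its non-missing generation-panel calls:
heterozygous ratio = H/n, paternal ratio = PGL/n, maternal ratio =
MGL/n, where PGL/MGL are calls homozygous for the sire-/dam-diagnostic
allele. The decision rule is: het ratio > 0.5 → F1; otherwise F2, with
paternal ratio > 0.5 → MSF2, maternal ratio > 0.5 → MDF2, and the
remainder split LSF2/LDF2 by which parental ratio is larger (an exact
tie goes to LSF2 and is flagged). The F1 rule is strict, so a ratio of
exactly 0.5 is F2.

Two properties matter for interpreting results. First, error-free F1
at strictly divergent loci have het ratio exactly 1, so F1 recall is
perfect in the noise-free limit. Second, backcross F2 have het ratio
distributed Binomial(L, 1/2)/L: the "> 0.5" line cuts that
distribution through its centre, so F1-versus-F2 accuracy for pure
backcross animals is $P(\mathrm{Bin}(L, 1/2) \le L/2)$ — about 0.54 at
100 loci and 0.51 at 1000 — and *approaches one half from above* as
the panel grows, rather than improving. The classifier's value for
backcross F2 lies in the paternal/maternal split (MSF2 versus the
rest), not in the F1/F2 line; the tests assert the exact binomial
behaviour rather than a spurious accuracy claim.

## Relatedness

**Method-of-moments IBD.** For a pair, the counts of loci
identical-by-state at 0/1/2 alleles are equated to their expectations
given allele frequencies under IBD states 0/1/2 and solved
sequentially for $\hat P_0, \hat P_1, \hat P_2$ (the genome-wide
moments estimator with PLINK `--genome` semantics; the hidden-Markov
formulation some tools mention is a different, linkage-aware
estimator and is not what produces the standard PI_HAT). Estimates
are clamped to $[0,1]$ and renormalised onto the simplex;
$\hat\pi = \hat P_2 + \hat P_1/2$. Frequencies default to
founder-derived estimates. Expected bands — 1 for duplicates, 0.5 for
parent–offspring, 0.25 for half-sibs, 0 for unrelated — are recovered
within 0.02–0.03 at 5,000 loci.

**Kinship.** Centered-IBS / VanRaden: mean-impute missing calls,
centre by twice the allele frequency, normalise the cross-product by
the summed per-locus binomial variance. The unscaled matrix is on the
kinship-coefficient scale (parent–offspring ≈ 0.25); `times_two =
TRUE` (the default) doubles it to expected covariances
(parent–offspring ≈ 0.5), which is the scale used when comparing
candidate relatives.

**Distances and trees.** The p-distance is the allele-sharing dialect:
0 / 0.5 / 1 per locus for identical / one-shared-allele / opposite
genotypes, averaged over pairwise-complete loci. Neighbor joining is
the Saitou–Nei algorithm with the Studier–Keppler criterion;
selection ties break to the lowest pair index so results are
deterministic, and for additive inputs the tree is recovered exactly
(checked against path-length matrices and against `ape::nj`).
Negative branch lengths, which arise for non-additive inputs, are
kept by default; `clamp_negative = TRUE` zeroes them while preserving
the pair distance, recording how many were clamped.

## Parentage assignment

**Likelihood engine.** At each locus the ratio of
P(offspring | candidate is parent) to P(offspring | unrelated) uses
single-parent transmission with the missing parental allele drawn from
the population, or pair transmission when the dam is known.
Genotyping error mixes the transmission probability with the
Hardy–Weinberg genotype probability at rate $e$: the ratio is exactly
1 when $e = 1$ (no information) and never collapses to 0 when
$e > 0$. With $e = 0$ an impossible transmission gives a per-locus
log-ratio floored at $\log 10^{-9}$ so a single opposing homozygote
cannot erase an otherwise overwhelming score. LOD is the summed log
ratio; Delta is the gap to the second-best candidate (for a single
candidate, Delta = LOD). Confidence tiers come from a pre-assignment
simulation: offspring are generated from fathers who are in the
candidate set with probability `prop_fathers_sampled`, scored
identically, and the smallest Delta whose acceptance set reaches the
strict (95 %) or relaxed (80 %) correct-assignment proportion becomes
the critical value. When no Delta achieves the level (e.g. 50 % error
on a 10-locus panel) the critical value is infinite and no assignment
earns that tier. Simulation defaults mirror common herd practice
(30 % loci typed, 0.01 % error, 10,000 offspring, 50 candidate
fathers, 90 % sampled, ≥ 10 typed loci); a few thousand simulated
offspring already give stable criticals, and the test suite uses
150–2,000 to stay fast.

**Transmission engine.** Every sire × dam pair is scored by the mean
per-locus Mendelian probability of the offspring genotype. Because the
score is a mean, incompatible loci lower it smoothly — robustness to
genotyping error without an explicit error model. The top three pair
scores give mendel1–3 and delta1/delta2; assignment acceptance keeps
pairs whose delta1 clears the `accepted_error_rate` quantile of the
empirical delta1 distribution, an intentionally simple calibration:
the offspring least separated from their runner-up pair are the likely
errors, so rejecting that fraction targets the requested error rate.
The default rate is 0.05.

**Exclusion engine.** Counts loci where the offspring genotype has
zero probability under the pair (and, per single candidate, opposing
homozygotes). Ranking is by ascending incompatibility count. This is
the most error-sensitive engine by construction — each miscall can
manufacture an incompatibility — which is why the consensus step
intersects the two score-based engines instead.

**Consensus.** The intersection of likelihood and transmission
assignments on (offspring, sire), with Venn counts. On simulated data
the intersection's accuracy is at least the better engine's, at the
cost of unassigned offspring where they disagree.

## The synthetic herd

`simulate_herd()` emulates the study design: 24 sires, 28 dams, 615
F1 and 308 F2 by default. The F2 split (224 backcross, 84 intercross)
follows the relative abundance of paternal-leaning versus
maternal-leaning F2 subclasses observed in such herds; the true split
is not knowable from classified counts alone, so these defaults are
approximate by construction. A fraction `frac_fixed_divergent`
(default 0.3) of loci is fixed for opposite alleles between breeds;
the rest draw breed-specific frequencies from configurable
distributions. Observation noise is RAD-like: Poisson depth (mean 20),
per-read allele flips (default 0.001), naive calling (both alleles
seen ⇒ heterozygote), dropout at depth 0 plus a flat missing rate
(default 0.05). A constant-depth override exists so calibration
checks can condition on depth exactly.

What the generator does *not* emulate: linkage and recombination maps,
restriction-site dropout correlated across samples (null alleles),
allele-specific bias, contamination, and population structure beyond
the two founder breeds. Passing tests therefore demonstrate
correctness of the algorithms under idealised RAD noise, not
robustness to null-allele-rich real data — on real herds, depth-based
masking and the consensus step carry that burden.

## Numerical choices and problem sizes

Degenerate inputs fail fast: empty founder sets, offspring with zero
genotyped panel loci, pairs with no co-called loci, trees with fewer
than three leaves, frequencies outside (0, 1). Monomorphic loci are
skipped by the IBD estimator; all-missing loci are dropped by the
kinship matrix. Determinism is end-to-end: every stochastic function
takes a seed, and the pipeline manifest records md5 checksums so
reruns are verifiable byte-for-byte.

The validation suite runs at desk scale, chosen to keep the full test
run under a minute while leaving 4-standard-deviation binomial bands
narrow: 1,000-locus divergent panels with 100–200 offspring for the
Mendelian checks, 5,000 loci for the π̂ bands, 10,000 offspring for
the single-locus phenotype ratio, 100 random trees (n ≤ 12) for exact
NJ recovery, and 500-SNP panels with 100 offspring and 24 candidate
sires for the ≥ 95 % assignment checks.
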