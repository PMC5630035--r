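---
title: "Methods: regional missense constraint and gene-specific pathogenicity models"
author: "mtrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional missense constraint and gene-specific pathogenicity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrtools)
```

# The model

## Missense Tolerance Ratio

For a protein-coding transcript with $L$ codons, every codon $i$ receives a
window $W_i = [\max(1, i-15),\ \min(L, i+15)]$ — 31 codons, 93 coding
nucleotides, truncated at the transcript ends. Within the window we count
distinct observed missense ($D_n$) and synonymous ($D_s$) variant sites from
a population reference sample, and the corresponding counts of *possible*
single-nucleotide changes ($P_n$, $P_s$) under the standard genetic code,
taking every substitution as equally likely. The Missense Tolerance Ratio is

$$\mathrm{MTR}_i \;=\; \frac{D_n / (D_n + D_s)}{P_n / (P_n + P_s)}.$$

The numerator is the observed missense proportion; the denominator is the
proportion expected under neutrality given the window's sequence
composition, so the codon usage of a region cannot masquerade as
constraint. MTR $<1$ indicates preferential depletion of missense variation,
the footprint of purifying selection. The classical alternative,
$\log(d_N/d_S)$, is undefined whenever $D_n = 0$ or $D_s = 0$ — common at
window scale — whereas the MTR remains defined whenever any variant is
observed; `computeLogDnds()` is provided for comparison, and on simulated
transcripts the two are very strongly rank-correlated where both exist
(the test suite requires Spearman $\rho > 0.9$).

Assumptions worth stating plainly:

- **Equal mutability.** All nine substitutions of a base are treated as
  equally likely when computing $P_n/(P_n+P_s)$. Transition/transversion and
  CpG effects are real but largely cancel in the ratio because numerator
  and denominator share the window's sequence; a mutation-rate-weighted
  denominator is a natural extension hook but is not implemented.
- **Site counting.** $D_n$ and $D_s$ count distinct variant sites
  (position + alternate allele), not allele counts: a common polymorphism
  and a singleton contribute equally. Duplicated records collapse on
  ingestion.
- **Both-zero windows.** A window with no observed variant at all has an
  undefined (NA) MTR. Such windows are excluded from percentile thresholds,
  deviation tests and downstream rank tests rather than imputed, because a
  0/0 proportion carries no information about depletion.

## Deviation test, FDR, and gene thresholds

Each window with $D_n + D_s \ge 1$ is tested against MTR $=1$ with a
two-sided exact binomial test of $D_n$ successes in $D_n+D_s$ trials at
$p_0 = P_n/(P_n+P_s)$, using the minimum-likelihood-sum convention for the
two-sided tail (the convention of `binom.test`); the sidedness is a
definitional choice — depletion *and* excess both deviate from neutrality.
P-values are adjusted by Benjamini–Hochberg across the family of all
windows of all transcripts in a run (`adjustFdrAcrossTracks()`); a per-gene
family is available by configuration. NA p-values pass through unadjusted
and do not count toward the family size.

Because "depleted" is only meaningful relative to a gene's own landscape,
each track also carries empirical percentile thresholds (5th, 25th, 50th by
default) of its defined per-codon MTR values, computed with linear
interpolation (`quantile` type 7) over codon-level values — one value per
codon, not per unique window, so long uniform stretches weight the
percentiles the way they occupy the protein.

## Control stratification and pathogenic qualification

Population controls come from two nested reference releases and form three
mutually exclusive groups of presumed-benign missense variants: (1)
singletons of the first release; (2) singletons of the second, larger
release that were absent at any frequency from the first; (3) non-singleton
second-release variants with MAF $< 0.05\%$ in each of seven ancestry
populations, excluding members of the first two groups. Missing population
frequencies make Group-3 evaluation an explicit error rather than a silent
pass; when only population allele counts are available the frequency is
their ratio, and a population with zero genotyped alleles conservatively
fails the screen.

Pathogenic candidates first pass a database screen (ClinVar Pathogenic /
Likely Pathogenic / their combination, HGMD DM, with consensus required
when both report) plus phenotype keyword matching (case-insensitive
substrings; the `glucose` keyword applies only to *SLC2A1*). Screened
records are **qualified** when the variant arose de novo, or segregated in
all of more than three genotyped affected carriers with no genotyped
affected non-carrier and at most one genotyped unaffected carrier.
Qualification is monotone in evidence: adding a de novo observation can
never demote a record.

## Gene-specific probability of pathogenicity (GPP)

Feature hygiene runs in a fixed order — impute, variance-prune,
correlation-prune, importance, selection — enforced by `runGppPipeline()`:

1. **Imputation.** Missing rank scores are replaced by the per-gene,
   per-feature median of annotated values; a feature with no annotated
   value in a gene is an error, not a zero.
2. **Near-zero variance.** A feature is dropped when its most-common /
   second-most-common value ratio exceeds 4 (80/20) *and* fewer than 5% of
   its values are distinct; this delegates to `caret::nearZeroVar`, the
   reference implementation of that rule.
3. **Correlation pruning.** While any pair of remaining features has
   $|r| > 0.75$, the member with the larger mean absolute correlation
   against the remaining set is removed and the means recomputed
   (`caret::findCorrelation`, `exact = TRUE`).
4. **Shadow importance.** Each of `runs` random forests sees every real
   feature alongside a shadow copy (its values permuted across variants).
   The scaled out-of-bag mean-decrease-in-accuracy importance is the
   feature's Z-score. A feature that beats the run-wise max-shadow Z
   significantly more often than chance (one-sided binomial against 0.5,
   Bonferroni-corrected across features at $\alpha = 0.05$) is
   *informative*; losing significantly more often makes it
   *uninformative*; otherwise *inconclusive*. *Highly informative*
   additionally requires the feature's minimum non-outlier Z (boxplot
   convention: within 1.5 IQR of the quartiles) to exceed the maximum
   shadow Z across all runs. Defaults mirror the published analysis: seed
   15, 1000 runs, 500 trees, `mtry` 4.
5. **Stepwise logistic selection.** Starting from the raw codon MTR (when
   the gene passed the MTR quartile screen at $p < 0.0045$) or the
   intercept, candidates enter in importance order. A candidate model is
   accepted only when the Akaike relative likelihood of the incumbent,
   $\exp((\mathrm{AIC}_{new}-\mathrm{AIC}_{old})/2)$, is at most 0.05 —
   i.e. the larger model must make the incumbent implausible — and
   selection halts at the first rejection; after each acceptance every
   included feature is re-tested for removal under the same criterion.
   The stop rule is the standard likelihood reading of "no longer likely
   ($P > 0.05$) to reduce information loss"; no formula was published, so
   the relative-likelihood interpretation is adopted and the trace records
   every decision. The MTR enters as a raw value, not a percentile; the fit
   learns its sign.

The fitted model yields the GPP score,
$\mathrm{logit}^{-1}(\beta_0 + \sum_i \beta_i X_i)$, strictly inside
$(0,1)$. Training AUC is the rank-based probability that a random case
outscores a random control, ties counting one half (equal to the
Mann–Whitney $U$ over $n_1 n_0$). A *global* mode pools all genes' labeled
rows through the identical selection path into one shared model.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `windowRadius` | 15 codons | flank either side of the index codon; 31-codon window |
| FDR scope | study | BH family = all windows of the run |
| percentiles | 5/25/50 | gene-specific depletion thresholds |
| quartile-test $p_0$ | 0.25 | null in-quartile proportion; `"possible"` mode reweights by missense opportunity per codon |
| Group-3 MAF | 0.05% | per-population rarity ceiling |
| importance seed/runs/trees/mtry | 15 / 1000 / 500 / 4 | shadow-importance forest settings |
| stop rule $\alpha$ | 0.05 | relative-likelihood acceptance threshold |
| MTR screen $\alpha$ | 0.0045 | quartile-test p below which MTR seeds the gene model |

The quartile test defaults to the one-sided greater-enrichment alternative
(enrichment is the directional claim); the rank and presence tests are
two-sided comparisons. "Within the quartile" means codon MTR at or below
the threshold — ties side with depletion. The quartile test counts distinct
case variants, not distinct codons, so recurrently hit codons weigh by
their variant count.

# The synthetic-data generator

`simulationConfig()` defaults describe one realistic study condition and
are not meant to be fitted: a 300-codon transcript; a single central region
(codons 121–180) retaining 20% of its missense observation probability;
per-possible-SNV observation probability 0.035, which yields roughly ten
observed variants per 31-codon window — the capture rate of a reference
cohort of about sixty thousand exomes; an allele-count spectrum with 70%
singletons and a geometric tail; 2% of sites failing QC; Beta(20, 2)
per-site coverage fractions; pathogenic variants drawn 80% from the
depleted region with 60% carrying qualifying evidence. Feature matrices
plant class-shifted normal features mapped to rank scores, so a planted
separation $d$ implies a single-feature AUC near $\Phi(d/\sqrt2)$.

The generator emulates the *structure* of reference-cohort data — site
tables with counts, frequencies and QC flags; evidence records; rank-score
matrices — not its population genetics. There is no linkage, no
trinucleotide mutation-rate variation, no ancestry structure, no
correlation between features beyond what is planted, and depletion is a
step function rather than a selection gradient. Passing tests therefore
demonstrate that the estimators recover what was planted under honest
sampling noise at realistic depth; they do not certify performance on real
cohort data, where coverage artifacts, annotation disagreements and feature
redundancy are harsher.

# Numerical choices and degenerate inputs

- Exact binomial and hypergeometric tails come from `binom.test` /
  `fisher.test`; the Mann–Whitney test uses the exact null only when the
  combined sample is at most 25 with no ties, otherwise the normal
  approximation with tie correction.
- Windowed tallies are integer cumulative-sum differences; equality with a
  naive per-codon recount is asserted exactly in the tests, not within a
  tolerance.
- Complete separation in small logistic fits falls back to a weakly
  ridge-penalized IRLS fit ($\lambda = 10^{-3}$, intercept unpenalized),
  with the unpenalized log-likelihood used for AIC bookkeeping and the
  fallback noted in the selection trace.
- Coverage positions absent from the track contribute zero to the codon
  mean and flag the codon `incomplete` instead of dropping it — thin
  coverage should look alarming, not invisible.
- Minus-strand transcripts hold their CDS on the coding strand; VCF
  alleles are reverse-complemented on ingestion, and the CDS/genome maps
  are asserted to be mutual inverses.
- Singleton status is global allele count exactly 1 as reported;
  hemizygous sites are taken at face value.

# Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` run entirely on generated data,
sized for quick iteration: oracle recounts on 50 transcripts of 40–100
codons; calibration and region-recovery at 20 replicates of 200–300
codons; shadow-importance recovery with 20 forest runs of 100 trees on 300
variants per class; logistic recovery at $n = 2000$. The importance
defaults (1000 runs, 500 trees) are what an analysis run should use; the
reduced settings are for verification loops, and the binomial hit test
adapts its threshold to the run count.

# Known limitations

- Window size is fixed; a 31-codon window smooths over critical regions
  shorter than ~15 codons, and terminal windows rest on fewer sites.
- At singleton-heavy depth the MTR of a sparse window is noisy and
  slightly coarse (a one-variant window can only take a handful of
  values); gene-level percentile thresholds inherit that noise.
- The equal-mutability denominator ignores context-dependent mutation
  rates; regions rich in hypermutable contexts are mildly mis-calibrated.
- The qualification rules automate written segregation criteria; free-text
  curation (e.g. reviewing "not provided" database entries) cannot be
  reproduced mechanically.
- GPP models are only as transferable as their training labels; the
  package deliberately refits per gene rather than shipping coefficients.
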