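# mtrtools

Regional missense constraint and gene-customized missense variant
interpretation.

## The problem

When a new missense variant turns up in an established disease gene, most of
the evidence a clinical geneticist can lean on is variant-level: database
reports, segregation data, in-silico deleteriousness scores. Large reference
cohorts of human standing variation add a complementary, *regional* signal:
within a gene, some stretches of protein tolerate missense change freely
while others are almost devoid of it, because purifying selection has
removed carriers. Pathogenic missense variants cluster in the depleted
stretches. `mtrtools` quantifies this signal and folds it, together with
empirically selected in-silico features, into per-gene logistic models of
pathogenicity. It is aimed at researchers building gene-specific variant
interpretation pipelines, and ships a synthetic-data generator so every
stage can be exercised and validated without access to restricted variant
databases.

## The statistic

The **Missense Tolerance Ratio (MTR)** is computed over a sliding window of
31 codons (the index codon and 15 codons either side):

    MTR = [ mis_obs / (mis_obs + syn_obs) ] / [ mis_pos / (mis_pos + syn_pos) ]

where `mis_obs`, `syn_obs` count distinct observed missense and synonymous
variant sites in the window and `mis_pos`, `syn_pos` count all possible
missense and synonymous single-nucleotide changes under the standard genetic
code, each taken as equally likely. MTR = 1 means the window carries exactly
the missense fraction expected under neutrality; values below 1 indicate
missense depletion. Unlike log(dN/dS) the ratio stays defined when either
observed count is zero, while remaining tightly rank-correlated with it.
Each window gets a two-sided exact binomial test against MTR = 1, with
Benjamini–Hochberg FDR control applied study-wide across all windows of a
run, and each gene gets empirical 5th/25th/50th-percentile MTR thresholds.

Around the statistic, the package implements the full interpretation
workflow:

- transcript models with CDS/genome coordinate maps and exhaustive
  possible-SNV enumeration (`buildTranscriptModel`, `enumeratePossibleSnvs`);
- ingestion of standing-variation VCF/TSV tables, stratification of control
  variants into three mutually exclusive frequency-defined groups, and
  qualification of pathogenic-reported variants by de novo / segregation
  evidence (`readVariantTable`, `assignControlGroups`, `qualifyPathogenic`);
- enrichment statistics: lowest-quartile binomial test, case–control
  Mann–Whitney comparison of codon MTRs, Fisher presence tests
  (`quartileEnrichmentTest`, `mtrRankTest`, `presenceFisherTest`);
- gene-specific probability of pathogenicity (GPP) models: per-gene median
  imputation, near-zero-variance and correlation pruning, shadow-feature
  random-forest importance screening, and forward–backward AIC stepwise
  logistic selection (`runGppPipeline`, `selectGeneModel`, `scoreGpp`);
- a seeded synthetic-data generator for transcripts, standing variation with
  planted regional depletion, pathogenic evidence records and feature
  matrices (`simulationConfig`, `writeFixtureSet`).

## Worked example

Simulate a 300-codon gene whose central codons 121–180 retain only 20% of
their missense variation, survey it at reference-cohort depth, and test
whether pathogenic variants concentrated there are recoverable:

```r
library(mtrtools)

cfg   <- simulationConfig(seed = 7)
model <- simulateTranscript(cfg)
sites <- simulateStandingVariation(model, cfg)
track <- computeMtrTrack(model, sites,
                         coverage = simulateCoverageTrack(model, cfg))
track
#> MtrTrack for simTx: 300 codons, window radius 15
#>   MTR median 0.683 [range 0.000-1.368], 298/300 windows estimable
#>   percentile thresholds: 5%=0.304, 25%=0.551, 50%=0.683

evidence <- simulatePathogenicVariants(model, cfg, 40)
table(qualifyPathogenic(evidence))
#>               qualified             unqualified not_pathogenic_reported
#>                      25                      15                       0

report <- runEvaluation(model, track, evidence, sites)
report[, c("n_qualified", "quartile_k", "quartile_n", "quartile_p",
           "case_median_mtr", "control_median_mtr", "rank_p")]
#>   n_qualified quartile_k quartile_n quartile_p case_median_mtr
#> 1          25          9         25  0.1494377       0.5964654
#>   control_median_mtr      rank_p
#> 1          0.9499637 0.002998474
```

The 25 qualified pathogenic variants sit at a median codon MTR of 0.60
against 0.95 for the standing-variation controls — the rank test sees the
planted clustering (p = 0.003) even at a depth (~10 variants per window)
where the lowest-quartile membership test on 25 cases does not reach
significance. `plotMtrTrack(track)` draws the track with the percentile
thresholds, FDR < 0.05 windows and the coverage trace.

A command-line wrapper over the same functions is installed at
`system.file("scripts", "mtrtool.R", package = "mtrtools")` with
subcommands `simulate`, `mtr`, `evaluate` and `gpp`.

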