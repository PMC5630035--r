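NONSTOP_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = ""),
  STOP_CODONS)

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults describe a
#' mid-sized constrained gene surveyed at the depth of a large exome
#' reference cohort: a 300-codon transcript; one central region retaining
#' 20\% of its missense variation; a per-possible-SNV observation
#' probability of 0.035, which yields roughly 10 observed variants per
#' 31-codon window, the capture rate reported for a ~60k-exome cohort; an
#' allele-count spectrum heavily skewed to singletons (70\% singletons with
#' a geometric tail); and pathogenic variants drawn preferentially (80\%)
#' from the depleted region, of which 60\% carry qualifying de novo or
#' segregation evidence.
#'
#' @param seed integer RNG seed.
#' @param transcriptLengthCodons protein length L of the simulated
#'   transcript.
#' @param depletionRegions data.frame with columns `codon_lo`, `codon_hi`,
#'   `missense_retention` (fraction of missense observation probability
#'   retained inside the region, in `[0, 1]`).
#' @param siteVariationProb per-possible-SNV probability of being observed
#'   as standing variation.
#' @param pathogenicConcentration fraction of pathogenic variants drawn from
#'   depleted regions.
#' @param qualifiedShare fraction of pathogenic records given qualifying
#'   evidence.
#' @param singletonProb probability an observed site is a singleton
#'   (AC = 1); the remainder get `1 + Geometric(acTailProb)` extra alleles.
#' @param acTailProb geometric tail parameter of the allele-count spectrum.
#' @param alleleNumber total chromosomes genotyped (AN).
#' @param qcFailRate fraction of simulated sites flagged as failing QC.
#' @param coverageShape1,coverageShape2 Beta parameters of the per-site
#'   >= 10x coverage fraction.
#' @param nExons number of exon blocks the CDS is split into.
#' @param strand strand of the simulated transcript.
#' @param gcBias codon-composition bias: sampling weight of a codon is
#'   proportional to `exp(gcBias * #GC bases)`; 0 gives uniform codon usage.
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             transcriptLengthCodons = 300L,
                             depletionRegions = data.frame(
                               codon_lo = floor(0.4 * transcriptLengthCodons) + 1L,
                               codon_hi = floor(0.6 * transcriptLengthCodons),
                               missense_retention = 0.2),
                             siteVariationProb = 0.035,
                             pathogenicConcentration = 0.8,
                             qualifiedShare = 0.6,
                             singletonProb = 0.7,
                             acTailProb = 0.5,
                             alleleNumber = 121412L,
                             qcFailRate = 0.02,
                             coverageShape1 = 20,
                             coverageShape2 = 2,
                             nExons = 3L,
                             strand = "+",
                             gcBias = 0) {
  cfg <- list(seed = as.integer(seed),
              transcriptLengthCodons = as.integer(transcriptLengthCodons),
              depletionRegions = depletionRegions,
              siteVariationProb = siteVariationProb,
              pathogenicConcentration = pathogenicConcentration,
              qualifiedShare = qualifiedShare,
              singletonProb = singletonProb,
              acTailProb = acTailProb,
              alleleNumber = as.integer(alleleNumber),
              qcFailRate = qcFailRate,
              coverageShape1 = coverageShape1,
              coverageShape2 = coverageShape2,
              nExons = as.integer(nExons),
              strand = strand,
              gcBias = gcBias)
  dr <- cfg$depletionRegions
  if (nrow(dr)) {
    stopifnot(all(dr$codon_lo >= 1L),
              all(dr$codon_hi <= cfg$transcriptLengthCodons),
              all(dr$codon_lo <= dr$codon_hi),
              all(dr$missense_retention >= 0 & dr$missense_retention <= 1))
  }
  stopifnot(cfg$siteVariationProb >= 0, cfg$siteVariationProb <= 1,
            cfg$pathogenicConcentration >= 0,
            cfg$pathogenicConcentration <= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

inDepletionRegion <- function(codon, config) {
  dr <- config$depletionRegions
  out <- rep(FALSE, length(codon))
  for (i in seq_len(nrow(dr))) {
    out <- out | (codon >= dr$codon_lo[i] & codon <= dr$codon_hi[i])
  }
  out
}

missenseRetention <- function(codon, config) {
  ret <- rep(1, length(codon))
  dr <- config$depletionRegions
  for (i in seq_len(nrow(dr))) {
    hit <- codon >= dr$codon_lo[i] & codon <= dr$codon_hi[i]
    ret[hit] <- dr$missense_retention[i]
  }
  ret
}

#' Simulate a random protein-coding transcript
#'
#' Draws codons from the 61 non-stop codons (uniformly, or weighted by GC
#' content under `gcBias`), appends a stop codon, and splits the CDS into
#' `nExons` exon blocks separated by random intron gaps on a synthetic
#' chromosome. Deterministic under the config seed.
#'
#' @param config a [simulationConfig()].
#' @param transcriptId identifier for the simulated transcript.
#' @return a [TranscriptModel-class].
#' @export
simulateTranscript <- function(config, transcriptId = "simTx") {
  set.seed(config$seed)
  L <- config$transcriptLengthCodons
  w <- if (config$gcBias == 0) NULL else {
    gc <- vapply(strsplit(NONSTOP_CODONS, ""),
                 function(b) sum(b %in% c("G", "C")), numeric(1L))
    exp(config$gcBias * gc)
  }
  codons <- sample(NONSTOP_CODONS, L, replace = TRUE, prob = w)
  cds <- paste0(paste0(codons, collapse = ""), "TAA")
  n <- nchar(cds)
  k <- max(1L, min(config$nExons, n %/% 2L))
  cuts <- if (k > 1L) sort(sample(seq_len(n - 1L), k - 1L)) else integer(0)
  lens <- diff(c(0L, cuts, n))
  gaps <- if (k > 1L) sample(50:500, k - 1L, replace = TRUE) else integer(0)
  starts <- integer(k)
  ends <- integer(k)
  pos <- 1001L
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + lens[i] - 1L
    pos <- ends[i] + (if (i < k) gaps[i] else 0L) + 1L
  }
  buildTranscriptModel(transcriptId, cds, starts, ends,
                       geneSymbol = transcriptId, chromosome = "chrS",
                       strand = config$strand)
}

acSpectrum <- function(n, config) {
  singleton <- runif(n) < config$singletonProb
  ac <- rep(1L, n)
  extra <- sum(!singleton)
  if (extra) ac[!singleton] <- 2L + rgeom(extra, config$acTailProb)
  ac
}

#' Simulate standing variation over a transcript
#'
#' Every possible SNV of the transcript is observed independently with
#' probability `siteVariationProb`, multiplied by the region's
#' `missense_retention` when the SNV is missense and falls inside a planted
#' depletion region; synonymous (and nonsense) sites are unaffected by
#' depletion. Observed sites receive an allele count from the
#' singleton-skewed spectrum, uniform per-population allele frequencies
#' `AC/AN`, and a QC flag failing at `qcFailRate`.
#'
#' @param model a [TranscriptModel-class].
#' @param config a [simulationConfig()].
#' @param seed RNG seed (default: `config$seed + 1`).
#' @param cohortTag cohort tag stamped on the sites.
#' @return variant-site data.frame in the [readVariantTable()] layout.
#' @export
simulateStandingVariation <- function(model, config,
                                      seed = config$seed + 1L,
                                      cohortTag = "v2") {
  set.seed(seed)
  poss <- enumeratePossibleSnvs(model)
  pObs <- rep(config$siteVariationProb, nrow(poss))
  isMis <- poss$consequence == "missense"
  pObs[isMis] <- pObs[isMis] *
    missenseRetention(poss$codon_index[isMis], config)
  keep <- runif(nrow(poss)) < pObs
  sites <- poss[keep, , drop = FALSE]
  n <- nrow(sites)
  sites$AC <- acSpectrum(n, config)
  sites$AN <- rep(config$alleleNumber, n)
  af <- sites$AC / sites$AN
  for (col in afColumns()) sites[[col]] <- af
  sites$qc_pass <- runif(n) >= config$qcFailRate
  sites$cohort_tag <- rep(cohortTag, n)
  rownames(sites) <- NULL
  sites
}

QUALIFYING_PHENOTYPES <- c("Dravet syndrome", "early infantile epileptic encephalopathy",
                           "infantile spasms", "febrile seizures")
OTHER_PHENOTYPES <- c("migraine", "intellectual disability", "ataxia")

#' Simulate pathogenic-candidate variant records
#'
#' Samples `n` missense substitutions, a fraction `pathogenicConcentration`
#' of them uniformly from depleted-region missense SNVs and the remainder
#' uniformly from the rest of the transcript, and attaches evidence fields
#' so that approximately `qualifiedShare` of the records meet the
#' qualification criteria (de novo, or segregation in > 3 affected carriers
#' with no affected non-carrier and at most one unaffected carrier).
#'
#' @param model a [TranscriptModel-class].
#' @param config a [simulationConfig()].
#' @param n number of records.
#' @param seed RNG seed (default: `config$seed + 2`).
#' @return evidence-record data.frame (see [qualifyPathogenic()]), with the
#'   planted `codon_index` and a `from_depleted_region` flag.
#' @export
simulatePathogenicVariants <- function(model, config, n,
                                       seed = config$seed + 2L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  poss <- enumeratePossibleSnvs(model)
  mis <- poss[poss$consequence == "missense", , drop = FALSE]
  inRegion <- inDepletionRegion(mis$codon_index, config)
  fromRegion <- runif(n) < config$pathogenicConcentration
  if (!any(inRegion)) fromRegion[] <- FALSE
  if (all(inRegion)) fromRegion[] <- TRUE
  pick <- integer(n)
  pick[fromRegion] <- sample(which(inRegion), sum(fromRegion), replace = TRUE)
  pick[!fromRegion] <- sample(which(!inRegion), sum(!fromRegion),
                              replace = TRUE)
  v <- mis[pick, , drop = FALSE]
  qualified <- runif(n) < config$qualifiedShare
  deNovo <- qualified & runif(n) < 0.7
  pedigree <- qualified & !deNovo
  rec <- data.frame(
    transcript_id = v$transcript_id,
    codon_index = v$codon_index,
    genomic_pos = v$genomic_pos,
    ref = v$ref, alt = v$alt,
    classification_clinvar = sample(c("Pathogenic", "Likely Pathogenic"),
                                    n, replace = TRUE),
    classification_hgmd = rep("DM", n),
    phenotype_terms = sample(QUALIFYING_PHENOTYPES, n, replace = TRUE),
    de_novo = deNovo,
    n_affected_genotyped_carriers = ifelse(pedigree, 4L + rbinom(n, 3L, 0.5),
                                           ifelse(deNovo, 1L,
                                                  rbinom(n, 3L, 0.7))),
    n_affected_genotyped_noncarriers = ifelse(qualified, 0L, rbinom(n, 2L, 0.4)),
    n_unaffected_genotyped_carriers = ifelse(qualified, rbinom(n, 1L, 0.3),
                                             rbinom(n, 3L, 0.5)),
    from_depleted_region = inDepletionRegion(v$codon_index, config),
    stringsAsFactors = FALSE)
  # evidence intended to be non-qualifying must not qualify by accident:
  # cap affected carriers at 3 for the non-qualified share
  nq <- !qualified
  rec$n_affected_genotyped_carriers[nq] <-
    pmin(rec$n_affected_genotyped_carriers[nq], 3L)
  rownames(rec) <- NULL
  rec
}

#' Simulate a per-site coverage track
#'
#' Per-site fractions of samples at >= 10-fold coverage, drawn from a Beta
#' distribution over all CDS positions of the transcript.
#'
#' @param model a [TranscriptModel-class].
#' @param config a [simulationConfig()].
#' @param seed RNG seed (default: `config$seed + 3`).
#' @return coverage data.frame (`chrom`, `pos`, `frac_ge_10x`).
#' @export
simulateCoverageTrack <- function(model, config, seed = config$seed + 3L) {
  set.seed(seed)
  pos <- sort(model@genomicPos)
  data.frame(chrom = model@chromosome, pos = pos,
             frac_ge_10x = rbeta(length(pos), config$coverageShape1,
                                 config$coverageShape2))
}

#' Simulate a labeled variant-by-feature rank-score matrix
#'
#' Informative features are drawn as class-shifted normal variables
#' (separation `effect` in standard-deviation units between case and control
#' means) and mapped to rank scores in `[0, 1]`; features with zero effect
#' are pure noise. For a normal shift `d`, the single-feature AUC approaches
#' `pnorm(d / sqrt(2))`.
#'
#' @param nCase,nControl class sizes.
#' @param featureSpec data.frame with columns `name` and `effect`
#'   (standardized case-control mean separation; 0 = noise).
#' @param seed RNG seed.
#' @param gene gene symbol stamped on the rows.
#' @param missingRate fraction of cells masked as missing (to exercise
#'   imputation).
#' @return a [FeatureMatrix-class] with labels.
#' @export
simulateFeatureMatrix <- function(nCase, nControl,
                                  featureSpec = data.frame(
                                    name = c("f1", "n1", "n2", "n3", "n4"),
                                    effect = c(2, 0, 0, 0, 0)),
                                  seed = 1L, gene = "simGene",
                                  missingRate = 0) {
  stopifnot(nCase >= 1L, nControl >= 1L)
  set.seed(seed)
  n <- nCase + nControl
  y <- c(rep(1L, nCase), rep(0L, nControl))
  x <- matrix(NA_real_, nrow = n, ncol = nrow(featureSpec),
              dimnames = list(NULL, featureSpec$name))
  for (j in seq_len(nrow(featureSpec))) {
    raw <- rnorm(n, mean = featureSpec$effect[j] * y, sd = 1)
    x[, j] <- (rank(raw) - 1) / (n - 1)
  }
  if (missingRate > 0) {
    mask <- runif(length(x)) < missingRate
    x[mask] <- NA_real_
  }
  featureMatrix(x, labels = y, gene = gene)
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates a transcript, standing variation, coverage, pathogenic evidence
#' records and a feature matrix under one config, and writes them in the
#' plain-text formats every reader of this package consumes: `cds.fasta`,
#' `exons.tsv`, `variants.vcf`, `coverage.tsv`, `evidence.tsv`,
#' `features.tsv`.
#'
#' @param dir output directory (created if needed).
#' @param config a [simulationConfig()].
#' @param nPathogenic number of pathogenic records.
#' @param nCase,nControl feature-matrix class sizes.
#' @return named list of file paths, invisibly.
#' @export
writeFixtureSet <- function(dir, config = simulationConfig(),
                            nPathogenic = 40L, nCase = 100L,
                            nControl = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- simulateTranscript(config)
  sites <- simulateStandingVariation(model, config)
  coverage <- simulateCoverageTrack(model, config)
  evidence <- simulatePathogenicVariants(model, config, nPathogenic)
  fm <- simulateFeatureMatrix(nCase, nControl, seed = config$seed + 4L)

  paths <- list(
    cds_fasta = file.path(dir, "cds.fasta"),
    exon_tsv = file.path(dir, "exons.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    coverage_tsv = file.path(dir, "coverage.tsv"),
    evidence_tsv = file.path(dir, "evidence.tsv"),
    feature_tsv = file.path(dir, "features.tsv"))

  seqs <- Biostrings::DNAStringSet(as.character(model@cds))
  names(seqs) <- model@transcriptId
  Biostrings::writeXStringSet(seqs, paths$cds_fasta)

  ex <- data.frame(transcript_id = model@transcriptId,
                   gene_symbol = model@geneSymbol,
                   chrom = model@chromosome, strand = model@strand,
                   exon_start = GenomicRanges::start(model@exons),
                   exon_end = GenomicRanges::end(model@exons))
  write.table(ex, paths$exon_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  writeVariantVcf(sites, model, paths$vcf)
  write.table(coverage, paths$coverage_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(evidence, paths$evidence_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  featTab <- data.frame(variant_id = fm@variantId, gene = fm@gene,
                        label = fm@labels, fm@scores, check.names = FALSE)
  write.table(featTab, paths$feature_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# Serialize simulated variant sites as a minimal valid VCF 4.2 with the
# INFO fields the reader expects. Alleles are written on the forward strand.
writeVariantVcf <- function(sites, model, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", model@chromosome),
    "##FILTER=<ID=LowQual,Description=\"Failed quality control\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    sprintf(
      "##INFO=<ID=AF_%s,Number=A,Type=Float,Description=\"%s allele frequency\">",
      POPULATIONS, POPULATIONS),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ref <- sites$ref
  alt <- sites$alt
  if (model@strand == "-") {
    ref <- unname(revcompBase(ref))
    alt <- unname(revcompBase(alt))
  }
  afs <- vapply(seq_len(nrow(sites)), function(i) {
    paste(sprintf("AF_%s=%.8g", POPULATIONS,
                  unlist(sites[i, afColumns()])), collapse = ";")
  }, character(1L))
  info <- sprintf("AC=%d;AN=%d;%s", sites$AC, sites$AN, afs)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  model@chromosome, sites$genomic_pos, ref, alt,
                  ifelse(sites$qc_pass, "PASS", "LowQual"), info)
  ord <- order(sites$genomic_pos)
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}
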