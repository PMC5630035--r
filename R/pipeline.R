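#' Run configuration for the pipeline commands
#'
#' Resolved settings shared by the pipeline runners; serialized as JSON next
#' to every output so a run can be reproduced from its artifacts.
#'
#' @param windowRadius codon flank of the MTR window (15 gives 31 codons).
#' @param fdrScope `"study"` (BH family = all windows of all transcripts in
#'   the run, the default) or `"gene"`.
#' @param percentiles gene percentile thresholds to report.
#' @param p0Mode null proportion mode of the quartile test (`"fixed"` or
#'   `"possible"`).
#' @param importanceSeed,importanceRuns,importanceTrees,importanceMtry
#'   shadow-importance hyperparameters.
#' @param stopAlpha stepwise-selection relative-likelihood threshold.
#' @param mtrScreenAlpha quartile-test p-value below which a gene's model
#'   starts from the MTR term.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(windowRadius = 15L,
                      fdrScope = c("study", "gene"),
                      percentiles = c(0.05, 0.25, 0.5),
                      p0Mode = c("fixed", "possible"),
                      importanceSeed = 15L, importanceRuns = 1000L,
                      importanceTrees = 500L, importanceMtry = 4L,
                      stopAlpha = 0.05, mtrScreenAlpha = 0.0045) {
  stopifnot(windowRadius >= 1L, stopAlpha > 0, stopAlpha < 1,
            mtrScreenAlpha > 0, mtrScreenAlpha < 1,
            all(percentiles > 0 & percentiles < 1))
  cfg <- list(windowRadius = as.integer(windowRadius),
              fdrScope = match.arg(fdrScope),
              percentiles = percentiles,
              p0Mode = match.arg(p0Mode),
              importanceSeed = as.integer(importanceSeed),
              importanceRuns = as.integer(importanceRuns),
              importanceTrees = as.integer(importanceTrees),
              importanceMtry = as.integer(importanceMtry),
              stopAlpha = stopAlpha,
              mtrScreenAlpha = mtrScreenAlpha)
  class(cfg) <- "RunConfig"
  cfg
}

writeRunConfig <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Compute and write MTR tracks for a set of transcripts
#'
#' Reads transcripts and their standing-variation tables, computes one MTR
#' track per transcript, applies the FDR adjustment at the configured scope
#' (study-wide by default), and writes per-transcript track TSVs and gene
#' summary JSONs plus the resolved run configuration.
#'
#' @param cdsFasta CDS FASTA path.
#' @param exonTsv exon structure TSV path.
#' @param variantPaths named character vector of variant tables (VCF or
#'   TSV), one per transcript id; an unnamed single path is used for all.
#' @param outDir output directory.
#' @param coverageTsv optional coverage track TSV; when absent, the coverage
#'   column is left empty with a warning.
#' @param config a [runConfig()].
#' @return named list of [MtrTrack-class] objects, invisibly.
#' @export
runMtrPipeline <- function(cdsFasta, exonTsv, variantPaths, outDir,
                           coverageTsv = NULL, config = runConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  models <- readTranscriptModels(cdsFasta, exonTsv)
  coverage <- if (!is.null(coverageTsv)) readCoverageTrack(coverageTsv) else {
    warning("no coverage track supplied; coverage column left empty")
    NULL
  }
  tracks <- lapply(names(models), function(id) {
    path <- if (!is.null(names(variantPaths)) && id %in% names(variantPaths)) {
      variantPaths[[id]]
    } else if (length(variantPaths) == 1L) {
      variantPaths[[1L]]
    } else {
      stop("no variant table for transcript ", id)
    }
    sites <- readVariantTable(path, models[[id]])
    computeMtrTrack(models[[id]], sites,
                    windowRadius = config$windowRadius, coverage = coverage)
  })
  names(tracks) <- names(models)
  if (config$fdrScope == "study") tracks <- adjustFdrAcrossTracks(tracks)
  for (id in names(tracks)) {
    writeMtrTrack(tracks[[id]],
                  file.path(outDir, paste0(id, "_mtr.tsv")),
                  file.path(outDir, paste0(id, "_summary.json")))
  }
  writeRunConfig(config, outDir)
  invisible(tracks)
}

#' Per-gene enrichment evaluation of pathogenic versus control variants
#'
#' Qualifies the evidence records, then reports for the gene: the quartile
#' enrichment binomial test of qualified case variants in the lowest MTR
#' quartile (under both null modes), the Mann-Whitney comparison of case
#' versus control codon MTR values, and the Fisher presence test contrasting
#' how often qualified versus unqualified case variants are seen in the
#' standing-variation sample.
#'
#' @param model a [TranscriptModel-class].
#' @param track the transcript's [MtrTrack-class].
#' @param evidence evidence-record data.frame (see [qualifyPathogenic()]).
#' @param controlSites variant-site data.frame of control missense variants.
#' @param outPath optional TSV path for the one-row report.
#' @return a one-row data.frame (or, when no case qualifies, a row marked
#'   `skipped`).
#' @export
runEvaluation <- function(model, track, evidence, controlSites,
                          outPath = NULL) {
  status <- qualifyPathogenic(evidence)
  qual <- evidence[status == "qualified", , drop = FALSE]
  unqual <- evidence[status == "unqualified", , drop = FALSE]
  mtr <- track@estimates$mtr

  if (nrow(qual) == 0L) {
    row <- data.frame(gene = model@geneSymbol, skipped = TRUE,
                      reason = "no qualified pathogenic variant")
  } else {
    qt <- quartileEnrichmentTest(qual$codon_index, track, model,
                                 p0Mode = "fixed")
    qtPoss <- quartileEnrichmentTest(qual$codon_index, track, model,
                                     p0Mode = "possible")
    ctl <- controlSites[controlSites$consequence == "missense" &
                          controlSites$qc_pass, , drop = FALSE]
    rank <- mtrRankTest(mtr[qual$codon_index], mtr[ctl$codon_index])
    key <- function(d) paste(d$genomic_pos, d$alt)
    present <- key(evidence) %in% key(controlSites)
    a <- sum(present[status == "qualified"])
    c2 <- sum(present[status == "unqualified"])
    fisher <- if (nrow(unqual)) {
      presenceFisherTest(a, nrow(qual) - a, c2, nrow(unqual) - c2)$p_value
    } else NA_real_
    row <- data.frame(
      gene = model@geneSymbol, skipped = FALSE, reason = "",
      n_qualified = nrow(qual), n_unqualified = nrow(unqual),
      quartile_n = qt$n_total, quartile_k = qt$n_in_quartile,
      quartile_p0 = qt$p0, quartile_p = qt$p_value,
      quartile_p0_possible = qtPoss$p0, quartile_p_possible = qtPoss$p_value,
      case_median_mtr = rank$median_case,
      control_median_mtr = rank$median_control,
      rank_U = rank$U, rank_p = rank$p_value,
      presence_fisher_p = fisher)
  }
  if (!is.null(outPath)) {
    write.table(row, outPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  row
}

#' Run the full feature-to-GPP modeling pipeline
#'
#' Enforces the fixed order impute -> near-zero-variance prune ->
#' correlation prune -> shadow importance -> stepwise model selection, then
#' scores the variants. With `global = TRUE` all genes' rows are pooled
#' through the same selection path into one shared model; otherwise one
#' model is fitted per gene.
#'
#' @param fm a labeled [FeatureMatrix-class].
#' @param includeMtr start models from the raw codon MTR term.
#' @param global pool all genes into a single model.
#' @param config a [runConfig()].
#' @param outDir optional directory for model JSONs and a score TSV.
#' @return list with `retained` (features surviving pruning), `importance`
#'   (per gene or global), `models`, `scores` (per-variant GPP), `auc`
#'   (training AUC per model).
#' @export
runGppPipeline <- function(fm, includeMtr = FALSE, global = FALSE,
                           config = runConfig(), outDir = NULL) {
  if (all(is.na(fm@labels))) stop("feature matrix has no labels")
  if (length(unique(fm@labels[!is.na(fm@labels)])) < 2L) {
    stop("both case and control labels are required")
  }
  fm <- imputeMissingScores(fm)
  keep <- pruneNearZeroVariance(fm)
  fm@scores <- fm@scores[, keep, drop = FALSE]
  keep <- prunePairwiseCorrelated(fm)
  fm@scores <- fm@scores[, keep, drop = FALSE]

  fitOne <- function(sub, label) {
    rep <- assessFeatureImportance(
      sub, seed = config$importanceSeed, runs = config$importanceRuns,
      trees = config$importanceTrees, mtry = config$importanceMtry)
    medZ <- apply(rep@zScores, 2L, median)
    cand <- colnames(rep@zScores)[rep@category == "informative"]
    cand <- cand[order(-medZ[cand])]
    model <- selectGeneModel(sub, cand, includeMtr = includeMtr,
                             stopAlpha = config$stopAlpha,
                             geneSymbol = label)
    list(importance = rep, model = model)
  }

  if (global) {
    fits <- list(global = fitOne(fm, "global"))
  } else {
    genes <- unique(fm@gene[!is.na(fm@labels)])
    fits <- lapply(genes, function(g) {
      sub <- fm
      rows <- fm@gene == g
      sub@scores <- fm@scores[rows, , drop = FALSE]
      sub@labels <- fm@labels[rows]
      sub@gene <- fm@gene[rows]
      sub@mtr <- fm@mtr[rows]
      sub@variantId <- fm@variantId[rows]
      fitOne(sub, g)
    })
    names(fits) <- genes
  }

  scores <- rep(NA_real_, nrow(fm@scores))
  for (nm in names(fits)) {
    rows <- if (nm == "global") rep(TRUE, nrow(fm@scores)) else fm@gene == nm
    feats <- as.data.frame(fm@scores[rows, , drop = FALSE])
    feats$MTR <- fm@mtr[rows]
    scores[rows] <- scoreGpp(fits[[nm]]$model, feats)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fits)) {
      writeGeneModel(fits[[nm]]$model,
                     file.path(outDir, paste0(nm, "_model.json")))
    }
    write.table(
      data.frame(variant_id = fm@variantId, gene = fm@gene, gpp = scores),
      file.path(outDir, "gpp_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunConfig(config, outDir)
  }
  list(retained = colnames(fm@scores),
       importance = lapply(fits, `[[`, "importance"),
       models = lapply(fits, `[[`, "model"),
       scores = scores,
       auc = vapply(fits, function(f) f$model@trainingAuc, numeric(1L)))
}
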