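#' @import methods
#' @importFrom stats median quantile setNames aggregate binom.test fisher.test
#'   wilcox.test p.adjust glm binomial coef AIC predict plogis rbinom rbeta
#'   rgeom rnorm runif cor complete.cases pbinom
#' @importFrom utils read.table write.table head
#' @importFrom rlang .data
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# alternate alleles per reference base, alphabetical
ALT_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))

# Central S4 containers. Tabular intermediates (variant sites, evidence
# records, coverage tracks) stay plain data.frames with documented columns;
# the objects a user carries between pipeline stages get classes.

#' TranscriptModel: a single protein-coding transcript
#'
#' Holds the coding sequence (coding strand, 5'->3'), the exon structure on
#' the chromosome, and a precomputed CDS-to-genome coordinate map. The stop
#' codon, when present, is recorded but excluded from the analyzed protein
#' codons `1..L`.
#'
#' @slot transcriptId transcript identifier.
#' @slot geneSymbol gene symbol.
#' @slot chromosome chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons a [GenomicRanges::GRanges] of exon blocks, ascending on the
#'   chromosome, 1-based inclusive.
#' @slot cds a [Biostrings::DNAString] with the CDS on the coding strand.
#' @slot hasStop whether the final codon of `cds` is a stop codon.
#' @slot proteinLength integer codon count L, excluding any stop codon.
#' @slot genomicPos integer vector: genomic coordinate of each CDS position
#'   in coding (5'->3') order; for minus-strand transcripts this vector is
#'   descending.
#'
#' @seealso [buildTranscriptModel()], [enumeratePossibleSnvs()]
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneSymbol = "character",
    chromosome = "character",
    strand = "character",
    exons = "GRanges",
    cds = "DNAString",
    hasStop = "logical",
    proteinLength = "integer",
    genomicPos = "integer"
  )
)

setValidity("TranscriptModel", function(object) {
  id <- object@transcriptId
  seqchr <- as.character(object@cds)
  n <- nchar(seqchr)
  if (grepl("[^ACGT]", seqchr)) {
    return(sprintf("non-ACGT character in CDS of transcript '%s'", id))
  }
  if (n %% 3L != 0L) {
    return(sprintf("CDS length (%d) of transcript '%s' is not a multiple of 3", n, id))
  }
  if (sum(GenomicRanges::width(object@exons)) != n) {
    return(sprintf(
      "exon block lengths (%d) do not sum to CDS length (%d) for transcript '%s'",
      sum(GenomicRanges::width(object@exons)), n, id))
  }
  if (!object@strand %in% c("+", "-")) {
    return(sprintf("strand of transcript '%s' must be '+' or '-'", id))
  }
  L <- object@proteinLength
  expectedL <- n %/% 3L - as.integer(object@hasStop)
  if (L != expectedL) {
    return(sprintf("proteinLength (%d) inconsistent with CDS for transcript '%s'", L, id))
  }
  if (L >= 1L) {
    codons <- substring(seqchr, seq(1L, by = 3L, length.out = L),
                        seq(3L, by = 3L, length.out = L))
    aa <- Biostrings::GENETIC_CODE[codons]
    if (any(aa == "*")) {
      return(sprintf("internal stop codon at codon %d in transcript '%s'",
                     which(aa == "*")[1L], id))
    }
  }
  if (length(object@genomicPos) != n) {
    return(sprintf("genomic map length mismatch for transcript '%s'", id))
  }
  TRUE
})

#' MtrTrack: per-codon missense tolerance estimates for one transcript
#'
#' One row per protein codon, giving windowed observed/possible missense and
#' synonymous tallies, the MTR, its binomial deviation p-value, the BH
#' FDR-adjusted q-value, and sample coverage, plus gene-level percentile
#' thresholds of the MTR distribution.
#'
#' @slot transcriptId transcript identifier.
#' @slot estimates data.frame with columns `codon_index`, `window_lo`,
#'   `window_hi`, `obs_mis`, `obs_syn`, `pos_mis`, `pos_syn`, `mtr`,
#'   `p_value`, `fdr_q`, `coverage`, `coverage_incomplete`.
#' @slot thresholds named numeric vector of MTR percentile thresholds
#'   (names are percentile levels, e.g. `"5"`, `"25"`, `"50"`).
#' @slot windowRadius integer flank size (15 gives the 31-codon window).
#'
#' @seealso [computeMtrTrack()], [genePercentileThresholds()]
#' @export
setClass("MtrTrack",
  representation(
    transcriptId = "character",
    estimates = "data.frame",
    thresholds = "numeric",
    windowRadius = "integer"
  )
)

setValidity("MtrTrack", function(object) {
  est <- object@estimates
  need <- c("codon_index", "window_lo", "window_hi", "obs_mis", "obs_syn",
            "pos_mis", "pos_syn", "mtr", "p_value", "fdr_q", "coverage",
            "coverage_incomplete")
  if (!all(need %in% names(est))) {
    return(paste("estimates missing columns:",
                 paste(setdiff(need, names(est)), collapse = ", ")))
  }
  if (nrow(est) > 0L) {
    if (any(est$pos_mis + est$pos_syn <= 0L)) {
      return("every window must contain at least one possible missense or synonymous SNV")
    }
    nullObs <- (est$obs_mis + est$obs_syn) == 0L
    if (any(is.na(est$mtr) != nullObs)) {
      return("mtr must be NA exactly when a window has no observed variants")
    }
  }
  if (length(object@thresholds) > 1L && is.unsorted(object@thresholds)) {
    return("percentile thresholds must be non-decreasing in percentile")
  }
  TRUE
})

#' FeatureMatrix: variant-by-feature rank scores with labels
#'
#' Rows are variants, columns are in-silico feature rank scores in `[0, 1]`
#' (possibly with missing cells before imputation). Case/control labels,
#' per-variant gene membership and an optional raw codon MTR value ride
#' alongside; the MTR is kept out of the score matrix because it is not a
#' rank score and is exempt from the `[0, 1]` constraint.
#'
#' @slot scores numeric matrix, variants x features, values in `[0, 1]` or NA.
#' @slot labels integer vector (1 = case, 0 = control, NA = unlabeled).
#' @slot gene character vector, gene symbol per variant.
#' @slot mtr numeric vector, raw codon MTR per variant (NA allowed).
#' @slot variantId character vector of row identifiers.
#'
#' @seealso [imputeMissingScores()], [assessFeatureImportance()],
#'   [selectGeneModel()]
#' @export
setClass("FeatureMatrix",
  representation(
    scores = "matrix",
    labels = "integer",
    gene = "character",
    mtr = "numeric",
    variantId = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  n <- nrow(object@scores)
  if (is.null(colnames(object@scores))) return("score columns must be named")
  if (length(object@labels) != n || length(object@gene) != n ||
      length(object@mtr) != n || length(object@variantId) != n) {
    return("labels, gene, mtr and variantId must each have one entry per row")
  }
  v <- object@scores[!is.na(object@scores)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    return("feature rank scores must lie in [0, 1]")
  }
  if (!all(object@labels %in% c(0L, 1L, NA_integer_))) {
    return("labels must be 0, 1 or NA")
  }
  TRUE
})

#' FeatureImportanceReport: shadow-feature random-forest screening result
#'
#' Per-feature distributions of mean-decrease-accuracy Z-scores across
#' repeated random-forest runs, the per-run maximum shadow-feature Z, and the
#' resulting category per feature.
#'
#' @slot zScores numeric matrix, runs x features.
#' @slot shadowMax numeric vector, per-run maximum Z among shadow features.
#' @slot hits integer vector, per feature, runs in which it beat the max shadow.
#' @slot category factor per feature with levels `uninformative`,
#'   `inconclusive`, `informative`.
#' @slot highlyInformative logical per feature (always a subset of
#'   `informative`).
#' @slot params list of run parameters (seed, runs, trees, mtry, alpha).
#'
#' @seealso [assessFeatureImportance()]
#' @export
setClass("FeatureImportanceReport",
  representation(
    zScores = "matrix",
    shadowMax = "numeric",
    hits = "integer",
    category = "factor",
    highlyInformative = "logical",
    params = "list"
  )
)

setValidity("FeatureImportanceReport", function(object) {
  k <- ncol(object@zScores)
  if (length(object@category) != k || length(object@highlyInformative) != k ||
      length(object@hits) != k) {
    return("per-feature slots must match the number of score columns")
  }
  if (any(object@highlyInformative & object@category != "informative")) {
    return("highly informative features must be a subset of informative features")
  }
  TRUE
})

#' GeneModel: a fitted gene-specific logistic pathogenicity model
#'
#' Logistic regression coefficients over the selected features (optionally
#' including the raw codon MTR), the stepwise-selection trace, and the AUC
#' obtained when the model is reapplied to its training data.
#'
#' @slot geneSymbol gene the model was fit for (`"global"` for pooled fits).
#' @slot intercept numeric intercept coefficient.
#' @slot coefficients named numeric vector of feature coefficients.
#' @slot trace data.frame with one row per selection step (`step`, `action`,
#'   `feature`, `aic`, `accepted`, `note`).
#' @slot trainingAuc numeric training-set AUC.
#'
#' @seealso [selectGeneModel()], [scoreGpp()]
#' @export
setClass("GeneModel",
  representation(
    geneSymbol = "character",
    intercept = "numeric",
    coefficients = "numeric",
    trace = "data.frame",
    trainingAuc = "numeric"
  )
)

setValidity("GeneModel", function(object) {
  if (length(object@coefficients) &&
      is.null(names(object@coefficients))) {
    return("coefficients must be named by feature")
  }
  TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf(
    "TranscriptModel %s (%s) %s:%s strand %s\n  %d exon block(s), CDS %d nt, L = %d codons%s\n",
    object@transcriptId, object@geneSymbol, object@chromosome,
    paste(range(GenomicRanges::start(object@exons),
                GenomicRanges::end(object@exons)), collapse = "-"),
    object@strand, length(object@exons), length(object@cds),
    object@proteinLength,
    if (object@hasStop) " (+ stop codon)" else ""))
})

setMethod("show", "MtrTrack", function(object) {
  est <- object@estimates
  cat(sprintf("MtrTrack for %s: %d codons, window radius %d\n",
              object@transcriptId, nrow(est), object@windowRadius))
  ok <- !is.na(est$mtr)
  if (any(ok)) {
    cat(sprintf("  MTR median %.3f [range %.3f-%.3f], %d/%d windows estimable\n",
                median(est$mtr[ok]), min(est$mtr[ok]), max(est$mtr[ok]),
                sum(ok), nrow(est)))
  }
  if (length(object@thresholds)) {
    cat("  percentile thresholds:",
        paste(sprintf("%s%%=%.3f", names(object@thresholds),
                      object@thresholds), collapse = ", "), "\n")
  }
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d variants x %d features, %d missing cells\n",
              nrow(object@scores), ncol(object@scores),
              sum(is.na(object@scores))))
  lb <- table(factor(object@labels, levels = c(0L, 1L)))
  cat(sprintf("  labels: %d control / %d case / %d unlabeled; genes: %s\n",
              lb[["0"]], lb[["1"]], sum(is.na(object@labels)),
              paste(unique(object@gene), collapse = ", ")))
})

setMethod("show", "FeatureImportanceReport", function(object) {
  cat(sprintf("FeatureImportanceReport: %d features over %d runs\n",
              ncol(object@zScores), nrow(object@zScores)))
  print(table(object@category))
  if (any(object@highlyInformative)) {
    cat("  highly informative:",
        paste(colnames(object@zScores)[object@highlyInformative],
              collapse = ", "), "\n")
  }
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel [%s]: intercept %.3f, %d feature(s); training AUC %.3f\n",
              object@geneSymbol, object@intercept,
              length(object@coefficients), object@trainingAuc))
  if (length(object@coefficients)) {
    for (f in names(object@coefficients)) {
      cat(sprintf("    %s: %+.3f\n", f, object@coefficients[[f]]))
    }
  }
})

# ---- accessors -------------------------------------------------------------

#' @rdname accessors
#' @param object an mtrtools S4 object.
#' @export
setGeneric("transcriptId", function(object) standardGeneric("transcriptId"))

#' Accessors for mtrtools objects
#'
#' Small read-only accessors for the S4 containers: `transcriptId()`,
#' `proteinLength()`, `cdsSequence()`, `trackEstimates()`, `mtrValues()`,
#' `percentileThresholds()`, `featureScores()`, `featureLabels()`,
#' `importanceCategory()`, `modelCoefficients()`.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(object) object@transcriptId)

#' @rdname accessors
#' @export
setMethod("transcriptId", "MtrTrack", function(object) object@transcriptId)

#' @rdname accessors
#' @export
setGeneric("proteinLength", function(object) standardGeneric("proteinLength"))

#' @rdname accessors
#' @export
setMethod("proteinLength", "TranscriptModel", function(object) object@proteinLength)

#' @rdname accessors
#' @export
cdsSequence <- function(object) {
  stopifnot(is(object, "TranscriptModel"))
  object@cds
}

#' @rdname accessors
#' @export
trackEstimates <- function(object) {
  stopifnot(is(object, "MtrTrack"))
  object@estimates
}

#' @rdname accessors
#' @export
mtrValues <- function(object) {
  stopifnot(is(object, "MtrTrack"))
  setNames(object@estimates$mtr, object@estimates$codon_index)
}

#' @rdname accessors
#' @export
percentileThresholds <- function(object) {
  stopifnot(is(object, "MtrTrack"))
  object@thresholds
}

#' @rdname accessors
#' @export
featureScores <- function(object) {
  stopifnot(is(object, "FeatureMatrix"))
  object@scores
}

#' @rdname accessors
#' @export
featureLabels <- function(object) {
  stopifnot(is(object, "FeatureMatrix"))
  object@labels
}

#' @rdname accessors
#' @export
importanceCategory <- function(object) {
  stopifnot(is(object, "FeatureImportanceReport"))
  setNames(object@category, colnames(object@zScores))
}

#' @rdname accessors
#' @export
modelCoefficients <- function(object) {
  stopifnot(is(object, "GeneModel"))
  c("(Intercept)" = object@intercept, object@coefficients)
}
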