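#' Quartile enrichment test for pathogenic variants in intolerant regions
#'
#' Tests whether case (pathogenic) missense variants preferentially occur in
#' the most missense-depleted quartile of a gene's MTR distribution. A case
#' variant counts as "in the quartile" when its codon's MTR is at or below
#' the gene's 25th-percentile threshold (ties included, by depletion
#' semantics). The p-value is a one-sided exact binomial tail
#' `P(X >= k)` with `n` = number of scoreable case variants.
#'
#' The null proportion `p0` defaults to 0.25 (the quartile is built over
#' codons). `p0Mode = "possible"` instead uses the fraction of possible
#' missense SNVs whose codon falls in the lowest quartile — a
#' better-calibrated null when codon missense opportunity varies; both are
#' reported by the evaluation pipeline.
#'
#' @param caseCodons integer vector of case-variant codon indices.
#' @param track an [MtrTrack-class] with defined estimates.
#' @param model the matching [TranscriptModel-class]; required for
#'   `p0Mode = "possible"`.
#' @param p0Mode `"fixed"` (0.25) or `"possible"`.
#' @param percentile quartile level (default 0.25).
#' @return list with `n_total`, `n_in_quartile`, `n_unscoreable` (cases at
#'   codons with undefined MTR), `threshold`, `p0`, `p_value`.
#' @export
quartileEnrichmentTest <- function(caseCodons, track, model = NULL,
                                   p0Mode = c("fixed", "possible"),
                                   percentile = 0.25) {
  stopifnot(is(track, "MtrTrack"))
  p0Mode <- match.arg(p0Mode)
  if (!length(caseCodons)) stop("empty case variant list")
  est <- track@estimates
  if (any(caseCodons < 1L | caseCodons > nrow(est))) {
    stop("case codon outside the transcript")
  }
  mtr <- est$mtr
  if (all(is.na(mtr))) stop("track has no defined MTR estimates")
  threshold <- unname(genePercentileThresholds(mtr, percentile))
  caseMtr <- mtr[caseCodons]
  scoreable <- !is.na(caseMtr)
  k <- sum(caseMtr[scoreable] <= threshold)
  n <- sum(scoreable)
  if (n == 0L) stop("no case variant falls on a codon with a defined MTR")
  p0 <- if (p0Mode == "fixed") percentile else {
    stopifnot(is(model, "TranscriptModel"))
    poss <- enumeratePossibleSnvs(model)
    mis <- poss[poss$consequence == "missense", , drop = FALSE]
    inQ <- !is.na(mtr[mis$codon_index]) & mtr[mis$codon_index] <= threshold
    def <- !is.na(mtr[mis$codon_index])
    sum(inQ) / sum(def)
  }
  p <- pbinom(k - 1L, n, p0, lower.tail = FALSE)
  list(n_total = n, n_in_quartile = k, n_unscoreable = sum(!scoreable),
       threshold = threshold, p0 = p0, p_value = p)
}

#' Mann-Whitney comparison of case and control MTR distributions
#'
#' Two-sided Mann-Whitney U test comparing the per-variant codon MTR values
#' of case (pathogenic) versus control (presumed benign) missense variants.
#' Undefined MTR values are removed. The exact null distribution is used
#' when the combined sample size is at most 25 and there are no ties;
#' otherwise the normal approximation with tie correction is used.
#'
#' @param caseMtr,controlMtr numeric vectors of codon MTR values.
#' @return list with `U`, `p_value`, `median_case`, `median_control`,
#'   `exact` (logical).
#' @export
mtrRankTest <- function(caseMtr, controlMtr) {
  x <- caseMtr[!is.na(caseMtr)]
  y <- controlMtr[!is.na(controlMtr)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y) <= 25L) && !anyDuplicated(c(x, y))
  wt <- wilcox.test(x, y, exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_case = median(x), median_control = median(y),
       exact = exact)
}

#' Fisher exact test on a 2x2 presence table
#'
#' Two-sided Fisher exact test (sum of hypergeometric tables no more
#' probable than the observed one) for comparing, e.g., the rate at which
#' qualified versus unqualified pathogenic variants are observed in
#' population reference cohorts.
#'
#' @param a,b first row (e.g. present / absent among qualified).
#' @param c2,d second row (present / absent among unqualified).
#' @return list with the 2x2 `table`, `p_value`, and `odds_ratio` (MLE).
#' @export
presenceFisherTest <- function(a, b, c2, d) {
  counts <- c(a, b, c2, d)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("all-zero contingency table")
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  ft <- fisher.test(tab)
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}
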