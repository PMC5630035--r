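windowSum <- function(x, lo, hi) {
  cs <- c(0, cumsum(x))
  cs[hi + 1L] - cs[lo]
}

#' Compute the Missense Tolerance Ratio track of a transcript
#'
#' Slides a window of `2 * windowRadius + 1` codons (31 by default, i.e. 93
#' coding nucleotides) across protein codons `1..L` and, per index codon,
#' computes
#' \deqn{MTR = \frac{obs_{mis} / (obs_{mis} + obs_{syn})}
#'                 {pos_{mis} / (pos_{mis} + pos_{syn})}}
#' where the numerator is the observed proportion of missense among observed
#' missense plus synonymous variant sites in the window, and the denominator
#' is the same proportion over all possible SNVs of the window, with every
#' substitution taken as equally likely. Values below 1 indicate preferential
#' depletion of missense variation (purifying selection); windows at the
#' transcript ends are truncated to the available codons.
#'
#' Observed sites are restricted to quality-passing missense/synonymous SNVs
#' and deduplicated by (genomic position, alternate allele) — counts are
#' distinct variant sites, not allele counts. A window with no observed
#' variants has an undefined (NA) MTR and is excluded from percentile
#' thresholds and deviation tests.
#'
#' Each window with at least one observed variant also receives a two-sided
#' exact binomial test against MTR = 1 ([windowDeviationTest()]) and a
#' Benjamini-Hochberg q-value over the track's windows (for multi-transcript
#' runs, re-adjust study-wide with [adjustFdrAcrossTracks()]).
#'
#' @param model a [TranscriptModel-class].
#' @param observed variant-site data.frame as from [readVariantTable()].
#' @param windowRadius codons flanking the index codon on each side.
#' @param coverage optional coverage track ([readCoverageTrack()]).
#' @return an [MtrTrack-class].
#' @export
computeMtrTrack <- function(model, observed, windowRadius = 15L,
                            coverage = NULL) {
  stopifnot(is(model, "TranscriptModel"))
  L <- model@proteinLength
  if (L < 1L) stop("transcript has no protein codons")
  windowRadius <- as.integer(windowRadius)

  possible <- enumeratePossibleSnvs(model)
  posMis <- tabulate(possible$codon_index[possible$consequence == "missense"], L)
  posSyn <- tabulate(possible$codon_index[possible$consequence == "synonymous"], L)

  obs <- observed[observed$qc_pass &
                    observed$consequence %in% c("missense", "synonymous"), ,
                  drop = FALSE]
  if (nrow(obs) && any(obs$codon_index > L | obs$codon_index < 1L)) {
    stop("observed site outside the transcript CDS")
  }
  obs <- obs[!duplicated(obs[, c("genomic_pos", "alt")]), , drop = FALSE]
  obsMis <- tabulate(obs$codon_index[obs$consequence == "missense"], L)
  obsSyn <- tabulate(obs$codon_index[obs$consequence == "synonymous"], L)

  idx <- seq_len(L)
  lo <- pmax(1L, idx - windowRadius)
  hi <- pmin(L, idx + windowRadius)
  wObsMis <- as.integer(windowSum(obsMis, lo, hi))
  wObsSyn <- as.integer(windowSum(obsSyn, lo, hi))
  wPosMis <- as.integer(windowSum(posMis, lo, hi))
  wPosSyn <- as.integer(windowSum(posSyn, lo, hi))

  obsTot <- wObsMis + wObsSyn
  p0 <- wPosMis / (wPosMis + wPosSyn)
  mtr <- ifelse(obsTot > 0L, (wObsMis / obsTot) / p0, NA_real_)
  p <- windowDeviationTest(wObsMis, wObsSyn, wPosMis, wPosSyn)

  est <- data.frame(
    codon_index = idx, window_lo = lo, window_hi = hi,
    obs_mis = wObsMis, obs_syn = wObsSyn,
    pos_mis = wPosMis, pos_syn = wPosSyn,
    mtr = mtr, p_value = p, fdr_q = adjustFdrBh(p),
    coverage = NA_real_, coverage_incomplete = NA)
  if (!is.null(coverage)) {
    cv <- codonCoverage(coverage, model)
    est$coverage <- cv$coverage
    est$coverage_incomplete <- cv$incomplete
  }
  thresholds <- if (all(is.na(mtr))) numeric(0) else {
    genePercentileThresholds(mtr)
  }
  new("MtrTrack", transcriptId = model@transcriptId, estimates = est,
      thresholds = thresholds, windowRadius = windowRadius)
}

#' Exact binomial test for deviation from MTR = 1
#'
#' Two-sided exact binomial test of the observed missense count among the
#' window's observed missense plus synonymous variants, against the null
#' proportion given by the window's possible-SNV composition (the proportion
#' under MTR = 1). Uses the minimum-likelihood-sum convention for the
#' two-sided p-value. Windows without observed variants return `NA`.
#'
#' @param obsMis,obsSyn observed distinct missense / synonymous sites.
#' @param posMis,posSyn possible missense / synonymous SNV counts.
#' @return numeric vector of p-values.
#' @export
windowDeviationTest <- function(obsMis, obsSyn, posMis, posSyn) {
  n <- obsMis + obsSyn
  p0 <- posMis / (posMis + posSyn)
  vapply(seq_along(n), function(i) {
    if (is.na(n[i]) || n[i] < 1L) return(NA_real_)
    binom.test(obsMis[i], n[i], p0[i])$p.value
  }, numeric(1L))
}

#' Benjamini-Hochberg FDR adjustment with NA pass-through
#'
#' Step-up BH adjustment where the family size is the number of non-missing
#' p-values; `NA` entries (windows without observed variants) pass through
#' unadjusted.
#'
#' @param p numeric vector of p-values (NA allowed).
#' @return numeric vector of q-values.
#' @export
adjustFdrBh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Re-adjust FDR study-wide across several MTR tracks
#'
#' Pools the window p-values of all tracks into one family and rewrites each
#' track's `fdr_q` with the study-wide Benjamini-Hochberg adjustment; this is
#' the default family used when a run spans multiple transcripts.
#'
#' @param tracks list of [MtrTrack-class] objects.
#' @return the list, with `fdr_q` columns replaced.
#' @export
adjustFdrAcrossTracks <- function(tracks) {
  stopifnot(all(vapply(tracks, is, logical(1L), "MtrTrack")))
  p <- unlist(lapply(tracks, function(t) t@estimates$p_value))
  q <- adjustFdrBh(p)
  off <- 0L
  for (i in seq_along(tracks)) {
    k <- nrow(tracks[[i]]@estimates)
    tracks[[i]]@estimates$fdr_q <- q[off + seq_len(k)]
    off <- off + k
  }
  tracks
}

#' Gene-specific percentile thresholds of the MTR distribution
#'
#' Empirical percentiles (linear interpolation) of the per-codon MTR values
#' of a gene; codons with undefined MTR are excluded. The defaults give the
#' 5th-percentile (most depleted), 25th-percentile and median thresholds
#' used to flag intolerant regions.
#'
#' @param x an [MtrTrack-class] or a numeric vector of per-codon MTR values.
#' @param percentiles probabilities in (0, 1).
#' @return named numeric vector of thresholds.
#' @export
genePercentileThresholds <- function(x, percentiles = c(0.05, 0.25, 0.5)) {
  v <- if (is(x, "MtrTrack")) x@estimates$mtr else as.numeric(x)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no defined MTR estimates to take percentiles of")
  setNames(quantile(v, probs = percentiles, type = 7, names = FALSE),
           sub("^0\\.", "", as.character(percentiles * 100)))
}

#' Windowed log(dN/dS) analogue
#'
#' The classical log-ratio of observed-to-possible missense rate over
#' observed-to-possible synonymous rate for a window. Undefined (NA) when
#' either observed count is zero — the instability the MTR formulation is
#' designed to avoid.
#'
#' @inheritParams windowDeviationTest
#' @return numeric vector (NA where undefined).
#' @export
computeLogDnds <- function(obsMis, obsSyn, posMis, posSyn) {
  ifelse(obsMis > 0L & obsSyn > 0L,
         log((obsMis / posMis) / (obsSyn / posSyn)),
         NA_real_)
}

#' Write an MTR track to TSV (and optional JSON gene summary)
#'
#' @param track an [MtrTrack-class].
#' @param tsvPath output TSV path.
#' @param jsonPath optional JSON path for the gene summary (transcript id,
#'   codon count, percentile thresholds, windows at FDR < 0.05).
#' @return the estimates data.frame, invisibly.
#' @export
writeMtrTrack <- function(track, tsvPath, jsonPath = NULL) {
  stopifnot(is(track, "MtrTrack"))
  est <- track@estimates
  out <- data.frame(transcript_id = track@transcriptId,
                    codon_index = est$codon_index,
                    protein_pos = est$codon_index,
                    est[, c("obs_mis", "obs_syn", "pos_mis", "pos_syn",
                            "mtr", "p_value", "fdr_q", "coverage")])
  write.table(out, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    summary <- list(
      transcript_id = track@transcriptId,
      n_codons = nrow(est),
      window_radius = track@windowRadius,
      percentile_thresholds = as.list(track@thresholds),
      n_windows_fdr_lt_05 = sum(est$fdr_q < 0.05, na.rm = TRUE))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(est)
}

#' Plot an MTR track
#'
#' Line plot of per-codon MTR with dashed reference lines at MTR = 1 (blue),
#' the gene median (black), 25th percentile (dark green) and 5th percentile
#' (orange); windows at FDR < 0.05 highlighted in red; the coverage fraction,
#' when present, drawn as a grey trace.
#'
#' @param track an [MtrTrack-class].
#' @param fdrCut FDR threshold for highlighting (default 0.05).
#' @return a [ggplot2::ggplot] object.
#' @export
plotMtrTrack <- function(track, fdrCut = 0.05) {
  stopifnot(is(track, "MtrTrack"))
  est <- track@estimates
  th <- track@thresholds
  g <- ggplot2::ggplot(est, ggplot2::aes(x = .data$codon_index, y = .data$mtr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "blue") +
    ggplot2::geom_line(na.rm = TRUE)
  for (nm in names(th)) {
    col <- switch(nm, "5" = "orange", "25" = "darkgreen", "50" = "black",
                  "grey40")
    g <- g + ggplot2::geom_hline(yintercept = th[[nm]], linetype = "dashed",
                                 colour = col)
  }
  sig <- est[!is.na(est$fdr_q) & est$fdr_q < fdrCut, , drop = FALSE]
  if (nrow(sig)) {
    g <- g + ggplot2::geom_point(data = sig, colour = "red", size = 0.8,
                                 na.rm = TRUE)
  }
  if (any(!is.na(est$coverage))) {
    g <- g + ggplot2::geom_line(ggplot2::aes(y = .data$coverage),
                                colour = "grey60", linetype = "dashed",
                                na.rm = TRUE)
  }
  g + ggplot2::labs(x = "protein codon", y = "MTR",
                    title = track@transcriptId) +
    ggplot2::theme_minimal()
}
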