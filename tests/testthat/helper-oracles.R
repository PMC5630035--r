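# Independent oracles used across the suite. Deliberately naive: loops and
# by-definition formulas, no shared code paths with the package internals.

# Per-codon window recount by filtering full site lists, one codon at a time.
naiveMtrRecount <- function(model, observed, radius = 15L) {
  poss <- enumeratePossibleSnvs(model)
  obs <- observed[observed$qc_pass &
                    observed$consequence %in% c("missense", "synonymous"), ]
  obs <- obs[!duplicated(paste(obs$genomic_pos, obs$alt)), ]
  L <- proteinLength(model)
  out <- data.frame(codon_index = seq_len(L), obs_mis = NA_integer_,
                    obs_syn = NA_integer_, pos_mis = NA_integer_,
                    pos_syn = NA_integer_, mtr = NA_real_)
  for (i in seq_len(L)) {
    lo <- max(1L, i - radius); hi <- min(L, i + radius)
    pw <- poss[poss$codon_index >= lo & poss$codon_index <= hi, ]
    ow <- obs[obs$codon_index >= lo & obs$codon_index <= hi, ]
    pm <- sum(pw$consequence == "missense")
    ps <- sum(pw$consequence == "synonymous")
    om <- sum(ow$consequence == "missense")
    os <- sum(ow$consequence == "synonymous")
    out$pos_mis[i] <- pm; out$pos_syn[i] <- ps
    out$obs_mis[i] <- om; out$obs_syn[i] <- os
    if (om + os > 0L) {
      out$mtr[i] <- (om / (om + os)) / (pm / (pm + ps))
    }
  }
  out
}

# Two-sided exact binomial p by direct enumeration of the outcome space
# under the minimum-likelihood-sum convention.
enumBinomTwoSided <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)])
}

# Benjamini-Hochberg by its definition: with order statistics p_(1..m),
# q_i = min over sorted positions j with p_(j) >= p_i of m * p_(j) / j,
# capped at 1.
bruteForceBH <- function(p) {
  m <- length(p)
  ps <- sort(p)
  stepup <- m * ps / seq_len(m)
  vapply(p, function(pi) min(1, min(stepup[ps >= pi])), numeric(1))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of case
# labels to the combined (tie-free) sample; doubling convention.
enumExactMWp <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x); n <- length(v)
  combos <- combn(n, n1)
  Ud <- apply(combos, 2L, function(ix) {
    xs <- v[ix]; ys <- v[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pLo <- mean(Ud <= u); pHi <- mean(Ud >= u)
  min(1, 2 * min(pLo, pHi))
}

# Neutral (no-depletion) simulation config used by several tests.
neutralConfig <- function(seed, lengthCodons = 200L) {
  simulationConfig(
    seed = seed, transcriptLengthCodons = lengthCodons,
    depletionRegions = data.frame(codon_lo = integer(0),
                                  codon_hi = integer(0),
                                  missense_retention = numeric(0)))
}

# A synthetic MtrTrack with prescribed per-codon MTR values (counts filled
# in consistently), for tests that only exercise threshold logic.
makeTrackFromMtr <- function(mtr, transcriptId = "fake") {
  L <- length(mtr)
  obsTot <- ifelse(is.na(mtr), 0L, 1L)
  est <- data.frame(
    codon_index = seq_len(L), window_lo = pmax(1L, seq_len(L) - 15L),
    window_hi = pmin(L, seq_len(L) + 15L),
    obs_mis = obsTot, obs_syn = 0L, pos_mis = 200L, pos_syn = 60L,
    mtr = mtr, p_value = NA_real_, fdr_q = NA_real_,
    coverage = NA_real_, coverage_incomplete = NA)
  # keep mtr-null <=> zero-obs invariant without implying real tallies
  est$obs_mis <- ifelse(is.na(mtr), 0L, 1L)
  new("MtrTrack", transcriptId = transcriptId, estimates = est,
      thresholds = genePercentileThresholds(mtr[!is.na(mtr)]),
      windowRadius = 15L)
}

# Minimal hand-written VCF writer for reader tests (independent of the
# package's serializer).
writeTestVcf <- function(path, chrom, rows) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chrom),
           "##FILTER=<ID=LowQual,Description=\"low\">",
           "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"ac\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"an\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, rows), path)
  path
}
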