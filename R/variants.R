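# Seven ancestry populations used for the rare-variant (Group 3) MAF screen.
POPULATIONS <- c("AFR", "AMR", "ASJ", "EAS", "FIN", "NFE", "SAS")
GROUP3_MAF_MAX <- 0.0005

afColumns <- function() paste0("AF_", POPULATIONS)

revcompBase <- function(x) c(A = "T", C = "G", G = "C", T = "A")[x]

#' Read a standing-variation site table against a transcript model
#'
#' Accepts a VCF 4.x file (INFO fields `AC`, `AN` and per-population
#' `AF_<pop>` for the seven ancestry groups; `FILTER` used as the QC flag) or
#' a TSV with columns `chrom`, `pos`, `ref`, `alt`, `AC`, `AN`, `FILTER` and
#' the `AF_<pop>` columns. Multi-allelic VCF records are split into one site
#' per alternate allele.
#'
#' Only single-nucleotide sites are kept. Sites failing QC (FILTER other than
#' `PASS`), falling outside the transcript CDS, or whose reference allele
#' disagrees with the transcript sequence are excluded and counted in the
#' `exclusions` attribute of the result. For minus-strand transcripts the
#' forward-strand VCF alleles are reverse-complemented onto the coding
#' strand. Consequences are assigned from the standard genetic code; sites in
#' the stop codon are excluded (counted as `outside_cds`).
#'
#' @param path VCF (`.vcf`) or TSV file path.
#' @param model a [TranscriptModel-class].
#' @param cohortTag which reference release the table represents (`"v1"` or
#'   `"v2"`).
#' @return data.frame of variant sites with columns `transcript_id`,
#'   `codon_index`, `position_in_codon`, `cds_pos`, `genomic_pos`, `ref`,
#'   `alt`, `AC`, `AN`, the seven `AF_<pop>` columns, `qc_pass`,
#'   `consequence`, `cohort_tag`; exclusion counts in `attr(, "exclusions")`.
#' @export
readVariantTable <- function(path, model, cohortTag = c("v2", "v1")) {
  stopifnot(is(model, "TranscriptModel"))
  cohortTag <- match.arg(cohortTag)
  if (!file.exists(path)) stop("cannot read variant table: ", path)
  raw <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) {
    readVariantVcf(path, model)
  } else {
    readVariantTsv(path)
  }
  buildVariantSites(raw, model, cohortTag)
}

readVariantVcf <- function(path, model) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  if (!all(c("AC", "AN") %in% names(info))) {
    stop("VCF INFO is missing required AC/AN fields: ", path)
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  if (length(chrom) && !all(chrom == model@chromosome)) {
    stop(sprintf("VCF contig(s) %s do not match transcript '%s' on %s",
                 paste(unique(setdiff(chrom, model@chromosome)), collapse = ","),
                 model@transcriptId, model@chromosome))
  }
  out <- data.frame(
    chrom = chrom,
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    AC = as.integer(unlist(info$AC)),
    AN = as.integer(info$AN),
    FILTER = rr$FILTER,
    stringsAsFactors = FALSE)
  for (col in afColumns()) {
    out[[col]] <- if (col %in% names(info)) as.numeric(unlist(info[[col]])) else NA_real_
  }
  out
}

readVariantTsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "AC", "AN", "FILTER")
  if (!all(need %in% names(tab))) {
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  }
  for (col in afColumns()) if (!col %in% names(tab)) tab[[col]] <- NA_real_
  tab
}

buildVariantSites <- function(raw, model, cohortTag) {
  excl <- c(not_snv = 0L, qc_fail = 0L, outside_cds = 0L, ref_mismatch = 0L)
  isSnv <- nchar(raw$ref) == 1L & nchar(raw$alt) == 1L &
    raw$ref %in% BASES & raw$alt %in% BASES
  excl[["not_snv"]] <- sum(!isSnv)
  raw <- raw[isSnv, , drop = FALSE]

  qc <- raw$FILTER %in% c("PASS", ".")
  excl[["qc_fail"]] <- sum(!qc)
  raw <- raw[qc, , drop = FALSE]

  cdsPos <- genomicToCds(model, raw$pos)
  inCds <- !is.na(cdsPos) & cdsPos <= 3L * model@proteinLength
  excl[["outside_cds"]] <- sum(!inCds)
  raw <- raw[inCds, , drop = FALSE]
  cdsPos <- cdsPos[inCds]

  ref <- raw$ref
  alt <- raw$alt
  if (model@strand == "-") {
    ref <- unname(revcompBase(ref))
    alt <- unname(revcompBase(alt))
  }
  seqchr <- as.character(model@cds)
  refOk <- substring(seqchr, cdsPos, cdsPos) == ref
  excl[["ref_mismatch"]] <- sum(!refOk)
  raw <- raw[refOk, , drop = FALSE]
  cdsPos <- cdsPos[refOk]
  ref <- ref[refOk]
  alt <- alt[refOk]

  codonIndex <- (cdsPos - 1L) %/% 3L + 1L
  posInCodon <- cdsPos - 3L * (codonIndex - 1L)
  consequence <- if (nrow(raw)) {
    classifyConsequence(model, codonIndex, posInCodon, alt)
  } else character(0)

  out <- data.frame(
    transcript_id = rep(model@transcriptId, nrow(raw)),
    codon_index = codonIndex,
    position_in_codon = posInCodon,
    cds_pos = cdsPos,
    genomic_pos = raw$pos,
    ref = ref, alt = alt,
    AC = raw$AC, AN = raw$AN,
    stringsAsFactors = FALSE)
  for (col in afColumns()) out[[col]] <- raw[[col]]
  out$qc_pass <- rep(TRUE, nrow(raw))
  out$consequence <- consequence
  out$cohort_tag <- rep(cohortTag, nrow(raw))
  if (any(out$AC > out$AN)) stop("AC exceeds AN in variant table")
  attr(out, "exclusions") <- excl
  out
}

#' Stratify population missense variants into the three control groups
#'
#' Assigns each quality-passing missense site to one of three mutually
#' exclusive presumed-benign control groups, or to none:
#' \describe{
#'   \item{Group 1}{singletons (global allele count exactly 1) in the first
#'     reference release (`cohort_tag == "v1"`).}
#'   \item{Group 2}{singletons in the second, larger release that were absent
#'     at any frequency from the first release.}
#'   \item{Group 3}{non-singleton second-release variants with minor allele
#'     frequency below 0.05\% in every one of the seven ancestry populations,
#'     excluding Group 1/2 members.}
#' }
#' Sites that are not quality-passing missense SNVs are assigned `none`.
#'
#' @param sites variant-site data.frame as from [readVariantTable()].
#' @param inV1 logical vector: was the site reported (at any frequency) in
#'   the first release?
#' @param v1AC optional integer vector of first-release allele counts
#'   (needed to recognize first-release singletons among second-release
#'   rows); `NA` where not in the first release.
#' @return data.frame with columns `group` (factor `1`,`2`,`3`,`none`) and
#'   `reason`.
#' @export
assignControlGroups <- function(sites, inV1, v1AC = NULL) {
  n <- nrow(sites)
  stopifnot(length(inV1) == n)
  if (is.null(v1AC)) v1AC <- rep(NA_integer_, n)
  group <- rep("none", n)
  reason <- rep("", n)

  eligible <- sites$qc_pass & sites$consequence == "missense"
  reason[!eligible] <- "not a quality-passing missense site"

  isV1 <- sites$cohort_tag == "v1"
  g1 <- eligible & isV1 & sites$AC == 1L
  group[g1] <- "1"
  reason[g1] <- "first-release singleton"

  g2 <- eligible & !isV1 & sites$AC == 1L & !inV1
  group[g2] <- "2"
  reason[g2] <- "second-release singleton absent from first release"

  # a second-release row that is a first-release singleton belongs to Group 1
  # by construction; it is not re-assigned here
  v1Member <- inV1 & !is.na(v1AC) & v1AC == 1L
  g3cand <- eligible & !isV1 & sites$AC > 1L & !v1Member
  if (any(g3cand)) {
    af <- as.matrix(sites[g3cand, afColumns(), drop = FALSE])
    if (anyNA(af)) {
      bad <- which(g3cand)[apply(af, 1L, anyNA)]
      stop(sprintf(
        "missing population allele frequencies for %d site(s) (first at genomic_pos %s); Group-3 evaluation requires all seven populations",
        length(bad), sites$genomic_pos[bad[1L]]))
    }
    rare <- apply(af, 1L, function(x) all(x < GROUP3_MAF_MAX))
    idx <- which(g3cand)
    group[idx[rare]] <- "3"
    reason[idx[rare]] <- "second-release rare variant, MAF < 0.05% in all populations"
    reason[idx[!rare]] <- "population MAF at or above 0.05%"
  }
  remaining <- eligible & group == "none" & reason == ""
  reason[remaining] <- "does not meet any group definition"
  data.frame(group = factor(group, levels = c("1", "2", "3", "none")),
             reason = reason, stringsAsFactors = FALSE)
}

PHENOTYPE_KEYWORDS <- c("seizure", "epilepsy", "convulsion", "gastaut",
                        "spasm", "ohtahara", "west syndrome",
                        "encephalopathy", "dravet")

#' Match phenotype terms against the epilepsy keyword list
#'
#' Case-insensitive substring matching of free-text phenotype terms against
#' the fixed epilepsy keyword list (seizure, epilepsy, convulsion, Gastaut,
#' spasm, Ohtahara, west syndrome, encephalopathy, Dravet). The additional
#' keyword `glucose` matches only for gene *SLC2A1*, whose phenotype (GLUT1
#' deficiency) is described in glucose-transport terms.
#'
#' @param terms character vector of phenotype strings.
#' @param geneSymbol gene symbol of the variant's gene.
#' @return `TRUE` if any term contains any applicable keyword.
#' @export
matchPhenotypeKeywords <- function(terms, geneSymbol = "") {
  if (length(terms) == 0L) return(FALSE)
  kw <- PHENOTYPE_KEYWORDS
  if (identical(toupper(geneSymbol), "SLC2A1")) kw <- c(kw, "glucose")
  lower <- tolower(terms)
  any(vapply(kw, function(k) any(grepl(k, lower, fixed = TRUE)), logical(1L)))
}

CLINVAR_PATHOGENIC <- c("pathogenic", "likely pathogenic",
                        "likely pathogenic; pathogenic",
                        "pathogenic; likely pathogenic")

screenPathogenicReport <- function(clinvar, hgmd) {
  cvPresent <- !is.na(clinvar) & nzchar(clinvar)
  hgPresent <- !is.na(hgmd) & nzchar(hgmd)
  cvPass <- cvPresent & tolower(trimws(clinvar)) %in% CLINVAR_PATHOGENIC
  hgPass <- hgPresent & trimws(hgmd) == "DM"
  # consensus rule: when both databases report, both must claim pathogenicity
  ifelse(cvPresent & hgPresent, cvPass & hgPass,
         ifelse(cvPresent, cvPass, ifelse(hgPresent, hgPass, FALSE)))
}

#' Qualify pathogenic-reported variants by segregation evidence
#'
#' A record first passes the database screen: ClinVar classification among
#' Pathogenic / Likely Pathogenic / their combination, and/or HGMD `DM`,
#' with consensus required when both databases report. Screened records are
#' then `qualified` when the variant arose de novo, or when it segregated in
#' all (and more than three) genotyped affected carriers with no genotyped
#' affected non-carrier and at most one genotyped unaffected carrier;
#' otherwise `unqualified`. Records failing the screen are
#' `not_pathogenic_reported`.
#'
#' @param records data.frame with columns `classification_clinvar`,
#'   `classification_hgmd` (NA or "" where absent), `de_novo` (logical),
#'   `n_affected_genotyped_carriers`, `n_affected_genotyped_noncarriers`,
#'   `n_unaffected_genotyped_carriers`.
#' @return factor with levels `qualified`, `unqualified`,
#'   `not_pathogenic_reported`, one per record.
#' @export
qualifyPathogenic <- function(records) {
  need <- c("classification_clinvar", "classification_hgmd", "de_novo",
            "n_affected_genotyped_carriers", "n_affected_genotyped_noncarriers",
            "n_unaffected_genotyped_carriers")
  if (!all(need %in% names(records))) {
    stop("evidence records must have columns: ", paste(need, collapse = ", "))
  }
  counts <- records[, need[4:6]]
  if (any(as.matrix(counts) < 0L, na.rm = TRUE)) {
    stop("genotype counts must be non-negative")
  }
  screened <- screenPathogenicReport(records$classification_clinvar,
                                     records$classification_hgmd)
  segregates <- records$n_affected_genotyped_carriers > 3L &
    records$n_affected_genotyped_noncarriers == 0L &
    records$n_unaffected_genotyped_carriers <= 1L
  status <- ifelse(!screened, "not_pathogenic_reported",
                   ifelse(records$de_novo | segregates,
                          "qualified", "unqualified"))
  factor(status, levels = c("qualified", "unqualified",
                            "not_pathogenic_reported"))
}

#' Read pathogenic-candidate evidence records from TSV
#'
#' @param path TSV with the columns documented in [qualifyPathogenic()], plus
#'   variant identity columns (`transcript_id`, `codon_index`, `ref`, `alt`)
#'   and optionally `phenotype_terms` (semicolon-separated). A small
#'   synthetic example ships with the package:
#'   `system.file("extdata", "example_evidence.tsv", package = "mtrtools")`.
#' @return data.frame of evidence records.
#' @export
readEvidenceRecords <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "")
  tab$de_novo <- as.logical(tab$de_novo)
  tab
}

#' Read a per-site coverage track
#'
#' @param path TSV with columns `chrom`, `pos`, `frac_ge_10x`.
#' @return data.frame coverage track.
#' @export
readCoverageTrack <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "frac_ge_10x")
  if (!all(need %in% names(tab))) {
    stop("coverage track must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$frac_ge_10x < 0 | tab$frac_ge_10x > 1, na.rm = TRUE)) {
    stop("frac_ge_10x values must lie in [0, 1]")
  }
  tab
}

#' Mean >= 10-fold coverage fraction over a codon's three sites
#'
#' Averages the per-site fraction of samples with at least 10-fold coverage
#' over the three genomic positions of each codon. Positions missing from the
#' track contribute 0 and the codon is flagged `incomplete` rather than
#' dropped, so thinly covered codons remain visible with a caution flag.
#'
#' @param track coverage data.frame as from [readCoverageTrack()].
#' @param model a [TranscriptModel-class].
#' @param codonIndex integer vector of codons in `1..L` (default: all).
#' @return data.frame with columns `codon_index`, `coverage`, `incomplete`.
#' @export
codonCoverage <- function(track, model, codonIndex = seq_len(model@proteinLength)) {
  stopifnot(is(model, "TranscriptModel"))
  if (any(codonIndex < 1L | codonIndex > model@proteinLength)) {
    stop("codon index out of range")
  }
  cdsPos <- rep(3L * (codonIndex - 1L), each = 3L) + 1:3
  gpos <- model@genomicPos[cdsPos]
  hit <- match(gpos, track$pos[track$chrom == model@chromosome])
  frac <- track$frac_ge_10x[track$chrom == model@chromosome][hit]
  frac[is.na(frac)] <- 0
  m <- matrix(frac, ncol = 3L, byrow = TRUE)
  found <- matrix(!is.na(hit), ncol = 3L, byrow = TRUE)
  data.frame(codon_index = codonIndex,
             coverage = rowMeans(m),
             incomplete = !apply(found, 1L, all))
}
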