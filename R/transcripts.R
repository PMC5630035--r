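#' Build and validate a TranscriptModel
#'
#' Assembles a [TranscriptModel-class] from a CDS sequence (already on the
#' coding strand, 5'->3') and its exon structure on the chromosome. The
#' CDS-to-genome coordinate map is precomputed: exon blocks are ascending on
#' the chromosome; for minus-strand transcripts coding order runs from the
#' last block's end back to the first block's start.
#'
#' A trailing stop codon is detected and recorded; the analyzed protein
#' length `L` always excludes it. Validation rejects non-ACGT characters,
#' CDS lengths not divisible by 3, exon blocks whose lengths do not sum to
#' the CDS length, and internal stop codons, each with a distinct error
#' naming the transcript.
#'
#' @param transcriptId transcript identifier.
#' @param cdsSequence character or [Biostrings::DNAString] CDS on the coding
#'   strand.
#' @param exonStarts,exonEnds integer vectors of 1-based inclusive exon
#'   bounds, ascending on the chromosome.
#' @param geneSymbol gene symbol (default the transcript id).
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @return a validated [TranscriptModel-class].
#' @examples
#' m <- buildTranscriptModel("tx1", "ATGAAATAA", 101, 109)
#' proteinLength(m)  # 2
#' @export
buildTranscriptModel <- function(transcriptId, cdsSequence, exonStarts,
                                 exonEnds, geneSymbol = transcriptId,
                                 chromosome = "chr1", strand = "+") {
  seqchr <- toupper(as.character(cdsSequence))
  if (grepl("[^ACGT]", seqchr)) {
    stop(sprintf("non-ACGT character in CDS of transcript '%s'", transcriptId))
  }
  n <- nchar(seqchr)
  if (n %% 3L != 0L) {
    stop(sprintf("CDS length (%d) of transcript '%s' is not a multiple of 3",
                 n, transcriptId))
  }
  if (length(exonStarts) != length(exonEnds) || any(exonEnds < exonStarts)) {
    stop(sprintf("malformed exon blocks for transcript '%s'", transcriptId))
  }
  widths <- exonEnds - exonStarts + 1L
  if (sum(widths) != n) {
    stop(sprintf(
      "exon block lengths (%d) do not sum to CDS length (%d) for transcript '%s'",
      sum(widths), n, transcriptId))
  }
  ncod <- n %/% 3L
  codons <- substring(seqchr, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
  hasStop <- ncod >= 1L && codons[ncod] %in% STOP_CODONS
  L <- ncod - as.integer(hasStop)
  if (L >= 1L) {
    aa <- unname(Biostrings::GENETIC_CODE[codons[seq_len(L)]])
    if (any(aa == "*")) {
      stop(sprintf("internal stop codon at codon %d in transcript '%s'",
                   which(aa == "*")[1L], transcriptId))
    }
  }
  gpos <- unlist(Map(seq.int, as.integer(exonStarts), as.integer(exonEnds)),
                 use.names = FALSE)
  if (identical(strand, "-")) gpos <- rev(gpos)
  exons <- GenomicRanges::GRanges(
    seqnames = chromosome,
    ranges = IRanges::IRanges(start = as.integer(exonStarts),
                              end = as.integer(exonEnds)),
    strand = strand)
  new("TranscriptModel",
      transcriptId = transcriptId, geneSymbol = geneSymbol,
      chromosome = chromosome, strand = strand, exons = exons,
      cds = Biostrings::DNAString(seqchr), hasStop = hasStop,
      proteinLength = as.integer(L), genomicPos = as.integer(gpos))
}

#' Interconvert CDS and genomic coordinates
#'
#' `cdsToGenomic()` maps 1-based CDS positions (coding order) to genomic
#' coordinates; `genomicToCds()` is its inverse and returns `NA` for
#' positions outside the CDS. The two maps are mutual inverses on all CDS
#' positions, on both strands.
#'
#' @param model a [TranscriptModel-class].
#' @param cdsPos integer vector of CDS positions in `1..length(cds)`.
#' @param genomicPos integer vector of genomic coordinates.
#' @return integer vector of coordinates (`NA` where unmapped).
#' @export
cdsToGenomic <- function(model, cdsPos) {
  stopifnot(is(model, "TranscriptModel"))
  out <- rep(NA_integer_, length(cdsPos))
  ok <- !is.na(cdsPos) & cdsPos >= 1L & cdsPos <= length(model@genomicPos)
  out[ok] <- model@genomicPos[cdsPos[ok]]
  out
}

#' @rdname cdsToGenomic
#' @export
genomicToCds <- function(model, genomicPos) {
  stopifnot(is(model, "TranscriptModel"))
  match(genomicPos, model@genomicPos)
}

codonStrings <- function(model) {
  seqchr <- as.character(model@cds)
  L <- model@proteinLength
  substring(seqchr, seq(1L, by = 3L, length.out = L),
            seq(3L, by = 3L, length.out = L))
}

#' Enumerate all possible single-nucleotide variants of a transcript
#'
#' Lists every single-base substitution over protein codons `1..L` (the stop
#' codon, when present, is excluded) and classifies each by the standard
#' genetic code. Exactly `9 * L` rows are produced, ordered by codon,
#' position in codon, and alternate base; for every codon the missense,
#' synonymous and nonsense tallies sum to 9.
#'
#' Alleles are expressed on the coding strand; `genomic_pos` gives the
#' chromosome coordinate of each site.
#'
#' @param model a [TranscriptModel-class].
#' @return data.frame with columns `transcript_id`, `codon_index`,
#'   `position_in_codon`, `cds_pos`, `genomic_pos`, `ref`, `alt`,
#'   `consequence`.
#' @examples
#' m <- buildTranscriptModel("tx1", "ATGCTGTAA", 1, 9)
#' table(enumeratePossibleSnvs(m)$consequence)
#' @export
enumeratePossibleSnvs <- function(model) {
  stopifnot(is(model, "TranscriptModel"))
  L <- model@proteinLength
  if (L < 1L) stop("transcript has no protein codons")
  seqchr <- as.character(model@cds)
  ncds <- 3L * L
  refAll <- strsplit(substr(seqchr, 1L, ncds), "")[[1L]]
  cdsPos <- rep(seq_len(ncds), each = 3L)
  ref <- refAll[cdsPos]
  alt <- unlist(ALT_BASES[refAll], use.names = FALSE)
  codonIndex <- (cdsPos - 1L) %/% 3L + 1L
  posInCodon <- cdsPos - 3L * (codonIndex - 1L)
  codons <- codonStrings(model)
  refCodon <- codons[codonIndex]
  altCodon <- paste0(substr(refCodon, 1L, posInCodon - 1L), alt,
                     substr(refCodon, posInCodon + 1L, 3L))
  refAA <- unname(Biostrings::GENETIC_CODE[refCodon])
  altAA <- unname(Biostrings::GENETIC_CODE[altCodon])
  consequence <- ifelse(altAA == "*", "nonsense",
                        ifelse(altAA == refAA, "synonymous", "missense"))
  data.frame(
    transcript_id = model@transcriptId,
    codon_index = codonIndex,
    position_in_codon = posInCodon,
    cds_pos = cdsPos,
    genomic_pos = model@genomicPos[cdsPos],
    ref = ref, alt = alt,
    consequence = consequence,
    stringsAsFactors = FALSE)
}

#' Classify the consequence of a single substitution
#'
#' Applies the standard genetic code on the coding strand to a substitution
#' at `position_in_codon` of codon `codon_index`.
#'
#' @param model a [TranscriptModel-class].
#' @param codonIndex codon in `1..L`.
#' @param positionInCodon position 1..3 within the codon.
#' @param altBase alternate base (coding strand), must differ from the
#'   reference base.
#' @return one of `"missense"`, `"synonymous"`, `"nonsense"`.
#' @export
classifyConsequence <- function(model, codonIndex, positionInCodon, altBase) {
  stopifnot(is(model, "TranscriptModel"))
  if (any(codonIndex < 1L | codonIndex > model@proteinLength)) {
    stop(sprintf("codon index out of range 1..%d for transcript '%s'",
                 model@proteinLength, model@transcriptId))
  }
  if (any(!positionInCodon %in% 1:3)) stop("position in codon must be 1, 2 or 3")
  if (any(!altBase %in% BASES)) stop("alternate base must be one of A, C, G, T")
  codons <- codonStrings(model)
  refCodon <- codons[codonIndex]
  ref <- substr(refCodon, positionInCodon, positionInCodon)
  if (any(ref == altBase)) stop("alternate base equals the reference base")
  altCodon <- paste0(substr(refCodon, 1L, positionInCodon - 1L), altBase,
                     substr(refCodon, positionInCodon + 1L, 3L))
  refAA <- unname(Biostrings::GENETIC_CODE[refCodon])
  altAA <- unname(Biostrings::GENETIC_CODE[altCodon])
  ifelse(altAA == "*", "nonsense",
         ifelse(altAA == refAA, "synonymous", "missense"))
}

#' Read transcript models from a CDS FASTA and an exon table
#'
#' The FASTA holds one record per transcript (record id = transcript id,
#' sequence = CDS on the coding strand). The exon table is a TSV with columns
#' `transcript_id`, `gene_symbol`, `chrom`, `strand`, `exon_start`,
#' `exon_end` (1-based inclusive, ascending on the chromosome).
#'
#' @param cdsFasta path to the CDS FASTA file.
#' @param exonTsv path to the exon structure TSV.
#' @return named list of [TranscriptModel-class] objects.
#' @export
readTranscriptModels <- function(cdsFasta, exonTsv) {
  seqs <- Biostrings::readDNAStringSet(cdsFasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  exons <- read.table(exonTsv, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(exons))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  }
  ids <- names(seqs)
  models <- lapply(ids, function(id) {
    ex <- exons[exons$transcript_id == id, , drop = FALSE]
    if (nrow(ex) == 0L) stop(sprintf("no exon rows for transcript '%s'", id))
    ex <- ex[order(ex$exon_start), , drop = FALSE]
    buildTranscriptModel(
      transcriptId = id,
      cdsSequence = as.character(seqs[[id]]),
      exonStarts = ex$exon_start, exonEnds = ex$exon_end,
      geneSymbol = if ("gene_symbol" %in% names(ex)) ex$gene_symbol[1L] else id,
      chromosome = ex$chrom[1L], strand = ex$strand[1L])
  })
  setNames(models, ids)
}

#' Write the possible-SNV table of a transcript to TSV
#'
#' @param model a [TranscriptModel-class].
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
writePossibleSnvTable <- function(model, path) {
  tab <- enumeratePossibleSnvs(model)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
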