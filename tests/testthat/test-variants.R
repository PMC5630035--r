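missenseSite <- function(AC = 1L, cohort = "v2", afs = 1e-5, qc = TRUE,
                         pos = 1L) {
  s <- data.frame(transcript_id = "tx", codon_index = 1L,
                  position_in_codon = 1L, cds_pos = 1L, genomic_pos = pos,
                  ref = "A", alt = "G", AC = AC, AN = 10000L,
                  stringsAsFactors = FALSE)
  for (col in paste0("AF_", c("AFR", "AMR", "ASJ", "EAS", "FIN", "NFE",
                              "SAS"))) s[[col]] <- afs
  s$qc_pass <- qc
  s$consequence <- "missense"
  s$cohort_tag <- cohort
  s
}

test_that("control groups follow the singleton/rare stratification rules", {
  # Group 1: first-release singleton
  g <- assignControlGroups(missenseSite(AC = 1L, cohort = "v1"), inV1 = TRUE,
                           v1AC = 1L)
  expect_equal(as.character(g$group), "1")
  # Group 2: second-release singleton absent from the first release
  g <- assignControlGroups(missenseSite(AC = 1L, cohort = "v2"), inV1 = FALSE)
  expect_equal(as.character(g$group), "2")
  # ... but not when it was already present in the first release
  g <- assignControlGroups(missenseSite(AC = 1L, cohort = "v2"), inV1 = TRUE,
                           v1AC = 1L)
  expect_equal(as.character(g$group), "none")
  # Group 3: rare non-singleton below 0.05% in all seven populations
  g <- assignControlGroups(missenseSite(AC = 3L, afs = 4e-4), inV1 = FALSE)
  expect_equal(as.character(g$group), "3")
  # one population at 6e-4 disqualifies
  s <- missenseSite(AC = 3L, afs = 4e-4)
  s$AF_EAS <- 6e-4
  g <- assignControlGroups(s, inV1 = FALSE)
  expect_equal(as.character(g$group), "none")
  # a first-release singleton seen again at AC > 1 is a Group-1 member, not 3
  g <- assignControlGroups(missenseSite(AC = 3L, afs = 4e-4), inV1 = TRUE,
                           v1AC = 1L)
  expect_equal(as.character(g$group), "none")
})

test_that("group evaluation demands population frequencies and ignores non-missense", {
  s <- missenseSite(AC = 3L)
  s$AF_NFE <- NA_real_
  expect_error(assignControlGroups(s, inV1 = FALSE),
               "missing population allele frequencies")
  syn <- missenseSite(AC = 1L, cohort = "v1")
  syn$consequence <- "synonymous"
  g <- assignControlGroups(syn, inV1 = TRUE, v1AC = 1L)
  expect_equal(as.character(g$group), "none")
})

test_that("group assignment is disjoint and stable under reordering", {
  set.seed(9)
  n <- 60L
  sites <- do.call(rbind, lapply(seq_len(n), function(i) {
    missenseSite(AC = sample(c(1L, 1L, 2L, 5L), 1L),
                 cohort = sample(c("v1", "v2"), 1L),
                 afs = sample(c(1e-5, 4e-4, 8e-4), 1L), pos = i)
  }))
  inV1 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  v1AC <- ifelse(inV1, sample(1:3, n, replace = TRUE), NA_integer_)
  g1 <- assignControlGroups(sites, inV1, v1AC)
  perm <- sample(n)
  g2 <- assignControlGroups(sites[perm, ], inV1[perm], v1AC[perm])
  expect_equal(as.character(g2$group), as.character(g1$group)[perm])
  expect_true(all(table(sites$genomic_pos, g1$group) <= 1))
})

test_that("phenotype keyword matching is case-insensitive with the SLC2A1 rule", {
  expect_true(matchPhenotypeKeywords("Dravet syndrome"))
  expect_true(matchPhenotypeKeywords("EPILEPTIC ENCEPHALOPATHY"))
  expect_true(matchPhenotypeKeywords("West syndrome, infantile"))
  expect_true(matchPhenotypeKeywords("glucose transporter deficiency",
                                     geneSymbol = "SLC2A1"))
  expect_false(matchPhenotypeKeywords("glucose transporter deficiency",
                                      geneSymbol = "SCN1A"))
  expect_false(matchPhenotypeKeywords("migraine"))
  expect_false(matchPhenotypeKeywords(character(0)))
})

evidenceRecord <- function(clinvar = "Pathogenic", hgmd = "DM",
                           deNovo = FALSE, affCar = 0L, affNon = 0L,
                           unaffCar = 0L) {
  data.frame(classification_clinvar = clinvar, classification_hgmd = hgmd,
             de_novo = deNovo,
             n_affected_genotyped_carriers = affCar,
             n_affected_genotyped_noncarriers = affNon,
             n_unaffected_genotyped_carriers = unaffCar,
             stringsAsFactors = FALSE)
}

test_that("qualification combines the database screen with segregation rules", {
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(clinvar = NA, hgmd = "DM", deNovo = TRUE))), "qualified")
  # pedigree route: more than three affected carriers, none discordant,
  # at most one unaffected carrier
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(affCar = 4L, unaffCar = 1L))), "qualified")
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(affCar = 3L, unaffCar = 1L))), "unqualified")
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(affCar = 4L, affNon = 1L))), "unqualified")
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(affCar = 4L, unaffCar = 2L))), "unqualified")
  # screen failures
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(clinvar = "Benign", hgmd = NA, deNovo = TRUE))),
    "not_pathogenic_reported")
  # consensus rule: databases must agree when both report
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(clinvar = "Benign", hgmd = "DM", deNovo = TRUE))),
    "not_pathogenic_reported")
  expect_equal(as.character(qualifyPathogenic(
    evidenceRecord(clinvar = "Likely pathogenic; Pathogenic", hgmd = NA,
                   deNovo = TRUE))), "qualified")
})

test_that("adding de novo evidence never demotes a screened record", {
  set.seed(4)
  for (i in 1:25) {
    rec <- evidenceRecord(affCar = sample(0:5, 1L),
                          affNon = sample(0:2, 1L),
                          unaffCar = sample(0:3, 1L))
    before <- qualifyPathogenic(rec)
    rec$de_novo <- TRUE
    after <- qualifyPathogenic(rec)
    expect_equal(as.character(after), "qualified")
    expect_false(as.character(before) == "qualified" &&
                   as.character(after) != "qualified")
  }
})

test_that("codon coverage averages the three sites with missing ones flagged", {
  m <- buildTranscriptModel("tx", "ATGAAATAA", 101, 109)
  track <- data.frame(chrom = "chr1", pos = 101:106,
                      frac_ge_10x = c(1, 1, 1, 0.9, 0.9, 0.6))
  cv <- codonCoverage(track, m, 1:2)
  expect_equal(cv$coverage, c(1, 0.8))
  expect_false(any(cv$incomplete))
  # drop one site of codon 1
  cv2 <- codonCoverage(track[-2L, ], m, 1L)
  expect_equal(cv2$coverage, 2 / 3)
  expect_true(cv2$incomplete)
})

test_that("the VCF reader splits, filters, maps and annotates sites", {
  # codons: ATG(101-103) CTG(104-106) TAC(107-109) GAT(110-112) stop(113-115)
  m <- buildTranscriptModel("tx", "ATGCTGTACGATTAA", 101, 115)
  rows <- c(
    "chr1\t106\t.\tG\tA\t.\tPASS\tAC=1;AN=1000",       # CTG->CTA synonymous
    "chr1\t103\t.\tG\tA,T\t.\tPASS\tAC=2,1;AN=1000",   # ATG->ATA / ATT
    "chr1\t109\t.\tC\tA\t.\tPASS\tAC=1;AN=1000",       # TAC->TAA nonsense
    "chr1\t111\t.\tA\tG\t.\tPASS\tAC=1;AN=1000",       # GAT->GGT missense
    "chr1\t104\t.\tC\tT\t.\tLowQual\tAC=1;AN=1000",    # filtered
    "chr1\t114\t.\tA\tG\t.\tPASS\tAC=1;AN=1000",       # stop codon: excluded
    "chr1\t90\t.\tA\tG\t.\tPASS\tAC=1;AN=1000")        # outside CDS
  path <- writeTestVcf(withr::local_tempfile(fileext = ".vcf"), "chr1", rows)
  sites <- readVariantTable(path, m)
  excl <- attr(sites, "exclusions")
  expect_equal(nrow(sites), 5L)  # multi-allelic contributes two
  expect_equal(unname(excl[["qc_fail"]]), 1L)
  expect_equal(unname(excl[["outside_cds"]]), 2L)
  # hand-derived consequences
  expect_equal(sites$consequence[sites$genomic_pos == 106], "synonymous")
  expect_equal(sites$consequence[sites$genomic_pos == 103],
               c("missense", "missense"))
  expect_equal(sort(sites$alt[sites$genomic_pos == 103]), c("A", "T"))
  expect_equal(sites$consequence[sites$genomic_pos == 109], "nonsense")
  expect_equal(sites$consequence[sites$genomic_pos == 111], "missense")
})

test_that("minus-strand ingestion reverse-complements forward-strand alleles", {
  # coding CDS ATGAAATAA on the minus strand of 101..109: CDS position 3
  # (coding G of the ATG codon) sits at genomic 107, forward-strand base C.
  m <- buildTranscriptModel("tx", "ATGAAATAA", 101, 109, strand = "-")
  rows <- "chr1\t107\t.\tC\tA\t.\tPASS\tAC=1;AN=1000"  # coding G>T
  path <- writeTestVcf(withr::local_tempfile(fileext = ".vcf"), "chr1", rows)
  sites <- readVariantTable(path, m)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$ref, "G")
  expect_equal(sites$alt, "T")
  expect_equal(sites$cds_pos, 3L)
  expect_equal(sites$consequence, "missense")  # ATG -> ATT (Ile)
})

test_that("contig mismatches and missing INFO fields are hard errors", {
  m <- buildTranscriptModel("tx", "ATGAAATAA", 101, 109)
  rows <- "chr2\t103\t.\tG\tA\t.\tPASS\tAC=1;AN=1000"
  path <- writeTestVcf(withr::local_tempfile(fileext = ".vcf"), "chr2", rows)
  expect_error(readVariantTable(path, m), "contig")
  expect_error(readVariantTable(withr::local_tempfile(fileext = ".vcf"), m),
               "cannot read")
})
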