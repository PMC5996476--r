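writeToyVcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

toyMeta <- function(ids, path = tempfile(fileext = ".tsv")) {
  utils::write.table(
    data.frame(sample_id = ids, region = "Asian", status = "wild",
               species = "toy"),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("GT fields map to dosages and non-SNP records are skipped", {
  vcf <- writeToyVcf(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    "chr1\t10\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t20\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0",      # indel
    "chr1\t30\t.\tG\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1",
    "chr1\t40\t.\tC\tA,G\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",     # triallelic
    "chr1\t50\t.\tT\tG\t.\tPASS\t.\tGT\t1/1\t0/0\t0/1"))
  co <- suppressMessages(readCohortVcf(vcf, toyMeta(c("s1", "s2", "s3"))))
  expect_equal(nrow(co), 3L)  # indel and triallelic dropped
  expect_equal(unname(dosages(co)[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(dosages(co)[2, 1]))
  expect_equal(GenomicRanges::start(siteRanges(co)), c(10L, 30L, 50L))
})

test_that("a VCF sample absent from metadata is an error naming it", {
  vcf <- writeToyVcf(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "sX", sep = "\t"),
    "chr1\t10\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/1"))
  expect_error(suppressMessages(readCohortVcf(vcf, toyMeta("s1"))), "sX")
})

test_that("write + read round trip preserves the cohort", {
  study <- defaultStudy()
  co <- study$cohort[1:2000, ]
  v <- tempfile(fileext = ".vcf"); m <- tempfile(fileext = ".tsv")
  writeCohortVcf(co, v, m)
  co2 <- suppressMessages(readCohortVcf(v, m))
  expect_identical(dosages(co), dosages(co2))
  expect_identical(as.character(GenomicRanges::seqnames(siteRanges(co))),
                   as.character(GenomicRanges::seqnames(siteRanges(co2))))
  expect_identical(GenomicRanges::start(siteRanges(co)),
                   GenomicRanges::start(siteRanges(co2)))
  expect_identical(siteRanges(co)$ref, siteRanges(co2)$ref)
})

test_that("missing-rate filter is strict and idempotent", {
  # site 2: missing in 3 of 6 samples (rate exactly 0.5) -> dropped
  d <- matrix(0L, 3, 6)
  d[2, 1:3] <- NA
  d[3, 1:4] <- NA                     # rate 0.667 -> dropped
  co <- makeCohort(d)
  f <- suppressMessages(filterVariants(co, 0.5))
  expect_equal(nrow(f), 1L)
  expect_identical(nrow(suppressMessages(filterVariants(f, 0.5))), nrow(f))
  # vacuous threshold keeps everything
  expect_equal(nrow(suppressMessages(filterVariants(co, 1.0))), 3L)
})

test_that("per-group filtering applies the rate within every group", {
  groups <- rep(c("wild_Asian", "wild_European"), each = 4)
  d <- matrix(0L, 2, 8)
  d[1, 1:2] <- NA        # rate 0.5 in wild_Asian -> dropped per-group
  co <- makeCohort(d, groups = groups)
  overall <- suppressMessages(filterVariants(co, 0.5))
  expect_equal(nrow(overall), 2L)     # overall rate 0.25 passes
  perGroup <- suppressMessages(
    filterVariants(co, 0.5, groups = c("wild_Asian", "wild_European")))
  expect_equal(nrow(perGroup), 1L)
})

test_that("coding-effect classification follows the codon table and strand", {
  refSeq <- paste0("AAAAAAAAA", "ATGCTTGACTAA", "AAAAAAAAA")  # CDS at 10-21
  gene <- geneModel("g1", "chr1", "+",
                    data.frame(start = 10L, end = 21L, phase = 0L))
  # third position of codon 1: ATG -> ATA is Met -> Ile
  expect_equal(classifyCodingEffect("chr1", 12L, "G", "A", gene, refSeq),
               "non-synonymous")
  # third position of codon 2: CTT -> CTC stays Leu
  expect_equal(classifyCodingEffect("chr1", 15L, "T", "C", gene, refSeq),
               "synonymous")
  # outside the CDS
  expect_equal(classifyCodingEffect("chr1", 3L, "A", "C", gene, refSeq),
               "non-coding")
  # disagreement with the reference is an error
  expect_error(classifyCodingEffect("chr1", 12L, "C", "A", gene, refSeq),
               "disagrees")
})

test_that("minus-strand classification reverse-complements correctly", {
  # coding strand CDS: ATG GAC TAA; genomic strand carries its reverse
  # complement TTAGTCCAT at positions 5..13
  refSeq <- paste0("CCCC", "TTAGTCCAT", "CCCC")
  gene <- geneModel("g2", "chr1", "-",
                    data.frame(start = 5L, end = 13L, phase = 0L))
  # genomic G->A at position 8 hits codon GAC's third base (C->T on the
  # coding strand gives GAT): Asp -> Asp
  expect_equal(classifyCodingEffect("chr1", 8L, "G", "A", gene, refSeq),
               "synonymous")
  # genomic T->C at position 9 changes GAC -> GGC: Asp -> Gly
  expect_equal(classifyCodingEffect("chr1", 9L, "T", "C", gene, refSeq),
               "non-synonymous")
})

test_that("coding-effect tallies match brute-force mutant translation", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  cdsLen <- 30L
  codingSeq <- c("ATG", sample(c("CTT", "GAC", "AAA", "TTC", "GGA", "CCT"),
                               (cdsLen - 6) / 3, replace = TRUE), "TAA")
  coding <- paste(codingSeq, collapse = "")
  refSeq <- paste0("AAAA", coding, "AAAA")
  gene <- geneModel("g3", "chr1", "+",
                    data.frame(start = 5L, end = 4L + cdsLen, phase = 0L))
  for (off in seq_len(cdsLen)) {
    pos <- 4L + off
    ref <- substr(refSeq, pos, pos)
    alt <- sample(setdiff(bases, ref), 1)
    got <- classifyCodingEffect("chr1", pos, ref, alt, gene, refSeq)
    mutant <- coding
    substr(mutant, off, off) <- alt
    aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(coding),
                                               no.init.codon = TRUE))
    aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(mutant),
                                               no.init.codon = TRUE))
    expect_equal(got, if (aa1 == aa2) "synonymous" else "non-synonymous")
  }
})
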