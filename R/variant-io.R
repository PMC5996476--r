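#' Read a multi-sample VCF plus accession metadata into a GenotypeCohort
#'
#' Genotypes become alternate-allele dosages (0/1/2, `NA` for `./.`).
#' Half-calls (e.g. `./1`) are treated as missing, and records that are not
#' biallelic SNPs (indels, multiallelic sites) are skipped with a message.
#'
#' @param path VCF file (v4.x, GT field required).
#' @param metadataPath TSV with header
#'   `sample_id region status species` (optional `group` column).
#' @return A [GenotypeCohort-class].
#' @export
readCohortVcf <- function(path, metadataPath) {
  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "status", "species")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = " "))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  isSnp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nSkip <- sum(!isSnp)
  if (nSkip) message(nSkip, " non-biallelic-SNP record(s) skipped")
  gtRaw <- v@gt[isSnp, -1, drop = FALSE]
  vcfSamples <- colnames(v@gt)[-1]
  missingMeta <- setdiff(vcfSamples, meta$sample_id)
  if (length(missingMeta))
    stop("VCF sample(s) missing from metadata: ",
         paste(missingMeta, collapse = ", "))
  meta <- meta[match(vcfSamples, meta$sample_id), , drop = FALSE]

  gt <- sub(":.*", "", gtRaw)
  gt[is.na(gt)] <- "./."           # vcfR reads missing genotypes as NA
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  bad <- !(a1 %in% c("0", "1", ".")) | !(a2 %in% c("0", "1", "."))
  if (any(bad)) {
    w <- arrayInd(which(bad)[1], dim(gtRaw))
    stop(sprintf("malformed GT '%s' at record %d, sample %s",
                 gt[bad][1], w[1], vcfSamples[w[2]]))
  }
  called <- a1 != "." & a2 != "."
  dosage <- rep(NA_integer_, length(a1))
  dosage[called] <- as.integer(a1[called]) + as.integer(a2[called])
  nHalf <- sum(xor(a1 == ".", a2 == "."))
  if (nHalf) message(nHalf, " half-call(s) treated as missing")
  dim(dosage) <- dim(gtRaw)

  chrom <- fix[isSnp, "CHROM"]
  pos <- as.integer(fix[isSnp, "POS"])
  sites <- GRanges(chrom, IRanges(pos, width = 1L),
                   ref = unname(ref[isSnp]), alt = unname(alt[isSnp]))
  ctg <- grep("^##contig", v@meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
    lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", ctg)))
    keep <- ids %in% seqlevels(sites) & !is.na(lens)
    seqlengths(sites)[ids[keep]] <- lens[keep]
  }
  GenotypeCohort(dosage, sites, meta)
}

#' Write a GenotypeCohort as a plain-text VCF v4.2 (with sidecar metadata)
#'
#' @param cohort a [GenotypeCohort-class].
#' @param path output VCF path (uncompressed).
#' @param metadataPath optional TSV path for the accession metadata.
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(cohort, path, metadataPath = NULL) {
  rr <- rowRanges(cohort)
  d <- dosages(cohort)
  gtStrings <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtStrings[d[ok] + 1L]
  sl <- seqlengths(rr)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(sl), sl),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cohort)), collapse = "\t"))
  body <- paste(as.character(seqnames(rr)), start(rr), ".",
                mcols(rr)$ref, mcols(rr)$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  if (!is.null(metadataPath))
    utils::write.table(as.data.frame(sampleInfo(cohort)), metadataPath,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter sites by missing-genotype rate
#'
#' Retains sites whose missing fraction is strictly below `maxMissingRate`,
#' either over all samples or within every listed group (the stricter,
#' per-group form used ahead of between-group scans).
#'
#' @param cohort a [GenotypeCohort-class].
#' @param maxMissingRate sites with missing rate `>=` this are dropped.
#' @param groups optional character vector of group labels; when given the
#'   rate criterion must hold within every group.
#' @return The filtered cohort; retained/dropped counts are reported via
#'   `message()`.
#' @export
filterVariants <- function(cohort, maxMissingRate = 0.5, groups = NULL) {
  stopifnot(maxMissingRate >= 0, maxMissingRate <= 1)
  d <- dosages(cohort)
  if (is.null(groups)) {
    keep <- rowMeans(is.na(d)) < maxMissingRate
  } else {
    keep <- rep(TRUE, nrow(d))
    for (g in groups) {
      ids <- samplesInGroup(cohort, g)
      keep <- keep & rowMeans(is.na(d[, ids, drop = FALSE])) < maxMissingRate
    }
  }
  message(sum(keep), " site(s) retained, ", sum(!keep), " dropped")
  cohort[keep, ]
}

#' A minimal gene model for coding-effect classification
#'
#' @param geneId gene identifier.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame `start,end,phase` (1-based inclusive), ordered 5'
#'   to 3' on the coding strand.
#' @return A `list` of class `GeneModel`.
#' @export
geneModel <- function(geneId, chrom, strand, cds) {
  stopifnot(strand %in% c("+", "-"), nrow(cds) >= 1)
  cds <- cds[order(cds$start, decreasing = (strand == "-")), , drop = FALSE]
  total <- sum(cds$end - cds$start + 1) - cds$phase[1]
  if (total %% 3 != 0)
    stop("CDS length not divisible by 3 after phase adjustment")
  structure(list(gene_id = geneId, chrom = chrom, strand = strand,
                 cds = cds), class = "GeneModel")
}

#' Classify a SNP as synonymous, non-synonymous or non-coding
#'
#' Substitutes the alternate allele into its codon (reverse-complementing on
#' minus-strand genes) and compares translated amino acids under the
#' standard code.
#'
#' @param chrom,pos,ref,alt the SNP (1-based position, genomic-strand
#'   alleles).
#' @param gene a [geneModel()].
#' @param referenceSeq a `Biostrings::DNAString` (or character) holding the
#'   chromosome sequence.
#' @return One of `"synonymous"`, `"non-synonymous"`, `"non-coding"`.
#' @export
classifyCodingEffect <- function(chrom, pos, ref, alt, gene, referenceSeq) {
  refSeq <- Biostrings::DNAString(as.character(referenceSeq))
  if (as.character(Biostrings::subseq(refSeq, pos, pos)) != ref)
    stop(sprintf("ref allele %s disagrees with reference at %s:%d",
                 ref, chrom, pos))
  if (chrom != gene$chrom) return("non-coding")
  cds <- gene$cds
  inSeg <- which(pos >= cds$start & pos <= cds$end)
  if (!length(inSeg)) return("non-coding")

  segs <- cds[order(cds$start), , drop = FALSE]
  genomicPos <- unlist(lapply(seq_len(nrow(segs)),
                              function(i) segs$start[i]:segs$end[i]))
  codingSeq <- unlist(strsplit(as.character(
    Biostrings::subseq(refSeq, min(segs$start), max(segs$end))), ""))
  codingSeq <- codingSeq[genomicPos - min(segs$start) + 1L]
  if (gene$strand == "-") {
    genomicPos <- rev(genomicPos)
    codingSeq <- rev(chartr("ACGT", "TGCA", codingSeq))
  }
  phase <- gene$cds$phase[1]
  if (phase > 0) {
    genomicPos <- genomicPos[-seq_len(phase)]
    codingSeq <- codingSeq[-seq_len(phase)]
  }
  cdsIdx <- match(pos, genomicPos)
  if (is.na(cdsIdx)) return("non-coding")

  refBase <- if (gene$strand == "+") ref else chartr("ACGT", "TGCA", ref)
  altBase <- if (gene$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  stopifnot(codingSeq[cdsIdx] == refBase)
  codonIdx <- (cdsIdx - 1L) %/% 3L
  codonPos <- codonIdx * 3L + 1:3
  refCodon <- paste(codingSeq[codonPos], collapse = "")
  mutSeq <- codingSeq; mutSeq[cdsIdx] <- altBase
  altCodon <- paste(mutSeq[codonPos], collapse = "")
  # no.init.codon: a lone CTG/TTG codon must not be read as an initiator
  aaRef <- as.character(Biostrings::translate(Biostrings::DNAString(refCodon),
                                              no.init.codon = TRUE))
  aaAlt <- as.character(Biostrings::translate(Biostrings::DNAString(altCodon),
                                              no.init.codon = TRUE))
  if (aaRef == aaAlt) "synonymous" else "non-synonymous"
}

#' Read gene annotation (GFF3) as GRanges
#'
#' @param path GFF3 file.
#' @return `GRanges` with `type`, `ID`/`Parent` metadata as imported by
#'   `rtracklayer`.
#' @export
readGff3 <- function(path) rtracklayer::import(path, format = "gff3")
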