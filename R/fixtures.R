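#' Write a simulated cohort and its truth set as a plain-text fixture
#'
#' Emits everything a downstream run needs: the VCF and accession-metadata
#' TSV, BED files of the planted truth intervals, a toy GFF3 with genes
#' tiled over the genome (so some fall inside truth intervals), and a QTL
#' BED whose intervals overlap a configurable fraction of the planted
#' sweeps.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param truth the matching [TruthSet-class].
#' @param outDir output directory (created if needed).
#' @param qtlOverlapFraction fraction of planted sweeps that get an
#'   overlapping QTL interval; the remaining QTL intervals avoid all
#'   sweeps.
#' @param nBackgroundQtl number of sweep-avoiding background QTL intervals.
#' @param seed RNG seed for QTL placement.
#' @return Named character vector of written file paths.
#' @export
emitFixture <- function(cohort, truth, outDir, qtlOverlapFraction = 0.7,
                        nBackgroundQtl = 5L, seed = 1L) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create ", outDir)
  fp <- function(f) file.path(outDir, f)
  files <- c(vcf = fp("cohort.vcf"), metadata = fp("samples.tsv"),
             truth_sweeps = fp("truth_sweeps.bed"),
             truth_ibd = fp("truth_ibd.bed"),
             truth_admixture = fp("truth_admixture.bed"),
             truth_balanced = fp("truth_balanced.bed"),
             genes = fp("genes.gff3"), qtl = fp("qtl.bed"))
  writeCohortVcf(cohort, files["vcf"], files["metadata"])

  writeBed(withName(plantedSweeps(truth),
                    function(g) paste0("sweep:", g$target_group)),
           files["truth_sweeps"])
  writeBed(withName(plantedIbd(truth),
                    function(g) paste0("ibd:", g$sample_a, "-", g$sample_b)),
           files["truth_ibd"])
  writeBed(withName(admixtureBlocks(truth),
                    function(g) paste0("admix:", g$donor)),
           files["truth_admixture"])
  writeBed(withName(balancedIntervals(truth), function(g)
    rep("balanced", length(g))), files["truth_balanced"])

  sl <- seqlengths(rowRanges(cohort))
  writeToyGff3(sl, files["genes"])
  qtl <- buildQtlIntervals(plantedSweeps(truth), sl, qtlOverlapFraction,
                           nBackgroundQtl, seed)
  writeBed(qtl, files["qtl"])
  files
}

withName <- function(gr, f) {
  if (length(gr)) gr$name <- f(gr) else gr$name <- character()
  gr
}

writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = if (!is.null(gr$name)) gr$name else ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as GRanges (1-based internal coordinates)
#'
#' @param path BED path (0-based half-open on disk).
#' @param genomeSizes optional named chromosome lengths to set.
#' @return `GRanges` with a `name` column when present.
#' @export
readBed <- function(path, genomeSizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genomeSizes))
    suppressWarnings(seqlengths(gr) <- genomeSizes[seqlevels(gr)])
  gr
}

# genes of 3 kb tiled every 50 kb: 200-bp 5' UTR, CDS 201-1199 and
# 1800-2798 (0-based offsets, 1998 bp total), intron between, 3' UTR tail
writeToyGff3 <- function(seqlens, path) {
  rows <- character()
  gid <- 0L
  for (ch in names(seqlens)) {
    starts <- seq(10001L, seqlens[[ch]] - 3000L, by = 50000L)
    for (s in starts) {
      gid <- gid + 1L
      g <- sprintf("gene%04d", gid); m <- paste0(g, ".t1")
      e <- s + 2999L
      feat <- function(type, a, b, id, parent = NA, phase = ".")
        sprintf("%s\ttoy\t%s\t%d\t%d\t.\t+\t%s\t%s", ch, type, a, b, phase,
                if (is.na(parent)) paste0("ID=", id)
                else paste0("ID=", id, ";Parent=", parent))
      rows <- c(rows,
        feat("gene", s, e, g),
        feat("mRNA", s, e, m, g),
        feat("exon", s, s + 1198L, paste0(m, ".e1"), m),
        feat("exon", s + 1800L, e, paste0(m, ".e2"), m),
        feat("five_prime_UTR", s, s + 199L, paste0(m, ".u5"), m),
        feat("CDS", s + 200L, s + 1198L, paste0(m, ".c1"), m, phase = "0"),
        feat("CDS", s + 1800L, s + 2798L, paste0(m, ".c2"), m, phase = "0"),
        feat("three_prime_UTR", s + 2799L, e, paste0(m, ".u3"), m))
    }
  }
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", names(seqlens),
                       seqlens)), path)
  cat(rows, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

buildQtlIntervals <- function(sweeps, seqlens, fraction, nBackground, seed) {
  set.seed(seed)
  stopifnot(fraction >= 0, fraction <= 1)
  qchr <- character(); qs <- integer(); qe <- integer()
  nHit <- round(fraction * length(sweeps))
  if (nHit > 0) {
    hit <- sweeps[seq_len(nHit)]
    qchr <- as.character(seqnames(hit))
    qs <- pmax(1L, start(hit) - 20000L)
    qe <- pmin(seqlens[qchr], start(hit) + 30000L)
  }
  # background QTLs of 50 kb avoiding every planted sweep
  for (k in seq_len(nBackground)) {
    for (try in 1:50) {
      ch <- names(seqlens)[sample.int(length(seqlens), 1L)]
      s <- sample.int(seqlens[[ch]] - 50000L, 1L)
      cand <- GRanges(ch, IRanges(s, s + 49999L))
      if (!length(findOverlaps(cand, sweeps))) {
        qchr <- c(qchr, ch); qs <- c(qs, s); qe <- c(qe, s + 49999L)
        break
      }
    }
  }
  qtl <- sort(GRanges(qchr, IRanges(qs, qe)))
  qtl$name <- sprintf("qtl%02d", seq_along(qtl))
  qtl
}
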