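#' Tajima's D normalizing constants
#'
#' The standard a1, a2, b1, b2, c1, c2, e1, e2 constants for a sample of
#' `n` chromosomes.
#'
#' @param n number of sampled chromosomes (>= 2).
#' @return Named list of the eight constants.
#' @export
tajimaConstants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# windows tiling each chromosome: start 1, given step; trailing partial
# window clipped at the chromosome end
scanWindows <- function(sites, spec) {
  sl <- seqlengths(sites)
  if (any(is.na(sl)))
    sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ch)
      max(end(sites)[as.character(seqnames(sites)) == ch]), 0)
  startList <- lapply(names(sl), function(ch) seq(1L, sl[[ch]], by = spec@stepBp))
  chrom <- rep(names(sl), lengths(startList))
  starts <- unlist(startList, use.names = FALSE)
  ends <- pmin(starts + spec@windowBp - 1L, sl[chrom])
  w <- GRanges(chrom, IRanges(starts, unname(ends)))
  seqlevels(w) <- seqlevels(sites)
  suppressWarnings(seqlengths(w) <- sl[seqlevels(w)])
  w
}

# per-site pairwise-diversity ingredients for one sample set
perSiteDiversity <- function(dosage) {
  sc <- siteCounts(dosage)
  C <- sc$C; cc <- sc$c
  usable <- C >= 2L
  seg <- usable & cc > 0L & cc < C
  pi <- numeric(length(C))
  pi[usable] <- 2 * cc[usable] * (C[usable] - cc[usable]) /
    (C[usable] * (C[usable] - 1))
  list(pi = pi, seg = seg, usable = usable, C = C)
}

#' Windowed nucleotide diversity, Watterson's theta and Tajima's D
#'
#' For each window: per-site pairwise diversity
#' `pi = 2 c (C - c) / (C (C - 1))` with `C` called allele copies and `c`
#' alternate copies (pairwise deletion under missingness), summed into
#' `theta_pi_count`; the segregating-site count `S`; the effective
#' chromosome number `n_chrom` (rounded harmonic mean of per-site `C`, since
#' Tajima's constants assume a fixed sample size); per-site
#' `theta_pi = theta_pi_count / L` and `theta_w = S / (a1 L)`; and
#' `tajima_d = (theta_pi_count - S/a1) / sqrt(e1 S + e2 S (S-1))`,
#' `NA` when `S = 0`.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param group group label (see [groupOf()]).
#' @param spec a [windowSpec()]; diversity scans conventionally use 10-kb
#'   windows with a 5-kb step.
#' @param callableSites optional numeric vector of per-window effective site
#'   counts used as `L` instead of the window span.
#' @return `GRanges` of windows with metadata columns `group`, `S`,
#'   `n_chrom`, `theta_pi_count`, `theta_pi`, `theta_w`, `tajima_d`, `L`.
#' @export
windowDiversity <- function(cohort, group, spec = windowSpec(10000L, 5000L),
                            callableSites = NULL) {
  validObject(spec)
  ids <- samplesInGroup(cohort, group)
  if (length(ids) < 2) stop("group '", group, "' has fewer than 2 samples")
  d <- dosages(cohort)[, ids, drop = FALSE]
  sites <- rowRanges(cohort)
  win <- scanWindows(sites, spec)
  ps <- perSiteDiversity(d)

  ov <- findOverlaps(sites, win)
  wIdx <- S4Vectors::subjectHits(ov); sIdx <- S4Vectors::queryHits(ov)
  use <- ps$usable[sIdx]
  wIdx <- wIdx[use]; sIdx <- sIdx[use]
  nW <- length(win)
  piCount <- rowsumAt(ps$pi[sIdx], wIdx, nW)
  S <- rowsumAt(as.numeric(ps$seg[sIdx]), wIdx, nW)
  invC <- rowsumAt(1 / ps$C[sIdx], wIdx, nW)
  nSites <- rowsumAt(rep(1, length(sIdx)), wIdx, nW)

  nChrom <- ifelse(nSites > 0, round(nSites / invC), NA_real_)
  L <- if (is.null(callableSites)) width(win) else {
    stopifnot(length(callableSites) == nW)
    callableSites
  }
  tajd <- rep(NA_real_, nW)
  thetaW <- rep(NA_real_, nW)
  for (w in which(nSites > 0 & nChrom >= 2)) {
    k <- tajimaConstants(nChrom[w])
    thetaW[w] <- S[w] / (k$a1 * L[w])
    if (S[w] > 0) {
      v <- k$e1 * S[w] + k$e2 * S[w] * (S[w] - 1)
      tajd[w] <- (piCount[w] - S[w] / k$a1) / sqrt(v)
    }
  }
  thetaW[nSites > 0 & S == 0] <- 0
  thetaW[nSites == 0] <- 0

  mcols(win) <- DataFrame(
    group = group, S = as.integer(S), n_chrom = as.integer(nChrom),
    theta_pi_count = piCount, theta_pi = piCount / L,
    theta_w = thetaW, tajima_d = tajd, L = as.numeric(L),
    n_sites = as.integer(nSites))
  win
}

rowsumAt <- function(x, idx, n) {
  out <- numeric(n)
  if (length(idx)) {
    s <- rowsum(x, idx)
    out[as.integer(rownames(s))] <- s[, 1]
  }
  out
}

#' Windowed Hudson F_ST between two groups
#'
#' Per site, the Hudson estimator with numerator
#' `(p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1)` and
#' denominator `p1 (1 - p2) + p2 (1 - p1)` (`p` = alternate-allele
#' frequency, `n` = called allele copies); the window value is the
#' ratio of summed numerators to summed denominators. Sites monomorphic
#' across both groups together, or with fewer than 4 called copies in either
#' group, are skipped; windows with no usable site are `NA`.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param groupA,groupB group labels.
#' @param spec a [windowSpec()].
#' @return `GRanges` of windows with metadata columns `group_a`, `group_b`,
#'   `fst`, `n_sites`.
#' @export
windowFst <- function(cohort, groupA, groupB, spec = windowSpec()) {
  validObject(spec)
  idsA <- samplesInGroup(cohort, groupA)
  idsB <- samplesInGroup(cohort, groupB)
  if (length(idsA) < 2 || length(idsB) < 2)
    stop("both groups need >= 2 samples")
  d <- dosages(cohort)
  hs <- hudsonSiteComponents(d[, idsA, drop = FALSE], d[, idsB, drop = FALSE])
  sites <- rowRanges(cohort)
  win <- scanWindows(sites, spec)
  ov <- findOverlaps(sites, win)
  wIdx <- S4Vectors::subjectHits(ov); sIdx <- S4Vectors::queryHits(ov)
  use <- hs$usable[sIdx]
  wIdx <- wIdx[use]; sIdx <- sIdx[use]
  nW <- length(win)
  num <- rowsumAt(hs$num[sIdx], wIdx, nW)
  den <- rowsumAt(hs$den[sIdx], wIdx, nW)
  nSites <- rowsumAt(rep(1, length(sIdx)), wIdx, nW)
  fst <- ifelse(nSites > 0 & den > 0, num / den, NA_real_)
  mcols(win) <- DataFrame(group_a = groupA, group_b = groupB, fst = fst,
                          n_sites = as.integer(nSites))
  win
}

hudsonSiteComponents <- function(dA, dB) {
  a <- siteCounts(dA); b <- siteCounts(dB)
  n1 <- a$C; n2 <- b$C
  p1 <- ifelse(n1 > 0, a$c / n1, NA_real_)
  p2 <- ifelse(n2 > 0, b$c / n2, NA_real_)
  usable <- n1 >= 4L & n2 >= 4L &
    !((a$c + b$c) == 0L | (a$c + b$c) == (n1 + n2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den, usable = usable & !is.na(num))
}

#' Hudson F_ST for explicit allele frequencies and sample sizes
#'
#' Single-site form of the estimator used by [windowFst()], convenient for
#' worked examples and cross-checks.
#'
#' @param p1,p2 alternate-allele frequencies.
#' @param n1,n2 called allele copies.
#' @return The ratio-of-sums Hudson estimate over the provided sites.
#' @export
hudsonFst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Windowed reduction of diversity (ROD)
#'
#' `ROD = 1 - theta_pi_cultivated / theta_pi_wild` per window; values near 1
#' mark diversity lost during domestication. `NA` where wild diversity
#' is zero.
#'
#' @param divCultivated,divWild outputs of [windowDiversity()] on identical
#'   window grids.
#' @return `GRanges` of windows with metadata columns `rod`,
#'   `theta_pi_cul`, `theta_pi_wild`.
#' @export
windowRod <- function(divCultivated, divWild) {
  sameGrid(divCultivated, divWild)
  piC <- divCultivated$theta_pi
  piW <- divWild$theta_pi
  rod <- ifelse(is.na(piW) | piW == 0, NA_real_, 1 - piC / piW)
  out <- granges(divCultivated)
  mcols(out) <- DataFrame(rod = rod, theta_pi_cul = piC, theta_pi_wild = piW)
  out
}

sameGrid <- function(a, b) {
  if (length(a) != length(b) ||
      !all(as.character(seqnames(a)) == as.character(seqnames(b))) ||
      !all(start(a) == start(b)) || !all(end(a) == end(b)))
    stop("window grids do not match")
  invisible(TRUE)
}

#' Nucleotide diversity by genomic feature class
#'
#' Assigns each SNP to exactly one class by the precedence
#' CDS > UTR > intron > other-mRNA > intergenic and computes per-class
#' diversity with `L` equal to the class footprint in bp.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param group group label.
#' @param gff `GRanges` from [readGff3()] (feature `type` column used).
#' @param classes classes to report (subset of the five above).
#' @return `data.frame` with `class`, `L`, `n_sites`, `S`, `theta_pi`,
#'   `theta_w`.
#' @export
diversityByFeature <- function(cohort, group, gff,
                               classes = c("CDS", "UTR", "intron",
                                           "mRNA_other", "intergenic")) {
  known <- c("CDS", "UTR", "intron", "mRNA_other", "intergenic")
  if (!all(classes %in% known))
    stop("unknown feature class: ",
         paste(setdiff(classes, known), collapse = ", "))
  ids <- samplesInGroup(cohort, group)
  d <- dosages(cohort)[, ids, drop = FALSE]
  sites <- granges(rowRanges(cohort))
  sl <- seqlengths(sites)

  typ <- as.character(gff$type)
  cds <- reduce(gff[typ == "CDS"])
  utr <- reduce(gff[typ %in% c("five_prime_UTR", "three_prime_UTR", "UTR")])
  mrna <- reduce(gff[typ == "mRNA"])
  exon <- reduce(gff[typ %in% c("exon", "CDS", "five_prime_UTR",
                                "three_prime_UTR", "UTR")])
  intron <- GenomicRanges::setdiff(mrna, exon, ignore.strand = TRUE)
  utr <- GenomicRanges::setdiff(utr, cds, ignore.strand = TRUE)
  intron <- GenomicRanges::setdiff(intron,
    GenomicRanges::union(cds, utr, ignore.strand = TRUE),
    ignore.strand = TRUE)
  covered <- GenomicRanges::union(
    GenomicRanges::union(cds, utr, ignore.strand = TRUE), intron,
    ignore.strand = TRUE)
  mrnaOther <- GenomicRanges::setdiff(mrna, covered, ignore.strand = TRUE)
  genome <- GRanges(names(sl), IRanges(1L, sl))
  genic <- GenomicRanges::union(covered, mrnaOther, ignore.strand = TRUE)
  intergenic <- GenomicRanges::setdiff(genome, genic, ignore.strand = TRUE)
  classRanges <- list(CDS = cds, UTR = utr, intron = intron,
                      mRNA_other = mrnaOther, intergenic = intergenic)

  ps <- perSiteDiversity(d)
  assigned <- rep(NA_character_, length(sites))
  for (cl in known) {  # precedence order
    hit <- overlapsAny(sites, classRanges[[cl]], ignore.strand = TRUE)
    assigned[is.na(assigned) & hit] <- cl
  }
  out <- lapply(classes, function(cl) {
    idx <- which(assigned == cl & ps$usable)
    L <- sum(width(classRanges[[cl]]))
    S <- sum(ps$seg[idx])
    piCount <- sum(ps$pi[idx])
    thetaW <- if (L > 0 && length(idx) && S > 0) {
      n <- round(length(idx) / sum(1 / ps$C[idx]))
      S / (tajimaConstants(max(n, 2))$a1 * L)
    } else 0
    data.frame(class = cl, L = L, n_sites = length(idx), S = S,
               theta_pi = if (L > 0) piCount / L else 0, theta_w = thetaW)
  })
  do.call(rbind, out)
}

#' @importFrom IRanges overlapsAny
NULL

#' Evolution-rate estimator d / (2T)
#'
#' Per-year substitution-rate proxy for a gene: `d` is its nucleotide
#' diversity and `T` the time in years since divergence from the most
#' recent common ancestor.
#'
#' @param d nucleotide diversity (>= 0).
#' @param T divergence time in years (> 0).
#' @return `list(d, T, rate)` with `rate = d / (2 * T)` in sites/year.
#' @export
evolutionRate <- function(d, T) {
  if (T <= 0) stop("T must be positive")
  if (d < 0) stop("d must be non-negative")
  list(d = d, T = T, rate = d / (2 * T))
}
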