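#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed allele counts: the p-value is the
#' sum of probabilities of all heterozygote configurations whose
#' conditional probability does not exceed that of the observed
#' configuration. Probabilities follow the standard recurrence over the
#' feasible heterozygote counts. Monomorphic sites return 1.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return Two-sided exact p-value.
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("no genotypes")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # unnormalized log conditional probabilities via the recurrence
  # P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1)),
  # with nAA(h) = (nA - h)/2 and naa(h) = (na - h)/2
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    logp[k] <- logp[k - 1L] +
      log(4 * ((nA - h) / 2) * ((na - h) / 2) / ((h + 2) * (h + 1)))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  if (is.na(obs)) stop("observed heterozygote count infeasible")
  sum(p[p <= obs * (1 + 1e-12)])
}

# EM haplotype-frequency estimation for many site pairs at once.
# counts: matrix with columns n00,n01,n02,n10,n11,n12,n20,n21,n22
# (rows = pairs; genotype g1*3+g2 order). Returns pAB and margins.
emHapFreqs <- function(counts, tol = 1e-10, maxIter = 1000L) {
  n <- rowSums(counts)
  # column index = g1 * 3 + g2 + 1 ("A"/"B" = alt allele at site 1/2)
  g1 <- rep(0:2, each = 3); g2 <- rep(0:2, times = 3)
  pA <- as.vector(counts %*% g1) / (2 * n)
  pB <- as.vector(counts %*% g2) / (2 * n)
  dh <- counts[, 5]                     # double heterozygotes, phase unknown
  # AB haplotype copies contributed by each phase-unambiguous genotype class
  abContrib <- c(0, 0, 0, 0, NA, 1, 0, 1, 2)
  known <- as.vector(counts[, -5, drop = FALSE] %*% abContrib[-5])
  pAB <- pA * pB
  for (it in seq_len(maxIter)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    num <- pAB * pab
    den <- num + pAb * paB
    frac <- ifelse(den > 0, num / den, 0.5)
    pABnew <- (known + dh * frac) / (2 * n)
    pABnew <- pmin(pmax(pABnew, pmax(0, pA + pB - 1)), pmin(pA, pB))
    delta <- max(abs(pABnew - pAB), na.rm = TRUE)
    pAB <- pABnew
    if (delta < tol) break
  }
  list(pAB = pAB, pA = pA, pB = pB, n = n, iterations = it)
}

hapStats <- function(fit) {
  D <- fit$pAB - fit$pA * fit$pB
  denom <- fit$pA * (1 - fit$pA) * fit$pB * (1 - fit$pB)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  Dmax <- ifelse(D >= 0, pmin(fit$pA * (1 - fit$pB), fit$pB * (1 - fit$pA)),
                 pmin(fit$pA * fit$pB, (1 - fit$pA) * (1 - fit$pB)))
  dprime <- ifelse(Dmax > 0, abs(D) / Dmax, NA_real_)
  list(D = D, r2 = r2, dprime = dprime)
}

genotypePairCounts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tab <- tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
  matrix(tab, 1L, 9L)
}

#' Two-locus r-squared from unphased diploid genotypes
#'
#' Haplotype frequencies are estimated by EM over unphased genotype pairs
#' (double heterozygotes carry ambiguous phase), initialized at linkage
#' equilibrium and iterated to `|delta| < 1e-10` (max 1000 iterations);
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))` from the converged frequencies.
#' Samples missing at either site are dropped pairwise.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) at the two sites.
#' @return list with `hap_freqs` (pAB, pAb, paB, pab), `D`, `r2`,
#'   `dprime`, `n`; all statistics `NA` when either site is monomorphic
#'   after pairwise deletion.
#' @export
pairR2 <- function(g1, g2) {
  counts <- genotypePairCounts(g1, g2)
  fit <- emHapFreqs(counts)
  if (fit$n == 0 || fit$pA %in% c(0, 1) || fit$pB %in% c(0, 1))
    return(list(hap_freqs = rep(NA_real_, 4), D = NA_real_, r2 = NA_real_,
                dprime = NA_real_, n = fit$n))
  st <- hapStats(fit)
  list(hap_freqs = c(pAB = fit$pAB, pAb = fit$pA - fit$pAB,
                     paB = fit$pB - fit$pAB,
                     pab = 1 - fit$pA - fit$pB + fit$pAB),
       D = st$D, r2 = st$r2, dprime = st$dprime, n = fit$n)
}

#' Site filters applied before LD computation
#'
#' Defaults mirror common practice for LD scans of resequencing data:
#' pair distance capped at 200 kb, minor-allele frequency >= 0.05,
#' per-site genotyping rate >= 0.6, Hardy-Weinberg exact p >= 0.01.
#'
#' @param maxDistanceBp,minMaf,minGenotypingRate,hwePCutoff thresholds.
#' @return list of class `LDFilterConfig`.
#' @export
ldFilterConfig <- function(maxDistanceBp = 200000L, minMaf = 0.05,
                           minGenotypingRate = 0.6, hwePCutoff = 0.01) {
  stopifnot(maxDistanceBp > 0, minMaf >= 0, minMaf <= 1,
            minGenotypingRate >= 0, minGenotypingRate <= 1,
            hwePCutoff >= 0, hwePCutoff <= 1)
  structure(list(maxDistanceBp = as.integer(maxDistanceBp), minMaf = minMaf,
                 minGenotypingRate = minGenotypingRate,
                 hwePCutoff = hwePCutoff), class = "LDFilterConfig")
}

restrictToAnchors <- function(cohort, nAnchors, anchorWidthBp, seed) {
  if (is.null(nAnchors)) return(cohort)
  set.seed(seed)
  sl <- seqlengths(rowRanges(cohort))
  ch <- names(sl)[sample.int(length(sl), nAnchors, replace = TRUE)]
  s <- vapply(ch, function(x)
    sample.int(max(sl[[x]] - anchorWidthBp, 1L), 1L), 0L)
  anchors <- GRanges(ch, IRanges(s, s + anchorWidthBp - 1L))
  keep <- overlapsAny(rowRanges(cohort), anchors)
  cohort[keep, ]
}

defaultLdBins <- function(maxDistanceBp) {
  edges <- c(seq(0L, min(2000L, maxDistanceBp), by = 100L))
  if (maxDistanceBp > 2000L)
    edges <- c(edges, seq(3000L, maxDistanceBp, by = 1000L))
  edges
}

#' Binned LD-decay profile for one group
#'
#' Sites are pre-filtered (MAF, genotyping rate, HWE exact test), all
#' within-chromosome pairs up to the distance cap are evaluated with the
#' EM r-squared of [pairR2()], and mean r-squared is reported per distance
#' bin (100-bp bins to 2 kb, 1-kb bins beyond, by default).
#'
#' For genome-scale inputs the full set of eligible pairs is quadratic in
#' site density; `nAnchors` restricts the computation to all pairs inside
#' `nAnchors` anchor regions of `anchorWidthBp` placed uniformly at random
#' (seeded), which preserves the short-range decay shape at a bounded cost.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param group group label.
#' @param filters an [ldFilterConfig()].
#' @param binEdges optional increasing vector of bin edges in bp.
#' @param nAnchors optional number of anchor regions; `NULL` evaluates
#'   every eligible pair.
#' @param anchorWidthBp width of each anchor region.
#' @param seed RNG seed for anchor placement.
#' @return `data.frame` with `bin_start`, `bin_end`, `mid`, `mean_r2`,
#'   `mean_dprime`, `n_pairs`; zero rows when no eligible pair exists.
#' @export
ldDecayProfile <- function(cohort, group, filters = ldFilterConfig(),
                           binEdges = NULL, nAnchors = NULL,
                           anchorWidthBp = 20000L, seed = 1L) {
  ids <- samplesInGroup(cohort, group)
  cohort <- restrictToAnchors(cohort, nAnchors, anchorWidthBp, seed)
  d <- dosages(cohort)[, ids, drop = FALSE]
  sc <- siteCounts(d)
  maf <- pmin(sc$c / sc$C, 1 - sc$c / sc$C)
  genoRate <- (sc$C / 2) / length(ids)
  pass <- !is.na(maf) & maf >= filters$minMaf &
    genoRate >= filters$minGenotypingRate
  if (filters$hwePCutoff > 0) {
    for (i in which(pass)) {
      gi <- d[i, ]
      p <- hweExactTest(sum(gi == 2L, na.rm = TRUE),
                        sum(gi == 1L, na.rm = TRUE),
                        sum(gi == 0L, na.rm = TRUE))
      if (p < filters$hwePCutoff) pass[i] <- FALSE
    }
  }
  emptyProfile <- data.frame(bin_start = integer(), bin_end = integer(),
                             mid = numeric(), mean_r2 = numeric(),
                             mean_dprime = numeric(), n_pairs = integer())
  if (sum(pass) < 2) return(emptyProfile)

  sites <- rowRanges(cohort)[pass]
  dd <- d[pass, , drop = FALSE]
  chroms <- as.character(seqnames(sites))
  posAll <- start(sites)
  pairI <- integer(); pairJ <- integer()
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    pos <- posAll[idx]
    cnt <- findInterval(pos + filters$maxDistanceBp, pos) - seq_along(pos)
    i <- rep(seq_along(pos), cnt)
    j <- i + sequence(cnt)
    pairI <- c(pairI, idx[i]); pairJ <- c(pairJ, idx[j])
  }
  if (!length(pairI)) return(emptyProfile)

  I0 <- !is.na(dd) & dd == 0L; I1 <- !is.na(dd) & dd == 1L
  I2 <- !is.na(dd) & dd == 2L
  ind <- list(I0, I1, I2)
  counts <- matrix(0, length(pairI), 9L)
  for (a in 0:2) for (b in 0:2)
    counts[, a * 3L + b + 1L] <-
      rowSums(ind[[a + 1L]][pairI, , drop = FALSE] &
                ind[[b + 1L]][pairJ, , drop = FALSE])
  fit <- emHapFreqs(counts)
  st <- hapStats(fit)
  r2 <- st$r2; dprime <- st$dprime
  mono <- fit$pA %in% c(0, 1) | fit$pB %in% c(0, 1) | fit$n == 0
  r2[mono] <- NA_real_; dprime[mono] <- NA_real_
  dist <- posAll[pairJ] - posAll[pairI]

  if (is.null(binEdges)) binEdges <- defaultLdBins(filters$maxDistanceBp)
  bin <- cut(dist, binEdges, right = TRUE, labels = FALSE)
  ok <- !is.na(bin) & !is.na(r2)
  if (!any(ok)) return(emptyProfile)
  agg <- rowsum(cbind(r2 = r2[ok], dp = dprime[ok], n = 1), bin[ok])
  b <- as.integer(rownames(agg))
  data.frame(bin_start = binEdges[b], bin_end = binEdges[b + 1L],
             mid = (binEdges[b] + binEdges[b + 1L]) / 2,
             mean_r2 = agg[, 1] / agg[, 3], mean_dprime = agg[, 2] / agg[, 3],
             n_pairs = as.integer(agg[, 3]))
}

#' Distance at which LD decays to half its maximum
#'
#' The maximum is the largest binned mean r-squared; the function returns
#' the midpoint of the first bin (scanning left to right in distance) whose
#' mean is at or below half that maximum, or `NA` if the profile never
#' reaches it.
#'
#' @param profile output of [ldDecayProfile()].
#' @return Distance in bp, or `NA_real_`.
#' @export
halfDecayDistance <- function(profile) {
  if (!nrow(profile)) stop("empty LD profile")
  profile <- profile[order(profile$mid), , drop = FALSE]
  mx <- max(profile$mean_r2)
  hit <- which(profile$mean_r2 <= mx / 2)
  if (!length(hit)) NA_real_ else profile$mid[hit[1]]
}
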