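#' Dosage p-distance similarity between two genotype vectors
#'
#' Per-site distance `|g_i - g_j| / 2` (the allele-content distance for
#' unphased diploids: two opposite homozygotes are distance 1, a
#' homozygote and a heterozygote 1/2, two heterozygotes 0), averaged over
#' co-called sites (pairwise deletion); similarity is one minus that mean.
#'
#' @param gi,gj dosage vectors (0/1/2/NA).
#' @return Similarity in `[0, 1]`, or `NA` with zero co-called sites.
#' @export
pairSimilarity <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) return(NA_real_)
  1 - mean(abs(gi[ok] - gj[ok]) / 2)
}

# site -> window index for a non-overlapping grid (one window per site)
siteWindowIndex <- function(sites, windows) {
  ov <- findOverlaps(sites, windows, select = "first")
  ov
}

# per-window co-called counts and similarity for one pair, given the
# precomputed site -> window assignment
pairWindowSimilarityIdx <- function(gi, gj, winIdx, nW) {
  ok <- !is.na(gi) & !is.na(gj) & !is.na(winIdx)
  sIdx <- which(ok); wIdx <- winIdx[ok]
  nSnps <- rowsumAt(rep(1, length(sIdx)), wIdx, nW)
  distSum <- rowsumAt(abs(gi[sIdx] - gj[sIdx]) / 2, wIdx, nW)
  sim <- ifelse(nSnps > 0, 1 - distSum / nSnps, NA_real_)
  list(n_snps = as.integer(nSnps), similarity = sim)
}

pairWindowSimilarity <- function(cohort, i, j, windows) {
  d <- dosages(cohort)
  pairWindowSimilarityIdx(d[, i], d[, j],
                          siteWindowIndex(rowRanges(cohort), windows),
                          length(windows))
}

#' Windowed IBD profile of an accession pair
#'
#' Similarity is computed in contiguous non-overlapping windows (10 kb by
#' default); a window is evaluable when it holds more than `minSnps`
#' co-called SNPs (strictly more than 10 by default) and is flagged IBD
#' when its similarity strictly exceeds 0.95. `P_ij` is the percentage of
#' IBD windows among evaluable windows genome-wide.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param i,j sample ids.
#' @param spec a [windowSpec()]; `minSnps` is the strict lower bound on
#'   co-called SNPs per window.
#' @param similarityCutoff IBD similarity threshold (strict).
#' @return An [IBDProfile-class].
#' @export
pairIbdProfile <- function(cohort, i, j,
                           spec = windowSpec(10000L, 10000L, minSnps = 10L),
                           similarityCutoff = 0.95) {
  stopifnot(i %in% colnames(cohort), j %in% colnames(cohort))
  windows <- scanWindows(rowRanges(cohort), spec)
  ws <- pairWindowSimilarity(cohort, i, j, windows)
  evaluable <- ws$n_snps > spec@minSnps
  flag <- evaluable & !is.na(ws$similarity) &
    ws$similarity > similarityCutoff
  mcols(windows) <- DataFrame(n_snps = ws$n_snps,
                              similarity = ws$similarity,
                              evaluable = evaluable, ibd_flag = flag)
  pij <- if (sum(evaluable) == 0) NA_real_ else
    100 * sum(flag) / sum(evaluable)
  new("IBDProfile", pair = c(i, j), windows = windows, pij = pij)
}

#' Genome-wide IBD percentage matrix
#'
#' `P_ij` ([pairIbdProfile()]) for every pair of the requested samples.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param samples sample ids (default: all).
#' @param spec,similarityCutoff as in [pairIbdProfile()].
#' @return Symmetric numeric matrix of `P_ij` percentages (diagonal 100).
#' @export
ibdMatrix <- function(cohort, samples = colnames(cohort),
                      spec = windowSpec(10000L, 10000L, minSnps = 10L),
                      similarityCutoff = 0.95) {
  n <- length(samples)
  P <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  diag(P) <- 100
  windows <- scanWindows(rowRanges(cohort), spec)
  winIdx <- siteWindowIndex(rowRanges(cohort), windows)
  d <- dosages(cohort)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ws <- pairWindowSimilarityIdx(d[, samples[a]], d[, samples[b]],
                                  winIdx, length(windows))
    evaluable <- ws$n_snps > spec@minSnps
    flag <- evaluable & !is.na(ws$similarity) &
      ws$similarity > similarityCutoff
    P[a, b] <- P[b, a] <- if (sum(evaluable) == 0) NA_real_ else
      100 * sum(flag) / sum(evaluable)
  }
  P
}

#' Group-level mean IBD (AverIBD)
#'
#' `AverIBD = (1/k) * sum_i sum_j P_ij` over pairs with `i` in `group`
#' and `j` in `referenceSet`; self-pairs are excluded when the two sets
#' overlap, and `k` counts the pairs with a non-missing `P_ij`.
#'
#' @param pijMatrix symmetric matrix from [ibdMatrix()].
#' @param groupSamples,referenceSamples sample id vectors.
#' @param group optional group label to record.
#' @return `data.frame` row with `group`, `n`, `m`, `k`, `aver_ibd`.
#' @export
averIbd <- function(pijMatrix, groupSamples, referenceSamples,
                    group = NA_character_) {
  stopifnot(all(groupSamples %in% rownames(pijMatrix)),
            all(referenceSamples %in% colnames(pijMatrix)))
  vals <- c()
  for (i in groupSamples) for (j in referenceSamples)
    if (i != j) vals <- c(vals, pijMatrix[i, j])
  k <- sum(!is.na(vals))
  if (k == 0) stop("no usable pairs between group and reference set")
  data.frame(group = group, n = length(groupSamples),
             m = length(referenceSamples), k = k,
             aver_ibd = mean(vals, na.rm = TRUE))
}

#' Paint an accession's genome by donor group
#'
#' For each evaluable window, the target's similarity to every member of
#' the two donor groups is computed; the window is assigned to the group
#' whose best-matching member passes the IBD criterion (co-called SNPs
#' above `minSnps`, similarity above the cutoff) with the higher maximum
#' similarity. Ties and windows where neither group passes are unassigned.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param target sample id, must not belong to either donor group.
#' @param donorA,donorB donor group labels.
#' @param spec,similarityCutoff as in [pairIbdProfile()].
#' @return list with `windows` (`GRanges` with `label`), and `proportions`
#'   (percent of evaluable windows labeled `donorA`, `donorB`,
#'   `unassigned`).
#' @export
paintAncestry <- function(cohort, target, donorA, donorB,
                          spec = windowSpec(10000L, 10000L, minSnps = 10L),
                          similarityCutoff = 0.95) {
  idsA <- samplesInGroup(cohort, donorA)
  idsB <- samplesInGroup(cohort, donorB)
  if (target %in% c(idsA, idsB))
    stop("target belongs to a donor group")
  windows <- scanWindows(rowRanges(cohort), spec)
  winIdx <- siteWindowIndex(rowRanges(cohort), windows)
  d <- dosages(cohort)
  gt <- d[, target]
  bestOf <- function(ids) {
    best <- rep(-Inf, length(windows)); anyEval <- rep(FALSE, length(windows))
    for (id in ids) {
      ws <- pairWindowSimilarityIdx(gt, d[, id], winIdx, length(windows))
      okW <- ws$n_snps > spec@minSnps & !is.na(ws$similarity)
      anyEval <- anyEval | okW
      s <- ifelse(okW, ws$similarity, -Inf)
      best <- pmax(best, s)
    }
    list(best = best, anyEval = anyEval)
  }
  a <- bestOf(idsA); b <- bestOf(idsB)
  evaluable <- a$anyEval | b$anyEval
  passA <- a$best > similarityCutoff
  passB <- b$best > similarityCutoff
  label <- rep("unassigned", length(windows))
  label[passA & (!passB | a$best > b$best)] <- donorA
  label[passB & (!passA | b$best > a$best)] <- donorB
  label[passA & passB & a$best == b$best] <- "unassigned"
  label[!evaluable] <- NA_character_
  windows$label <- label
  nEval <- sum(evaluable)
  prop <- c(
    100 * sum(label == donorA, na.rm = TRUE) / nEval,
    100 * sum(label == donorB, na.rm = TRUE) / nEval,
    100 * sum(label == "unassigned", na.rm = TRUE) / nEval)
  names(prop) <- c(donorA, donorB, "unassigned")
  list(windows = windows, proportions = prop)
}
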