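#' Percentile threshold with tie inclusion
#'
#' Returns the cut value such that the qualifying set (the top or bottom
#' `q` fraction) has at least `ceiling(q * N)` members, with ties at the
#' threshold included; missing values are excluded from `N`.
#'
#' @param values numeric vector (may contain `NA`).
#' @param q quantile fraction in (0, 1).
#' @param side `"top"` or `"bottom"`.
#' @return The threshold value.
#' @export
quantileThreshold <- function(values, q, side = c("top", "bottom")) {
  side <- match.arg(side)
  v <- values[!is.na(values)]
  if (!length(v)) stop("all values missing")
  stopifnot(q > 0, q < 1)
  k <- ceiling(q * length(v))
  if (side == "top") sort(v, decreasing = TRUE)[k] else sort(v)[k]
}

#' Criteria for calling selective sweeps
#'
#' A window qualifies when jointly: F_ST at or above its top
#' `fstTopQuantile` genome-wide cut, `ROD > rodMin`, and the screened
#' group's Tajima's D at or below its bottom `tajdBottomQuantile` cut.
#'
#' @param fstTopQuantile top F_ST fraction (default 0.05).
#' @param rodMin ROD threshold (default 0.5).
#' @param tajdBottomQuantile bottom Tajima's D fraction (default 0.10).
#' @return list of class `SweepCriteria`.
#' @export
sweepCriteria <- function(fstTopQuantile = 0.05, rodMin = 0.5,
                          tajdBottomQuantile = 0.10) {
  stopifnot(fstTopQuantile > 0, fstTopQuantile < 1,
            rodMin > 0, rodMin <= 1,
            tajdBottomQuantile > 0, tajdBottomQuantile < 1)
  structure(list(fstTopQuantile = fstTopQuantile, rodMin = rodMin,
                 tajdBottomQuantile = tajdBottomQuantile),
            class = "SweepCriteria")
}

#' Criteria for calling balancing-selection regions
#'
#' Conjunctive: bottom `fstBottomQuantile` of F_ST, top `tajdTopQuantile`
#' of Tajima's D, top `thetaPiTopQuantile` of theta-pi.
#'
#' @param fstBottomQuantile,tajdTopQuantile,thetaPiTopQuantile fractions.
#' @return list of class `BalancingCriteria`.
#' @export
balancingCriteria <- function(fstBottomQuantile = 0.05,
                              tajdTopQuantile = 0.05,
                              thetaPiTopQuantile = 0.10) {
  stopifnot(fstBottomQuantile > 0, fstBottomQuantile < 1,
            tajdTopQuantile > 0, tajdTopQuantile < 1,
            thetaPiTopQuantile > 0, thetaPiTopQuantile < 1)
  structure(list(fstBottomQuantile = fstBottomQuantile,
                 tajdTopQuantile = tajdTopQuantile,
                 thetaPiTopQuantile = thetaPiTopQuantile),
            class = "BalancingCriteria")
}

mergeQualifying <- function(windows, qualify, statCols) {
  qw <- windows[qualify]
  if (!length(qw)) {
    out <- GRanges()
    mcols(out) <- DataFrame(n_windows = integer(),
                            lapply(statCols, function(x) numeric()))
    return(out)
  }
  regions <- reduce(granges(qw), min.gapwidth = 1L)
  ov <- findOverlaps(regions, qw)
  byRegion <- split(S4Vectors::subjectHits(ov),
                    factor(S4Vectors::queryHits(ov),
                           levels = seq_along(regions)))
  stats <- lapply(statCols, function(f)
    vapply(byRegion,
           function(ii) f(mcols(qw)[ii, , drop = FALSE]), numeric(1)))
  mcols(regions) <- DataFrame(
    n_windows = as.integer(countOverlaps(regions, qw)), stats)
  regions
}

#' Call selective-sweep regions by joint percentile criteria
#'
#' Window grids must be identical non-overlapping scans. Thresholds are
#' computed genome-wide; a window with any missing statistic never
#' qualifies; adjacent qualifying windows are merged into maximal regions.
#'
#' @param fstWindows output of [windowFst()].
#' @param rodWindows output of [windowRod()].
#' @param tajdWindows [windowDiversity()] of the screened (cultivated)
#'   group, same grid.
#' @param criteria a [sweepCriteria()].
#' @return `GRanges` of merged regions with `n_windows`, `max_fst`,
#'   `max_rod`, `min_tajd` and an empty `gene_ids` slot for
#'   [annotateRegions()].
#' @export
callSelectiveSweeps <- function(fstWindows, rodWindows, tajdWindows,
                                criteria = sweepCriteria()) {
  sameGrid(fstWindows, rodWindows); sameGrid(fstWindows, tajdWindows)
  fst <- fstWindows$fst; rod <- rodWindows$rod; tajd <- tajdWindows$tajima_d
  fstCut <- quantileThreshold(fst, criteria$fstTopQuantile, "top")
  tajdCut <- quantileThreshold(tajd, criteria$tajdBottomQuantile, "bottom")
  qualify <- !is.na(fst) & !is.na(rod) & !is.na(tajd) &
    fst >= fstCut & rod > criteria$rodMin & tajd <= tajdCut
  win <- granges(fstWindows)
  mcols(win) <- DataFrame(fst = fst, rod = rod, tajd = tajd)
  out <- mergeQualifying(win, qualify, list(
    max_fst = function(m) max(m$fst), max_rod = function(m) max(m$rod),
    min_tajd = function(m) min(m$tajd)))
  metadata(out) <- list(fst_cut = fstCut, tajd_cut = tajdCut,
                        criteria = criteria)
  out
}

#' Call balancing-selection regions
#'
#' Conjunctive on low F_ST, high Tajima's D and high theta-pi; same grid,
#' merging and missing-value rules as [callSelectiveSweeps()].
#'
#' @param fstWindows output of [windowFst()].
#' @param tajdWindows,piWindows [windowDiversity()] of the screened group.
#' @param criteria a [balancingCriteria()].
#' @return `GRanges` of merged regions.
#' @export
callBalancingRegions <- function(fstWindows, tajdWindows, piWindows,
                                 criteria = balancingCriteria()) {
  sameGrid(fstWindows, tajdWindows); sameGrid(fstWindows, piWindows)
  fst <- fstWindows$fst; tajd <- tajdWindows$tajima_d
  pi <- piWindows$theta_pi
  fstCut <- quantileThreshold(fst, criteria$fstBottomQuantile, "bottom")
  tajdCut <- quantileThreshold(tajd, criteria$tajdTopQuantile, "top")
  piCut <- quantileThreshold(pi, criteria$thetaPiTopQuantile, "top")
  qualify <- !is.na(fst) & !is.na(tajd) & !is.na(pi) &
    fst <= fstCut & tajd >= tajdCut & pi >= piCut
  win <- granges(fstWindows)
  mcols(win) <- DataFrame(fst = fst, tajd = tajd, pi = pi)
  out <- mergeQualifying(win, qualify, list(
    min_fst = function(m) min(m$fst), max_tajd = function(m) max(m$tajd),
    max_pi = function(m) max(m$pi)))
  metadata(out) <- list(fst_cut = fstCut, tajd_cut = tajdCut,
                        pi_cut = piCut, criteria = criteria)
  out
}

#' Annotate regions with overlapping gene ids
#'
#' A gene overlapping at least 1 bp of a region (half-open interval
#' arithmetic: a gene starting exactly where a region ends is not counted)
#' is listed once per region.
#'
#' @param regions `GRanges` from [callSelectiveSweeps()] or
#'   [callBalancingRegions()].
#' @param gff `GRanges` annotation ([readGff3()]); `type == "gene"` rows
#'   are used, ids from `ID` (falling back to `gene_id`/`Name`).
#' @return `regions` with a `gene_ids` `CharacterList` column.
#' @export
annotateRegions <- function(regions, gff) {
  genes <- gff[as.character(gff$type) == "gene"]
  ids <- genes$ID
  if (is.null(ids)) ids <- genes$gene_id
  if (is.null(ids)) ids <- genes$Name
  ov <- findOverlaps(regions, genes, ignore.strand = TRUE)
  lst <- split(ids[S4Vectors::subjectHits(ov)],
               factor(S4Vectors::queryHits(ov), levels = seq_along(regions)))
  regions$gene_ids <- IRanges::CharacterList(lapply(lst, unique))
  regions
}
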