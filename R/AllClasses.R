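#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   findOverlaps countOverlaps reduce granges
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqinfo Seqinfo
NULL

VALID_REGIONS <- c("Asian", "European")
VALID_STATUS  <- c("wild", "cultivated")

#' Cohort of diploid biallelic genotypes with sample group labels
#'
#' `GenotypeCohort` extends `RangedSummarizedExperiment`: the single assay
#' `"dosage"` holds alternate-allele counts (0, 1, 2 or `NA` for missing) as
#' a sites-by-samples integer matrix, `rowRanges()` carries the site
#' coordinates with `ref`/`alt` alleles in its metadata columns, and
#' `colData()` carries the accession metadata (`region`, `status`, `species`,
#' `group`).
#'
#' The `group` column is the label used by every two-group statistic; for
#' ordinary accessions it is `<status>_<region>` (e.g. `cultivated_Asian`),
#' while special accessions (an admixed mosaic) carry their own label and are
#' excluded from the four status-by-region groups.
#'
#' @name GenotypeCohort-class
#' @aliases GenotypeCohort
#' @exportClass GenotypeCohort
setClass("GenotypeCohort", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  cd <- colData(object)
  for (col in c("region", "status", "species", "group"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  if ("region" %in% colnames(cd) && !all(cd$region %in% VALID_REGIONS))
    msg <- c(msg, "region must be 'Asian' or 'European'")
  if ("status" %in% colnames(cd) && !all(cd$status %in% VALID_STATUS))
    msg <- c(msg, "status must be 'wild' or 'cultivated'")
  rr <- rowRanges(object)
  if (!all(c("ref", "alt") %in% colnames(mcols(rr))))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
  else {
    if (!all(nchar(mcols(rr)$ref) == 1L) || !all(nchar(mcols(rr)$alt) == 1L))
      msg <- c(msg, "only biallelic SNPs allowed (single-base ref and alt)")
  }
  pos <- split(start(rr), as.character(seqnames(rr)))
  if (!all(vapply(pos, function(p) !is.unsorted(p, strictly = TRUE), TRUE)))
    msg <- c(msg, "positions must be strictly increasing within chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param dosage integer matrix, sites x samples, values 0/1/2/NA.
#' @param sites `GRanges` of width-1 SNP positions with metadata columns
#'   `ref` and `alt`; `seqlengths()` should be set.
#' @param samples `data.frame` or `DataFrame` with columns `sample_id`,
#'   `region`, `status`, `species` and optionally `group`.
#' @return A [GenotypeCohort-class] object.
#' @export
GenotypeCohort <- function(dosage, sites, samples) {
  samples <- as.data.frame(samples)
  stopifnot(nrow(dosage) == length(sites), ncol(dosage) == nrow(samples))
  if (is.null(samples$group))
    samples$group <- paste(samples$status, samples$region, sep = "_")
  cd <- DataFrame(samples, row.names = samples$sample_id)
  colnames(dosage) <- samples$sample_id
  mode(dosage) <- "integer"
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = sites, colData = cd)
  new("GenotypeCohort", se)
}

#' Simulator truth set: planted features of a synthetic cohort
#'
#' Records the intervals the simulator planted (sweeps, IBD segments,
#' admixture blocks, balanced locus) as `GRanges`, so parameter-recovery
#' tests can compare calls against ground truth.
#'
#' @slot sweeps `GRanges` with column `target_group`.
#' @slot ibd `GRanges` with columns `sample_a`, `sample_b`.
#' @slot admixture `GRanges` with column `donor` (group label per block) and
#'   `sample_id`.
#' @slot balanced `GRanges` of loci under balancing selection.
#' @exportClass TruthSet
setClass("TruthSet", representation(
  sweeps = "GRanges", ibd = "GRanges",
  admixture = "GRanges", balanced = "GRanges"))

#' @describeIn TruthSet-class planted sweep intervals
#' @param x a `TruthSet`
#' @export
setMethod("plantedSweeps", "TruthSet", function(x) x@sweeps)
#' @describeIn TruthSet-class planted IBD segments
#' @export
setMethod("plantedIbd", "TruthSet", function(x) x@ibd)
#' @describeIn TruthSet-class admixture donor blocks
#' @export
setMethod("admixtureBlocks", "TruthSet", function(x) x@admixture)
#' @describeIn TruthSet-class balanced-selection intervals
#' @export
setMethod("balancedIntervals", "TruthSet", function(x) x@balanced)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:",
      length(object@sweeps), "sweep(s),",
      length(object@ibd), "IBD segment(s),",
      length(object@admixture), "admixture block(s),",
      length(object@balanced), "balanced locus(i)\n")
})

#' Windowing scheme for scan statistics
#'
#' Diversity scans default to 10-kb windows sliding by 5 kb; selection and
#' IBD scans use non-overlapping 10-kb windows (`stepBp == windowBp`).
#'
#' @slot windowBp window size in bp.
#' @slot stepBp step between window starts in bp.
#' @slot minSnps minimum SNPs for a window to be evaluable.
#' @exportClass WindowSpec
setClass("WindowSpec", representation(
  windowBp = "integer", stepBp = "integer", minSnps = "integer"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@windowBp <= 0L || object@stepBp <= 0L)
    msg <- c(msg, "window and step must be positive")
  if (object@stepBp > object@windowBp)
    msg <- c(msg, "step must not exceed window size")
  if (object@minSnps < 0L) msg <- c(msg, "minSnps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param windowBp,stepBp,minSnps see [WindowSpec-class].
#' @rdname WindowSpec-class
#' @export
windowSpec <- function(windowBp = 10000L, stepBp = windowBp, minSnps = 1L) {
  new("WindowSpec", windowBp = as.integer(windowBp),
      stepBp = as.integer(stepBp), minSnps = as.integer(minSnps))
}

setMethod("show", "WindowSpec", function(object) {
  cat(sprintf("WindowSpec: %d bp windows, step %d bp, minSnps %d\n",
              object@windowBp, object@stepBp, object@minSnps))
})

#' Result of a permutation colocalization test
#'
#' @slot observed observed count of sweep windows overlapping a QTL.
#' @slot nPermutations number of random re-placements.
#' @slot nullCounts summary of the null overlap distribution.
#' @slot nullDraws the raw per-permutation null overlap counts (kept so
#'   calibration studies can form randomized tie-broken p-values).
#' @slot pValue empirical one-sided p with +1 correction.
#' @slot seed RNG seed used.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  observed = "integer", nPermutations = "integer",
  nullCounts = "numeric", nullDraws = "integer",
  pValue = "numeric", seed = "integer"))

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult: observed %d overlapping windows; null mean %.2f; p = %.3g (%d permutations, seed %d)\n",
    object@observed, object@nullCounts[["mean"]], object@pValue,
    object@nPermutations, object@seed))
})

#' Windowed IBD profile of one accession pair
#'
#' @slot pair the two sample ids.
#' @slot windows `GRanges` with per-window `n_snps`, `similarity`,
#'   `evaluable`, `ibd_flag`.
#' @slot pij genome-wide percentage of IBD windows among evaluable windows.
#' @exportClass IBDProfile
setClass("IBDProfile", representation(
  pair = "character", windows = "GRanges", pij = "numeric"))

setMethod("show", "IBDProfile", function(object) {
  cat(sprintf("IBDProfile %s ~ %s: %d evaluable windows, P_ij = %s\n",
              object@pair[1], object@pair[2],
              sum(object@windows$evaluable),
              if (is.na(object@pij)) "NA" else sprintf("%.2f%%", object@pij)))
})
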