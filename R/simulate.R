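#' Configuration of a synthetic resequencing cohort
#'
#' Describes a two-region (Asian-like / European-like) by two-status
#' (wild / cultivated) diploid cohort generated under a hierarchical
#' Balding--Nichols drift model, with optional planted features: selective
#' sweeps in a target group, identity-by-descent segments between sample
#' pairs, an admixed accession built as a block mosaic of two donor groups,
#' and a hypervariable locus under balancing selection.
#'
#' @slot nChromosomes,chromLengthBp genome layout.
#' @slot snpDensity expected SNPs per kb.
#' @slot groupSizes named integer vector, names `<status>_<region>`.
#' @slot fRegion divergence parameter between the two regional ancestries,
#'   in `[0, 1)`.
#' @slot fStatus wild-to-cultivated drift parameter, in `[0, 1)`.
#' @slot sweepSpecs data.frame `chrom,start,end,group,intensity`.
#' @slot ibdSpecs data.frame `sample_a,sample_b,chrom,start,end`.
#' @slot admixtureSpec list `sample_id,donor_a,donor_b,proportion_a,
#'   block_length_bp` or empty list.
#' @slot balancedLocus list `chrom,start,end,n_classes` or empty list.
#' @slot missingRate uniform genotype dropout rate.
#' @slot ldPoolSize haplotype-pool size per group for the mosaic LD mode;
#'   `0` (default) draws sites independently.
#' @slot ldSegmentBp mean haplotype-copy segment length in LD mode.
#' @slot seed RNG seed.
#' @exportClass CohortConfig
setClass("CohortConfig", representation(
  nChromosomes = "integer", chromLengthBp = "integer", snpDensity = "numeric",
  groupSizes = "integer", fRegion = "numeric", fStatus = "numeric",
  sweepSpecs = "data.frame", ibdSpecs = "data.frame",
  admixtureSpec = "list", balancedLocus = "list",
  missingRate = "numeric", ldPoolSize = "integer", ldSegmentBp = "numeric",
  seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L || object@chromLengthBp < 1L)
    msg <- c(msg, "need at least one chromosome of positive length")
  if (object@snpDensity <= 0) msg <- c(msg, "snpDensity must be positive")
  gs <- object@groupSizes
  if (is.null(names(gs)) || any(!nzchar(names(gs))))
    msg <- c(msg, "groupSizes must be named")
  if (any(gs < 2L))
    msg <- c(msg, "every group must have >= 2 samples")
  ok_groups <- as.vector(outer(VALID_STATUS, VALID_REGIONS, paste, sep = "_"))
  if (!all(names(gs) %in% ok_groups))
    msg <- c(msg, "group names must be <status>_<region>")
  if (object@fRegion < 0 || object@fRegion >= 1 ||
      object@fStatus < 0 || object@fStatus >= 1)
    msg <- c(msg, "fRegion and fStatus must be in [0, 1)")
  sw <- object@sweepSpecs
  if (nrow(sw)) {
    if (any(!sw$group %in% names(gs)))
      msg <- c(msg, "sweep target group absent from groupSizes")
    if (any(sw$intensity <= 0 | sw$intensity > 1))
      msg <- c(msg, "sweep intensity must be in (0, 1]")
    if (any(sw$start < 1 | sw$end > object@chromLengthBp | sw$start >= sw$end))
      msg <- c(msg, "sweep interval outside chromosome bounds")
  }
  ib <- object@ibdSpecs
  if (nrow(ib) &&
      any(ib$start < 1 | ib$end > object@chromLengthBp | ib$start >= ib$end))
    msg <- c(msg, "IBD interval outside chromosome bounds")
  ad <- object@admixtureSpec
  if (length(ad)) {
    if (!all(c(ad$donor_a, ad$donor_b) %in% names(gs)))
      msg <- c(msg, "admixture donor group absent from groupSizes")
    if (ad$proportion_a < 0 || ad$proportion_a > 1)
      msg <- c(msg, "admixture proportion must be in [0, 1]")
  }
  bl <- object@balancedLocus
  if (length(bl)) {
    if (bl$start < 1 || bl$end > object@chromLengthBp || bl$start >= bl$end)
      msg <- c(msg, "balanced locus outside chromosome bounds")
    if (bl$n_classes < 2) msg <- c(msg, "balanced locus needs >= 2 classes")
    if (nrow(sw)) {
      same_chrom <- sw$chrom == bl$chrom
      if (any(same_chrom & sw$start <= bl$end & sw$end >= bl$start))
        msg <- c(msg,
          "sweep interval overlaps the balanced locus (ambiguous truth)")
    }
  }
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param nChromosomes,chromLengthBp,snpDensity,groupSizes,fRegion,fStatus
#'   see [CohortConfig-class].
#' @param sweepSpecs,ibdSpecs,admixtureSpec,balancedLocus planted features.
#' @param missingRate,ldPoolSize,ldSegmentBp,seed see [CohortConfig-class].
#' @rdname CohortConfig-class
#' @export
cohortConfig <- function(nChromosomes = 2L, chromLengthBp = 5000000L,
                         snpDensity = 10,
                         groupSizes = c(wild_Asian = 12L,
                                        cultivated_Asian = 12L,
                                        wild_European = 12L,
                                        cultivated_European = 12L),
                         fRegion = 0.25, fStatus = 0.06,
                         sweepSpecs = emptySweepSpecs(),
                         ibdSpecs = emptyIbdSpecs(),
                         admixtureSpec = list(), balancedLocus = list(),
                         missingRate = 0.05, ldPoolSize = 0L,
                         ldSegmentBp = 2000, seed = 1L) {
  gs <- as.integer(groupSizes); names(gs) <- names(groupSizes)
  new("CohortConfig", nChromosomes = as.integer(nChromosomes),
      chromLengthBp = as.integer(chromLengthBp), snpDensity = snpDensity,
      groupSizes = gs, fRegion = fRegion, fStatus = fStatus,
      sweepSpecs = as.data.frame(sweepSpecs),
      ibdSpecs = as.data.frame(ibdSpecs),
      admixtureSpec = admixtureSpec, balancedLocus = balancedLocus,
      missingRate = missingRate, ldPoolSize = as.integer(ldPoolSize),
      ldSegmentBp = ldSegmentBp, seed = as.integer(seed))
}

#' @rdname CohortConfig-class
#' @export
emptySweepSpecs <- function()
  data.frame(chrom = character(), start = integer(), end = integer(),
             group = character(), intensity = numeric())

#' @rdname CohortConfig-class
#' @export
emptyIbdSpecs <- function()
  data.frame(sample_a = character(), sample_b = character(),
             chrom = character(), start = integer(), end = integer())

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d x %.1f Mb, ~%.1f SNPs/kb, %d samples (seed %d)\n",
    object@nChromosomes, object@chromLengthBp / 1e6, object@snpDensity,
    sum(object@groupSizes) + as.integer(length(object@admixtureSpec) > 0),
    object@seed))
  cat(sprintf("  fRegion %.2f, fStatus %.2f; %d sweep(s), %d IBD segment(s)",
              object@fRegion, object@fStatus, nrow(object@sweepSpecs),
              nrow(object@ibdSpecs)))
  cat(sprintf(", admixture: %s, balanced locus: %s\n",
              if (length(object@admixtureSpec)) "yes" else "no",
              if (length(object@balancedLocus)) "yes" else "no"))
})

groupSampleIds <- function(groupSizes) {
  abbrev <- c(wild_Asian = "wA", cultivated_Asian = "cA",
              wild_European = "wE", cultivated_European = "cE")
  unlist(lapply(names(groupSizes), function(g)
    sprintf("%s%02d", abbrev[[g]], seq_len(groupSizes[[g]]))),
    use.names = FALSE)
}

#' The default synthetic study cohort
#'
#' Two 5-Mb chromosomes at ~10 SNPs/kb, four groups of twelve accessions
#' (half the per-group size of a typical resequencing panel), three
#' planted full-intensity sweeps in cultivated Asian samples, one 200-kb IBD
#' segment between two wild Asian accessions, one admixed accession built
#' as a 60/40 mosaic of the two cultivated donor pools, and one 50-kb
#' balanced locus with six haplotype classes. All planted intervals are
#' aligned to the 10-kb scan grid.
#'
#' @param seed RNG seed for the simulation.
#' @return A [CohortConfig-class] (or, for `defaultCohortArgs`, the
#'   argument list it is built from, convenient for partial overrides).
#' @export
defaultCohortConfig <- function(seed = 1L) {
  do.call(cohortConfig, defaultCohortArgs(seed))
}

#' @rdname defaultCohortConfig
#' @export
defaultCohortArgs <- function(seed = 1L) {
  list(
    sweepSpecs = data.frame(
      chrom = c("chr1", "chr1", "chr2"),
      start = c(1000001L, 3000001L, 2000001L),
      end = c(1200000L, 3100000L, 2150000L),
      group = "cultivated_Asian", intensity = 1.0),
    ibdSpecs = data.frame(
      sample_a = "wA01", sample_b = "wA02",
      chrom = "chr1", start = 2000001L, end = 2200000L),
    admixtureSpec = list(sample_id = "adm01",
                         donor_a = "cultivated_Asian",
                         donor_b = "cultivated_European",
                         proportion_a = 0.6, block_length_bp = 500000L),
    balancedLocus = list(chrom = "chr2", start = 4000001L, end = 4050000L,
                         n_classes = 6L),
    seed = seed)
}

# Balding-Nichols draw of descendant frequencies around p with drift F
bnDraw <- function(p, f) {
  if (f <= 0) return(p)
  q <- stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  # rbeta returns NaN when both shapes underflow to 0; keep the fixed allele
  ifelse(is.nan(q), round(p), q)
}

# mosaic haplotype copied from a pool: per-site pool index with exponential
# segment lengths of mean segBp
mosaicIndex <- function(pos, nPool, segBp) {
  switchP <- 1 - exp(-diff(pos) / segBp)
  idx <- integer(length(pos))
  idx[1] <- sample.int(nPool, 1L)
  sw <- stats::runif(length(switchP)) < switchP
  cur <- idx[1]
  for (k in seq_along(sw)) {
    if (sw[k]) cur <- sample.int(nPool, 1L)
    idx[k + 1L] <- cur
  }
  idx
}

#' Simulate a genotype cohort with planted features
#'
#' Ancestral allele frequencies are drawn from a symmetric Beta(0.35, 0.35)
#' (a folded spectrum rich in low-frequency variants, so genome-wide
#' Tajima's D sits slightly below zero as in real resequencing panels);
#' region- and status-level frequencies follow a hierarchical
#' Balding--Nichols model (`fRegion`, then `fStatus` from the wild group of
#' each region); genotypes are two independent allele copies per sample.
#' Planted sweeps erase standing variation in the target group at rate
#' `intensity` and sprinkle singleton heterozygotes so the local frequency
#' spectrum is skewed toward rare variants; IBD segments overwrite one
#' sample's genotypes with its partner's; the admixed accession is a block
#' mosaic copied from random donors; the balanced locus holds
#' `n_classes` haplotype classes at equal frequency in every group.
#'
#' @param config a [CohortConfig-class].
#' @return `list(cohort = GenotypeCohort, truth = TruthSet)`.
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  gs <- config@groupSizes
  chroms <- sprintf("chr%d", seq_len(config@nChromosomes))
  L <- config@chromLengthBp
  seqinfo <- Seqinfo(chroms, rep(L, length(chroms)))

  sampleIds <- groupSampleIds(gs)
  groups <- rep(names(gs), gs)
  meta <- data.frame(
    sample_id = sampleIds,
    region = sub(".*_", "", groups),
    status = sub("_.*", "", groups),
    species = ifelse(sub(".*_", "", groups) == "Asian",
                     "Pyrus_pyrifolia_like", "Pyrus_communis_like"),
    group = groups, stringsAsFactors = FALSE)
  adm <- config@admixtureSpec
  if (length(adm)) {
    meta <- rbind(meta, data.frame(
      sample_id = adm$sample_id, region = "Asian", status = "cultivated",
      species = "admixed_hybrid", group = "admixed"))
  }
  nSamp <- nrow(meta)

  siteList <- list(); dosList <- list()
  balanced_gr <- GRanges(seqinfo = seqinfo)
  bl <- config@balancedLocus
  regions <- unique(meta$region[meta$group != "admixed"])

  for (chrom in chroms) {
    nSites <- round(config@snpDensity * L / 1000)
    pos <- sort(sample.int(L, nSites))
    p0 <- stats::rbeta(nSites, 0.35, 0.35)
    pRegion <- lapply(regions, function(r) bnDraw(p0, config@fRegion))
    names(pRegion) <- regions
    pGroup <- list()
    for (g in names(gs)) {
      r <- sub(".*_", "", g); st <- sub("_.*", "", g)
      pGroup[[g]] <- if (st == "wild") pRegion[[r]]
                     else bnDraw(pRegion[[r]], config@fStatus)
    }
    dos <- matrix(NA_integer_, nSites, nSamp,
                  dimnames = list(NULL, meta$sample_id))
    for (g in names(gs)) {
      cols <- which(meta$group == g)
      p <- pGroup[[g]]
      if (config@ldPoolSize > 0L) {
        P <- config@ldPoolSize
        pool <- matrix(stats::rbinom(nSites * P, 1L, p), nSites, P)
        for (col in cols) {
          h1 <- pool[cbind(seq_len(nSites),
                           mosaicIndex(pos, P, config@ldSegmentBp))]
          h2 <- pool[cbind(seq_len(nSites),
                           mosaicIndex(pos, P, config@ldSegmentBp))]
          dos[, col] <- h1 + h2
        }
      } else {
        dos[, cols] <- stats::rbinom(nSites * length(cols), 2L, p)
      }
    }

    # balanced locus: n_classes haplotypes at equal frequency in all groups
    if (length(bl) && bl$chrom == chrom) {
      inLoc <- which(pos >= bl$start & pos <= bl$end)
      if (length(inLoc)) {
        K <- bl$n_classes
        haps <- matrix(stats::rbinom(length(inLoc) * K, 1L, 0.5),
                       length(inLoc), K)
        memberCols <- which(meta$group != "admixed")
        for (col in memberCols) {
          k1 <- sample.int(K, 1L); k2 <- sample.int(K, 1L)
          dos[inLoc, col] <- haps[, k1] + haps[, k2]
        }
        balanced_gr <- c(balanced_gr,
          GRanges(chrom, IRanges(bl$start, bl$end), seqinfo = seqinfo))
      }
    }

    # sweeps: erase variation in target group, sprinkle singleton hets
    sw <- config@sweepSpecs
    sw <- sw[sw$chrom == chrom, , drop = FALSE]
    for (k in seq_len(nrow(sw))) {
      inSw <- which(pos >= sw$start[k] & pos <= sw$end[k])
      cols <- which(meta$group == sw$group[k])
      p <- pGroup[[sw$group[k]]]
      swept <- inSw[stats::runif(length(inSw)) < sw$intensity[k]]
      for (s in swept) {
        major <- if (p[s] >= 0.5) 2L else 0L
        dos[s, cols] <- major
        if (stats::runif(1) < 0.15)
          dos[s, sample(cols, 1L)] <- 1L
      }
    }

    siteList[[chrom]] <- pos
    dosList[[chrom]] <- dos
  }

  dosage <- do.call(rbind, dosList)
  allPos <- unlist(siteList, use.names = FALSE)
  allChrom <- rep(chroms, vapply(siteList, length, 0L))
  nTot <- length(allPos)
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, nTot, replace = TRUE)]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  sites <- GRanges(allChrom, IRanges(allPos, width = 1L), ref = ref,
                   alt = unname(alt), seqinfo = seqinfo)

  # IBD segments: overwrite sample_b with sample_a
  ib <- config@ibdSpecs
  ibd_gr <- GRanges(seqinfo = seqinfo)
  for (k in seq_len(nrow(ib))) {
    if (!all(c(ib$sample_a[k], ib$sample_b[k]) %in% meta$sample_id))
      stop("IBD spec names unknown sample: ",
           ib$sample_a[k], " / ", ib$sample_b[k])
    idx <- which(allChrom == ib$chrom[k] &
                 allPos >= ib$start[k] & allPos <= ib$end[k])
    dosage[idx, ib$sample_b[k]] <- dosage[idx, ib$sample_a[k]]
    seg <- GRanges(ib$chrom[k], IRanges(ib$start[k], ib$end[k]),
                   seqinfo = seqinfo)
    seg$sample_a <- ib$sample_a[k]; seg$sample_b <- ib$sample_b[k]
    ibd_gr <- c(ibd_gr, seg)
  }

  # admixed accession: exact-proportion block mosaic of the two donor pools
  admix_gr <- GRanges(seqinfo = seqinfo)
  if (length(adm)) {
    blockLen <- adm$block_length_bp
    bChrom <- character(); bStart <- integer(); bEnd <- integer()
    for (chrom in chroms) {
      offset <- sample.int(blockLen, 1L) - 1L
      starts <- unique(c(1L, seq(offset + 1L, L, by = blockLen)))
      starts <- starts[starts <= L]
      ends <- c(starts[-1] - 1L, L)
      bChrom <- c(bChrom, rep(chrom, length(starts)))
      bStart <- c(bStart, starts); bEnd <- c(bEnd, ends)
    }
    # donor pools allocated genome-wide so the realized mosaic proportion
    # tracks proportion_a up to one block
    nb <- length(bStart)
    nA <- round(adm$proportion_a * nb)
    donorGroup <- rep(adm$donor_b, nb)
    donorGroup[sample.int(nb, nA)] <- adm$donor_a
    for (b in seq_len(nb)) {
      donor <- sample(meta$sample_id[meta$group == donorGroup[b]], 1L)
      idx <- which(allChrom == bChrom[b] &
                   allPos >= bStart[b] & allPos <= bEnd[b])
      dosage[idx, adm$sample_id] <- dosage[idx, donor]
    }
    admix_gr <- GRanges(bChrom, IRanges(bStart, bEnd), seqinfo = seqinfo)
    admix_gr$donor <- donorGroup
    admix_gr$sample_id <- adm$sample_id
  }

  # uniform dropout, applied last so copied segments stay identical where
  # both copies are called
  if (config@missingRate > 0)
    dosage[stats::runif(length(dosage)) < config@missingRate] <- NA_integer_

  sw <- config@sweepSpecs
  sweep_gr <- GRanges(seqinfo = seqinfo)
  if (nrow(sw)) {
    sweep_gr <- GRanges(sw$chrom, IRanges(sw$start, sw$end),
                        seqinfo = seqinfo)
    sweep_gr$target_group <- sw$group
  }

  truth <- new("TruthSet", sweeps = sweep_gr, ibd = ibd_gr,
               admixture = admix_gr, balanced = balanced_gr)
  list(cohort = GenotypeCohort(dosage, sites, meta), truth = truth)
}
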