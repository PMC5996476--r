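# Shared fixtures, built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the default synthetic study cohort plus its non-overlapping-grid scans
defaultStudy <- function() {
  cached("defaultStudy", {
    sim <- simulateCohort(defaultCohortConfig(seed = 1))
    co <- sim$cohort
    spec <- windowSpec(10000L, 10000L)
    fst <- windowFst(co, "cultivated_Asian", "wild_Asian", spec)
    divCul <- windowDiversity(co, "cultivated_Asian", spec)
    divWild <- windowDiversity(co, "wild_Asian", spec)
    list(cohort = co, truth = sim$truth, fst = fst,
         divCul = divCul, divWild = divWild,
         rod = windowRod(divCul, divWild))
  })
}

# two full pipeline runs with the same seed, for determinism checks
pipelineRuns <- function() {
  cached("pipelineRuns", {
    d1 <- file.path(tempdir(), "pgs_run1")
    d2 <- file.path(tempdir(), "pgs_run2")
    unlink(c(d1, d2), recursive = TRUE)
    r1 <- runPipeline(defaultRunConfig(seed = 1L), d1)
    r2 <- runPipeline(defaultRunConfig(seed = 1L), d2)
    list(dir1 = d1, dir2 = d2, res1 = r1, res2 = r2)
  })
}

# build a small cohort directly from a dosage matrix
makeCohort <- function(dosage, pos = NULL, chromLen = NULL,
                       groups = NULL, chrom = "chr1") {
  n <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(nrow(dosage)) * 100L
  if (is.null(chromLen)) chromLen <- max(pos) + 100L
  if (is.null(groups)) groups <- rep("wild_Asian", n)
  region <- ifelse(grepl("European", groups), "European", "Asian")
  status <- ifelse(grepl("wild", groups), "wild", "cultivated")
  meta <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    region = region, status = status,
    species = "toy", group = groups)
  sites <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos, width = 1L), ref = "A", alt = "C",
    seqinfo = GenomeInfoDb::Seqinfo(chrom, chromLen))
  GenotypeCohort(dosage, sites, meta)
}

# brute-force mean pairwise difference count over all chromosome (allele)
# pairs, pairwise deletion -- the independent oracle for theta-pi counts
bruteThetaPiCount <- function(dosage) {
  total <- 0
  for (s in seq_len(nrow(dosage))) {
    g <- dosage[s, ]
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    alleles <- unlist(lapply(g, function(x) c(rep(1L, x), rep(0L, 2 - x))))
    C <- length(alleles)
    if (C < 2) next
    diffs <- 0; pairs <- 0
    for (a in seq_len(C - 1)) for (b in (a + 1):C) {
      diffs <- diffs + (alleles[a] != alleles[b])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs * 1  # mean per pair
  }
  total
}

# independently coded Tajima's D for a complete (no-missing) dosage matrix
oracleTajimaD <- function(dosage) {
  n <- 2L * ncol(dosage)
  cc <- rowSums(dosage)
  seg <- cc > 0 & cc < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi <- sum(2 * cc * (n - cc) / (n * (n - 1)))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force exact HWE p-value from explicit log-factorial probabilities
oracleHweP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    nAAh <- (nA - h) / 2; naah <- (na - h) / 2
    lfactorial(n) - lfactorial(nAAh) - lfactorial(h) - lfactorial(naah) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# grid-search maximizer of the unphased two-locus multinomial likelihood
# over pAB (margins fixed by the observed allele counts)
oracleGridR2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  cnt <- tabulate(g1 * 3L + g2 + 1L, nbins = 9L)  # index g1*3+g2+1
  pA <- sum(g1) / (2 * n); pB <- sum(g2) / (2 * n)
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  ll <- function(pAB) {  # vectorized over pAB
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    cls <- cbind(pab^2, 2 * pab * paB, paB^2,
                 2 * pab * pAb, 2 * pAB * pab + 2 * pAb * paB,
                 2 * paB * pAB, pAb^2, 2 * pAb * pAB, pAB^2)
    as.vector(log(pmax(cls, 1e-300)) %*% cnt)
  }
  grid <- seq(lo, hi, length.out = 2001)
  best <- grid[which.max(ll(grid))]
  step <- if (hi > lo) grid[2] - grid[1] else 0
  fine <- seq(max(lo, best - step), min(hi, best + step),
              length.out = 2001)
  pAB <- fine[which.max(ll(fine))]
  D <- pAB - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(NA_real_)
  D^2 / den
}
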