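test_that("quantile thresholds count order statistics with tie inclusion", {
  expect_equal(quantileThreshold(1:100, 0.05, "top"), 96)
  expect_equal(sum(1:100 >= quantileThreshold(1:100, 0.05, "top")), 5)
  expect_equal(quantileThreshold(1:10, 0.10, "bottom"), 1)
  # constant vector: everything ties at the threshold
  expect_true(all(rep(3, 10) >= quantileThreshold(rep(3, 10), 0.05, "top")))
  expect_equal(quantileThreshold(c(NA, 5, 1), 0.5, "bottom"), 1)
  expect_error(quantileThreshold(c(NA_real_, NA_real_), 0.1, "top"),
               "missing")
})

gridWindows <- function(vals) {
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1L, by = 10000L, length.out = length(vals)),
                     width = 10000L))
  gr
}

scanInputs <- function(fst, rod, tajd, pi = NULL) {
  f <- gridWindows(fst); S4Vectors::mcols(f)$fst <- fst
  r <- gridWindows(rod); S4Vectors::mcols(r)$rod <- rod
  t <- gridWindows(tajd); S4Vectors::mcols(t)$tajima_d <- tajd
  out <- list(fst = f, rod = r, tajd = t)
  if (!is.null(pi)) {
    p <- gridWindows(pi); S4Vectors::mcols(p)$theta_pi <- pi
    out$pi <- p
  }
  out
}

test_that("the sweep rule is conjunctive and merges adjacent windows", {
  n <- 100
  fst <- seq(0.01, 0.2, length.out = n)
  rod <- seq(0.05, 0.3, length.out = n)
  tajd <- seq(-1, 1, length.out = n)
  # windows 10-12 qualify on all three criteria; window 30 on two only
  fst[10:12] <- 0.9; rod[10:12] <- 0.8; tajd[10:12] <- -2.5
  fst[30] <- 0.95; rod[30] <- 0.8            # D stays near the median
  inp <- scanInputs(fst, rod, tajd)
  reg <- callSelectiveSweeps(inp$fst, inp$rod, inp$tajd,
                             sweepCriteria(0.05, 0.5, 0.10))
  expect_equal(length(reg), 1L)
  expect_equal(GenomicRanges::start(reg), 90001L)
  expect_equal(GenomicRanges::end(reg), 120000L)
  expect_equal(reg$n_windows, 3L)
  # nothing qualifies when thresholds cannot be met jointly
  inp2 <- scanInputs(seq(0.01, 0.2, length.out = n),
                     seq(0.05, 0.3, length.out = n),
                     seq(-1, 1, length.out = n))
  expect_equal(length(callSelectiveSweeps(inp2$fst, inp2$rod, inp2$tajd)), 0L)
})

test_that("windows with any missing statistic never qualify", {
  n <- 50
  fst <- rep(0.1, n); rod <- rep(0.9, n); tajd <- rep(-3, n)
  fst[25] <- NA
  inp <- scanInputs(fst, rod, tajd)
  reg <- callSelectiveSweeps(inp$fst, inp$rod, inp$tajd,
                             sweepCriteria(0.5, 0.5, 0.9))
  hit25 <- IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(240001L, 250000L)), reg)
  expect_false(hit25)
})

test_that("tightening any quantile never adds called windows", {
  study <- defaultStudy()
  loose <- callSelectiveSweeps(study$fst, study$rod, study$divCul,
                               sweepCriteria(0.05, 0.5, 0.10))
  tight <- callSelectiveSweeps(study$fst, study$rod, study$divCul,
                               sweepCriteria(0.02, 0.5, 0.05))
  looseW <- sum(loose$n_windows); tightW <- sum(tight$n_windows)
  expect_lte(tightW, looseW)
  # every tight window is also a loose window
  expect_true(all(IRanges::overlapsAny(tight, loose)))
})

test_that("region totals equal the sum of member windows on the grid", {
  study <- defaultStudy()
  reg <- callSelectiveSweeps(study$fst, study$rod, study$divCul)
  expect_true(all(GenomicRanges::width(reg) == reg$n_windows * 10000L))
  expect_true(all(GenomicRanges::start(reg) < GenomicRanges::end(reg)))
  # merging merged regions is a no-op
  expect_identical(
    GenomicRanges::reduce(GenomicRanges::granges(reg), min.gapwidth = 1L),
    GenomicRanges::granges(reg))
})

test_that("balancing calls are conjunctive and respect missing values", {
  n <- 100
  fst <- seq(0.1, 0.3, length.out = n)
  tajd <- seq(-1, 1, length.out = n)
  pi <- seq(5e-4, 2e-3, length.out = n)
  fst[40:42] <- 0.001; tajd[40:42] <- 2.5; pi[40:42] <- 5e-3
  inp <- scanInputs(fst, rod = fst, tajd, pi)
  reg <- callBalancingRegions(inp$fst, inp$tajd, inp$pi)
  expect_equal(length(reg), 1L)
  expect_equal(GenomicRanges::start(reg), 390001L)
  # high D and pi but missing theta-pi in one window disqualifies it
  pi[41] <- NA
  inp <- scanInputs(fst, rod = fst, tajd, pi)
  reg <- callBalancingRegions(inp$fst, inp$tajd, inp$pi)
  expect_equal(sum(reg$n_windows), 2L)
})

test_that("a neutral grid yields at most the strictest quantile fraction", {
  set.seed(33)
  n <- 1000
  fst <- rnorm(n, 0.05, 0.02); tajd <- rnorm(n); pi <- runif(n, 1e-4, 2e-3)
  inp <- scanInputs(fst, rod = fst, tajd, pi)
  reg <- callBalancingRegions(inp$fst, inp$tajd, inp$pi)
  expect_lte(sum(reg$n_windows), ceiling(0.05 * n))
})

test_that("gene annotation uses half-open overlap with per-region dedup", {
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10001L, 50001L), c(20000L, 60000L)))
  gffPath <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t12000\t13000\t.\t+\t.\tID=inside",
    "chr1\ttoy\tgene\t20001\t21000\t.\t+\t.\tID=abutting",
    "chr1\ttoy\tgene\t19500\t22000\t.\t+\t.\tID=spanning",
    "chr1\ttoy\tgene\t55000\t56000\t.\t+\t.\tID=second"), gffPath)
  ann <- annotateRegions(regions, readGff3(gffPath))
  expect_setequal(ann$gene_ids[[1]], c("inside", "spanning"))
  expect_setequal(ann$gene_ids[[2]], "second")
})

test_that("known intersections are annotated exactly", {
  set.seed(9)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000L, by = 5000L, length.out = 10), width = 2000L))
  genes$type <- "gene"; genes$ID <- sprintf("g%02d", 1:10)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(500L, 12000L, 30500L), c(3500L, 18000L, 47000L)))
  ann <- annotateRegions(regions, genes)
  expected <- lapply(seq_along(regions), function(i) {
    hits <- character()
    for (g in seq_along(genes))
      if (GenomicRanges::start(genes)[g] <= GenomicRanges::end(regions)[i] &&
          GenomicRanges::end(genes)[g] >= GenomicRanges::start(regions)[i])
        hits <- c(hits, genes$ID[g])
    hits
  })
  for (i in seq_along(regions))
    expect_setequal(ann$gene_ids[[i]], expected[[i]])
})
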