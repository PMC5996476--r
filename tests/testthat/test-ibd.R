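test_that("dosage p-distance similarity matches forced arithmetic", {
  expect_equal(pairSimilarity(c(0L, 1L, 2L), c(0L, 1L, 2L)), 1)
  expect_equal(pairSimilarity(c(0L, 2L, 1L), c(2L, 2L, 1L)), 2 / 3)
  expect_true(is.na(pairSimilarity(c(NA, NA), c(1L, 2L))))
  # allele-mismatch-counting oracle on random vectors
  set.seed(44)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    gi <- sample(c(0:2, NA), n, replace = TRUE)
    gj <- sample(c(0:2, NA), n, replace = TRUE)
    ok <- !is.na(gi) & !is.na(gj)
    if (!any(ok)) next
    # minimum allele mismatches between unordered genotype pairs, per site
    mism <- abs(gi[ok] - gj[ok])      # 0/1/2 allele differences
    expect_equal(pairSimilarity(gi, gj), 1 - mean(mism / 2),
                 tolerance = 1e-12)
  }
})

test_that("windows need more than minSnps co-called SNPs to be evaluable", {
  # 8 co-called SNPs in the only window: below the >10 rule
  d <- matrix(0L, 8, 2)
  co <- makeCohort(d, pos = seq(100L, 800L, by = 100L), chromLen = 10000L)
  prof <- pairIbdProfile(co, "s01", "s02")
  expect_false(any(prof@windows$evaluable))
  expect_true(is.na(prof@pij))
  # similarity exactly at the cutoff is not IBD (strict)
  d2 <- matrix(0L, 20, 2)
  d2[1:2, 2] <- 1L                    # 2 of 20 sites at distance 1/2
  co2 <- makeCohort(d2, pos = seq(100L, 2000L, by = 100L),
                    chromLen = 10000L)
  prof2 <- pairIbdProfile(co2, "s01", "s02")
  expect_equal(prof2@windows$similarity[1], 0.95)
  expect_false(prof2@windows$ibd_flag[1])
})

test_that("a planted IBD segment is recovered to the window", {
  study <- defaultStudy()
  prof <- pairIbdProfile(study$cohort, "wA01", "wA02")
  w <- prof@windows
  truthWin <- IRanges::overlapsAny(w, plantedIbd(study$truth),
                                   minoverlap = 5000L)
  flagged <- which(w$ibd_flag)
  planted <- which(truthWin)
  # all flagged windows are the planted ones, up to the two boundaries
  expect_true(all(abs(vapply(flagged, function(i)
    min(abs(i - planted)), 0L)) <= 1))
  expect_gte(sum(w$ibd_flag[truthWin]), 0.8 * sum(truthWin))
})

test_that("P_ij is symmetric and AverIBD averages exactly", {
  study <- defaultStudy()
  ids <- c("wA01", "wA02", "wA03", "wE01", "wE02")
  P <- ibdMatrix(study$cohort, ids)
  expect_equal(P, t(P))
  # single pair
  one <- averIbd(P, "wA01", "wA02")
  expect_equal(one$aver_ibd, P["wA01", "wA02"])
  expect_equal(one$k, 1L)
  # group x reference mean over all six cross pairs
  gs <- c("wA01", "wA02"); rs <- c("wA03", "wE01", "wE02")
  got <- averIbd(P, gs, rs)
  expect_equal(got$aver_ibd, mean(P[gs, rs]))
  expect_equal(got$k, 6L)
  # overlap excludes self-pairs
  got2 <- averIbd(P, gs, c(gs, "wA03"))
  vals <- c(P["wA01", "wA02"], P["wA01", "wA03"],
            P["wA02", "wA01"], P["wA02", "wA03"])
  expect_equal(got2$aver_ibd, mean(vals))
  expect_error(averIbd(P, "wA01", "wA01"), "no usable pairs")
})

test_that("within-group sharing exceeds cross-region sharing", {
  study <- defaultStudy()
  ids <- samplesInGroup(study$cohort, c("wild_Asian", "wild_European"))
  P <- ibdMatrix(study$cohort, ids)
  wa <- samplesInGroup(study$cohort, "wild_Asian")
  we <- samplesInGroup(study$cohort, "wild_European")
  within <- averIbd(P, wa, wa)$aver_ibd
  across <- averIbd(P, wa, we)$aver_ibd
  expect_gte(within, across)
})

test_that("painting a cloned target assigns every evaluable window", {
  study <- defaultStudy()
  co <- study$cohort
  # clone one cultivated Asian donor into the admixed slot
  d <- dosages(co)
  d[, "adm01"] <- d[, "cA05"]
  clone <- GenotypeCohort(d, siteRanges(co),
                          as.data.frame(sampleInfo(co)))
  p <- paintAncestry(clone, "adm01", "cultivated_Asian",
                     "cultivated_European")
  expect_gte(p$proportions[["cultivated_Asian"]], 99)
})

test_that("the admixture mosaic is recovered within five points", {
  study <- defaultStudy()
  p <- paintAncestry(study$cohort, "adm01", "cultivated_Asian",
                     "cultivated_European")
  blocks <- admixtureBlocks(study$truth)
  truthA <- 100 * sum(GenomicRanges::width(
    blocks[blocks$donor == "cultivated_Asian"])) /
    sum(GenomicRanges::width(blocks))
  expect_lt(abs(p$proportions[["cultivated_Asian"]] - truthA), 5)
  expect_lt(abs(p$proportions[["cultivated_Asian"]] - 60), 5)
  expect_lt(p$proportions[["unassigned"]], 10)
})

test_that("a target unrelated to both donor pools stays unassigned", {
  study <- defaultStudy()
  p <- paintAncestry(study$cohort, "wE01", "cultivated_Asian",
                     "wild_Asian")
  expect_gte(p$proportions[["unassigned"]], 90)
})

test_that("painting rejects a target inside a donor group", {
  study <- defaultStudy()
  expect_error(paintAncestry(study$cohort, "cA01", "cultivated_Asian",
                             "cultivated_European"), "donor group")
})
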