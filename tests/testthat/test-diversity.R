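test_that("single-site worked examples give the textbook values", {
  # one site, 4 called allele copies, 2 alt: per-site pi = 2/3
  d <- matrix(c(1L, 1L, NA_integer_), 1, 3)
  co <- makeCohort(d, pos = 500L, chromLen = 10000L)
  div <- windowDiversity(co, "wild_Asian", windowSpec(10000L, 10000L))
  expect_equal(div$theta_pi_count, 2 / 3, tolerance = 1e-12)
  expect_equal(div$theta_pi, (2 / 3) / 10000, tolerance = 1e-12)

  # S = 3 with n_chrom = 4: theta_w = 3 / (1 + 1/2 + 1/3) / 10000
  d <- rbind(c(0L, 1L), c(1L, 0L), c(0L, 1L))
  co <- makeCohort(d, pos = c(100L, 200L, 300L), chromLen = 10000L)
  div <- windowDiversity(co, "wild_Asian", windowSpec(10000L, 10000L))
  expect_equal(div$theta_w, 3 / (1 + 1 / 2 + 1 / 3) / 10000,
               tolerance = 1e-12)
})

test_that("a window without variation has zero estimates and no D", {
  d <- matrix(2L, 5, 4)
  co <- makeCohort(d)
  div <- windowDiversity(co, "wild_Asian", windowSpec(10000L, 10000L))
  expect_equal(div$theta_pi[1], 0)
  expect_equal(div$theta_w[1], 0)
  expect_true(is.na(div$tajima_d[1]))
})

test_that("an excess of singletons makes Tajima's D negative", {
  d <- matrix(0L, 5, 5)
  diag(d) <- 1L                        # five singleton hets, 10 chromosomes
  co <- makeCohort(d)
  div <- windowDiversity(co, "wild_Asian", windowSpec(10000L, 10000L))
  expect_lt(div$tajima_d[1], 0)
})

test_that("theta-pi counts equal the brute-force pairwise oracle", {
  set.seed(101)
  for (rep in 1:25) {
    ns <- sample(2:12, 1); nsites <- sample(5:50, 1)
    d <- matrix(sample(c(0L, 1L, 2L, NA), ns * nsites, replace = TRUE,
                       prob = c(0.4, 0.2, 0.3, 0.1)), nsites, ns)
    co <- makeCohort(d, chromLen = 100000L)
    div <- windowDiversity(co, "wild_Asian", windowSpec(100000L, 100000L))
    expect_equal(div$theta_pi_count[1], bruteThetaPiCount(d),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches an independently coded implementation", {
  set.seed(202)
  for (rep in 1:20) {
    ns <- sample(3:10, 1); nsites <- sample(10:50, 1)
    d <- matrix(rbinom(ns * nsites, 2L, runif(nsites)), nsites, ns)
    co <- makeCohort(d, chromLen = 100000L)
    div <- windowDiversity(co, "wild_Asian", windowSpec(100000L, 100000L))
    expect_equal(div$tajima_d[1], oracleTajimaD(d), tolerance = 1e-10)
  }
})

test_that("D is zero exactly when pi-count equals S/a1", {
  # two samples, one site with both hets: pi = 2*2*2/(4*3) = 2/3... choose
  # a case algebraically: n = 4 chromosomes, one singleton site gives
  # pi = 1/2 and S/a1 = 1/(1 + 1/2 + 1/3); engineered equality instead:
  k <- tajimaConstants(4)
  d <- rbind(c(0L, 1L))                # S = 1, pi = 2*1*3/(4*3) = 1/2
  co <- makeCohort(d)
  div <- windowDiversity(co, "wild_Asian", windowSpec(10000L, 10000L))
  expect_equal(div$tajima_d[1],
               (1 / 2 - 1 / k$a1) / sqrt(k$e1 + 0), tolerance = 1e-12)
})

test_that("Hudson F_ST hits its fixed points and the worked value", {
  expect_equal(hudsonFst(0.5, 0.5, 10, 10), -0.111111, tolerance = 1e-4)
  expect_equal(hudsonFst(0, 1, 10, 10), 1)
  # window form: fixed difference at every site
  d <- cbind(matrix(0L, 5, 4), matrix(2L, 5, 4))
  co <- makeCohort(d, groups = rep(c("wild_Asian", "wild_European"), each = 4))
  fst <- windowFst(co, "wild_Asian", "wild_European",
                   windowSpec(10000L, 10000L))
  expect_equal(fst$fst[1], 1)
})

test_that("F_ST under label permutation averages to zero", {
  set.seed(7)
  nsites <- 300
  d <- matrix(rbinom(nsites * 12, 2L, runif(nsites, 0.2, 0.8)), nsites, 12)
  vals <- replicate(300, {
    grp <- sample(rep(c("wild_Asian", "wild_European"), each = 6))
    co <- makeCohort(d, chromLen = 100000L, groups = grp)
    windowFst(co, "wild_Asian", "wild_European",
              windowSpec(100000L, 100000L))$fst[1]
  })
  expect_lt(abs(mean(vals)), 0.005)
})

test_that("ROD identities and the Table-1-scale worked value hold", {
  mk <- function(piC, piW) {
    div <- function(v) {
      gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(theta_pi = v)
      gr
    }
    windowRod(div(piC), div(piW))$rod
  }
  expect_equal(mk(5.21e-3, 5.21e-3), 0)
  expect_equal(mk(0, 5.21e-3), 1)
  expect_equal(mk(4.76e-3, 5.21e-3), 0.0864, tolerance = 5e-3)
  expect_true(is.na(mk(1e-3, 0)))
})

test_that("mismatched window grids are rejected", {
  study <- defaultStudy()
  expect_error(windowRod(study$divCul[-1], study$divWild), "grids")
})

test_that("feature classes partition sites with CDS precedence", {
  gffPath <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t1001\t2000\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\ttoy\texon\t1001\t1400\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\ttoy\texon\t1601\t2000\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\ttoy\tfive_prime_UTR\t1001\t1100\t.\t+\t.\tID=u1;Parent=m1",
    "chr1\ttoy\tCDS\t1101\t1400\t.\t+\t0\tID=c1;Parent=m1",
    "chr1\ttoy\tCDS\t1601\t1900\t.\t+\t0\tID=c2;Parent=m1",
    "chr1\ttoy\tthree_prime_UTR\t1901\t2000\t.\t+\t.\tID=u2;Parent=m1"),
    gffPath)
  gff <- readGff3(gffPath)
  # sites: CDS (1200), UTR (1050), intron (1500), intergenic (5000)
  d <- matrix(rep(c(0L, 1L), 8), 4, 4)
  co <- makeCohort(d, pos = c(1050L, 1200L, 1500L, 5000L),
                   chromLen = 10000L)
  tab <- diversityByFeature(co, "wild_Asian", gff)
  expect_equal(tab$n_sites[match(c("CDS", "UTR", "intron", "intergenic"),
                                 tab$class)], c(1L, 1L, 1L, 1L))
  expect_error(diversityByFeature(co, "wild_Asian", gff, classes = "promoter"),
               "unknown")
  # a denser variant load in CDS than intergenic orders theta-w
  expect_gt(tab$theta_w[tab$class == "CDS"],
            tab$theta_w[tab$class == "intergenic"])
})

test_that("the d/(2T) rate estimator behaves like the closed form", {
  expect_equal(evolutionRate(0, 1e6)$rate, 0)
  expect_equal(evolutionRate(0.172, 4.5e7)$rate, 1.911e-9, tolerance = 1e-3)
  expect_equal(evolutionRate(0.1, 2e6)$rate,
               evolutionRate(0.1, 1e6)$rate / 2)
  expect_error(evolutionRate(0.1, 0), "positive")
})
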