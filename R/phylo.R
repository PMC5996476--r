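#' Pairwise p-distance matrix from dosages
#'
#' Entry (i, j) is the mean per-site allele-content distance
#' `|g_i - g_j| / 2` over co-called sites (pairwise deletion).
#'
#' @param cohort a [GenotypeCohort-class].
#' @param samples sample ids (default all).
#' @param siteIdx optional site indices (e.g. a bootstrap resample, with
#'   repeats allowed).
#' @param weights optional per-site non-negative weights (an alternative
#'   way to express a bootstrap resample: multiplicities).
#' @return Symmetric matrix with zero diagonal.
#' @export
pDistanceMatrix <- function(cohort, samples = colnames(cohort),
                            siteIdx = NULL, weights = NULL) {
  if (length(samples) < 2) stop("need >= 2 samples")
  d <- dosages(cohort)[, samples, drop = FALSE]
  if (!is.null(siteIdx)) d <- d[siteIdx, , drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(d))
  stopifnot(length(weights) == nrow(d))
  pDistFromPre(pDistPrecompute(d), weights, samples)
}

# |g_a - g_b| = (g_a - g_b)^2 - 2 * [one sample 0, the other 2], so the
# whole weighted distance matrix reduces to four crossproducts over
# masked dosage matrices (fast enough to drive the SNP bootstrap)
pDistPrecompute <- function(d) {
  K <- (!is.na(d)) * 1
  E <- d; E[is.na(E)] <- 0L
  list(K = K, A = E^2 * K, C = E * K,
       M0 = K * (!is.na(d) & d == 0L), M2 = K * (!is.na(d) & d == 2L))
}

pDistFromPre <- function(pre, weights, samples = colnames(pre$K)) {
  X1 <- crossprod(pre$A * weights, pre$K)
  X2 <- crossprod(pre$M0 * weights, pre$M2)
  sq <- X1 + t(X1) - 2 * crossprod(pre$C * weights, pre$C)
  numer <- sq - 2 * (X2 + t(X2))
  denom <- crossprod(pre$K * weights, pre$K)
  if (any(denom[upper.tri(denom)] == 0)) {
    bad <- which(denom == 0 & upper.tri(denom), arr.ind = TRUE)[1, ]
    stop("no co-called sites for pair ", samples[bad[1]], " / ",
         samples[bad[2]])
  }
  D <- numer / (2 * denom)
  diag(D) <- 0
  dimnames(D) <- list(samples, samples)
  D
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' Standard neighbor joining on a symmetric distance matrix; negative
#' branch lengths (an artefact of noisy distances) are clamped to zero.
#'
#' @param dm symmetric numeric matrix with zero diagonal.
#' @return An unrooted `ape::phylo` tree.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix not symmetric")
  if (nrow(dm) < 3) stop("need >= 3 taxa")
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap neighbor-joining tree with majority-rule merge
#'
#' Each replicate resamples SNP sites with replacement to the original
#' count, rebuilds the p-distance matrix and its NJ tree; the replicate
#' trees are merged by majority rule (bipartitions in at least half the
#' replicates) and each retained bipartition is annotated with its percent
#' support. Branch lengths come from the full-data NJ tree when the merged
#' topology equals it (the usual case); otherwise they are completed by a
#' least-squares fit of the merged topology to the full-data distances.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param samples sample ids (default all).
#' @param nReplicates bootstrap replicates (200 by convention).
#' @param seed RNG seed.
#' @param outgroup optional sample id to root the returned tree on.
#' @return `ape::phylo` with `node.label` percent supports.
#' @export
bootstrapConsensus <- function(cohort, samples = colnames(cohort),
                               nReplicates = 200L, seed = 1L,
                               outgroup = NULL) {
  stopifnot(nReplicates >= 1)
  set.seed(seed)
  nSites <- nrow(cohort)
  pre <- pDistPrecompute(dosages(cohort)[, samples, drop = FALSE])
  full <- njTree(pDistFromPre(pre, rep(1, nSites), samples))
  reps <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    w <- tabulate(sample.int(nSites, nSites, replace = TRUE), nSites)
    reps[[r]] <- njTree(pDistFromPre(pre, w, samples))
  }
  class(reps) <- "multiPhylo"
  cons <- ape::consensus(reps, p = 0.5, check.labels = TRUE)
  if (sameTopology(cons, full)) {
    tree <- full
  } else {
    tree <- phangorn::nnls.tree(
      stats::as.dist(pDistanceMatrix(cohort, samples)),
      ape::unroot(cons), method = "unrooted")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  support <- ape::prop.clades(tree, reps, rooted = FALSE)
  support[is.na(support)] <- nReplicates
  tree$node.label <- round(100 * support / nReplicates, 1)
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  tree
}

sameTopology <- function(a, b) {
  a <- ape::unroot(a); b <- ape::unroot(b)
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  if (a$Nnode != b$Nnode) return(FALSE)
  isTRUE(all.equal(ape::dist.topo(a, b)[1], 0))
}

#' Path-length distances implied by a tree
#'
#' Utility for additivity checks: cophenetic distances between leaves.
#'
#' @param tree an `ape::phylo`.
#' @return Symmetric matrix of patristic distances.
#' @export
treePathDistances <- function(tree) ape::cophenetic.phylo(tree)
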