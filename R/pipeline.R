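#' Default end-to-end study configuration
#'
#' Parameters of the full synthetic study: simulation, site filtering,
#' diversity/differentiation scans, sweep and balancing calls, LD decay,
#' IBD and ancestry painting, bootstrap tree, and QTL enrichment. Any
#' element may be overridden via `modifyList()` semantics in
#' [runPipeline()].
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @return Nested list of stage parameter blocks.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(),                      # defaultCohortConfig overrides
    fixture = list(qtl_overlap_fraction = 1.0, n_background_qtl = 5L),
    filter = list(max_missing = 0.5,
                  groups = c("cultivated_Asian", "wild_Asian",
                             "cultivated_European", "wild_European")),
    diversity = list(window = 10000L, step = 5000L),
    scan = list(cultivated = "cultivated_Asian", wild = "wild_Asian",
                fst_top = 0.05, rod_min = 0.5, tajd_bottom = 0.10,
                bal_fst_bottom = 0.05, bal_tajd_top = 0.05,
                bal_pi_top = 0.10),
    ld = list(group = "cultivated_Asian", max_distance = 200000L,
              min_maf = 0.05, min_geno = 0.6, hwe = 0.01,
              n_anchors = 20L, anchor_width = 20000L),
    ibd = list(samples = "wild"),
    paint = list(target = "adm01",
                 donors = c("cultivated_Asian", "cultivated_European")),
    tree = list(replicates = 200L, max_sites = 20000L),
    enrichment = list(n_permutations = 100000L))
}

stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

grToTsv <- function(gr, path, drop = character()) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   as.data.frame(mcols(gr)))
  df <- df[, setdiff(colnames(df), drop), drop = FALSE]
  writeTsv(df, path)
}

#' Run the full synthetic study end to end
#'
#' Simulate a cohort, emit its file fixture, read the VCF back, filter
#' sites, run the diversity/F_ST/ROD scans, call sweep and balancing
#' regions and annotate their genes, profile LD decay, compute the IBD
#' matrix with group summaries, paint the admixed accession, build the
#' bootstrap NJ tree, and test sweep-QTL enrichment. Every artifact is a
#' plain-text file; a JSON manifest lists stages, parameters and file
#' checksums. Reruns with an existing up-to-date output directory
#' recompute in memory but rewrite only missing artifacts, so deleting one
#' stage's files regenerates exactly those.
#'
#' @param config nested list as from [defaultRunConfig()]; partial lists
#'   are completed with the defaults. A character scalar is treated as the
#'   path of a YAML file holding such a list.
#' @param outDir output directory.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- utils::modifyList(defaultRunConfig(), config)
  validateRunConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  cfgHash <- digestConfig(config)
  prev <- if (file.exists(fp("manifest.json")))
    tryCatch(jsonlite::read_json(fp("manifest.json")), error = function(e) NULL)
  forceAll <- is.null(prev) || !identical(prev$config_hash, cfgHash)
  manifest <- list(package = "popgenscan",
                   version = as.character(utils::packageVersion("popgenscan")),
                   config_hash = cfgHash, seed = config$seed,
                   stages = list())
  emit <- function(stage, params, outputs, writer) {
    missing <- !file.exists(outputs)
    if (forceAll || any(missing)) writer(outputs)
    md5 <- vapply(outputs, function(f) unname(tools::md5sum(f)), "")
    names(md5) <- basename(outputs)
    manifest$stages[[stage]] <<- list(params = params,
                                      outputs = as.list(md5))
  }

  ## simulate + fixture --------------------------------------------------
  simArgs <- utils::modifyList(
    defaultCohortArgs(seed = stageSeed(config$seed, "simulate")),
    config$simulation)
  simCfg <- do.call(cohortConfig, simArgs)
  sim <- simulateCohort(simCfg)
  cohort0 <- sim$cohort; truth <- sim$truth
  fixtureFiles <- c(vcf = fp("cohort.vcf"), metadata = fp("samples.tsv"),
                    truth_sweeps = fp("truth_sweeps.bed"),
                    truth_ibd = fp("truth_ibd.bed"),
                    truth_admixture = fp("truth_admixture.bed"),
                    truth_balanced = fp("truth_balanced.bed"),
                    genes = fp("genes.gff3"), qtl = fp("qtl.bed"))
  emit("simulate", list(seed = stageSeed(config$seed, "simulate"),
                        qtl_overlap = config$fixture$qtl_overlap_fraction),
       fixtureFiles, function(outs)
         emitFixture(cohort0, truth, outDir,
                     config$fixture$qtl_overlap_fraction,
                     config$fixture$n_background_qtl,
                     seed = stageSeed(config$seed, "fixture")))

  ## read back + filter --------------------------------------------------
  cohort <- readCohortVcf(fp("cohort.vcf"), fp("samples.tsv"))
  cohort <- suppressMessages(
    filterVariants(cohort, config$filter$max_missing, config$filter$groups))

  ## diversity scans -----------------------------------------------------
  divSpec <- windowSpec(config$diversity$window, config$diversity$step)
  groups <- setdiff(unique(groupOf(cohort)), "admixed")
  divTabs <- lapply(groups, function(g) windowDiversity(cohort, g, divSpec))
  names(divTabs) <- groups
  emit("diversity", config$diversity, fp("diversity.tsv"), function(outs) {
    all <- do.call(c, unname(divTabs))
    grToTsv(all, outs, drop = "theta_pi_count")
  })

  ## selection scans on the non-overlapping grid -------------------------
  sc <- config$scan
  gridSpec <- windowSpec(config$diversity$window, config$diversity$window)
  fstW <- windowFst(cohort, sc$cultivated, sc$wild, gridSpec)
  divCul <- windowDiversity(cohort, sc$cultivated, gridSpec)
  divWild <- windowDiversity(cohort, sc$wild, gridSpec)
  rodW <- windowRod(divCul, divWild)
  sweeps <- callSelectiveSweeps(fstW, rodW, divCul,
    sweepCriteria(sc$fst_top, sc$rod_min, sc$tajd_bottom))
  balancing <- callBalancingRegions(fstW, divCul, divCul,
    balancingCriteria(sc$bal_fst_bottom, sc$bal_tajd_top, sc$bal_pi_top))
  gff <- readGff3(fp("genes.gff3"))
  sweeps <- annotateRegions(sweeps, gff)
  balancing <- annotateRegions(balancing, gff)
  emit("scan", sc, c(fp("fst_rod.tsv"), fp("sweeps.bed"),
                     fp("balancing.bed"), fp("sweep_genes.tsv")),
       function(outs) {
         grid <- granges(fstW)
         mcols(grid) <- DataFrame(fst = fstW$fst, rod = rodW$rod,
                                  tajima_d_cul = divCul$tajima_d,
                                  theta_pi_cul = divCul$theta_pi)
         grToTsv(grid, outs[1])
         writeBed(withName(sweeps, function(g)
           sprintf("sweep%02d", seq_along(g))), outs[2])
         writeBed(withName(balancing, function(g)
           sprintf("balancing%02d", seq_along(g))), outs[3])
         genes <- data.frame(
           region = rep(sprintf("sweep%02d", seq_along(sweeps)),
                        lengths(sweeps$gene_ids)),
           gene_id = unlist(sweeps$gene_ids, use.names = FALSE))
         writeTsv(genes, outs[4])
       })

  ## LD decay ------------------------------------------------------------
  ld <- config$ld
  ldProf <- ldDecayProfile(cohort, ld$group,
    ldFilterConfig(ld$max_distance, ld$min_maf, ld$min_geno, ld$hwe),
    nAnchors = ld$n_anchors, anchorWidthBp = ld$anchor_width,
    seed = stageSeed(config$seed, "ld"))
  emit("ld", ld, fp("ld_decay.tsv"),
       function(outs) writeTsv(ldProf, outs))

  ## IBD + painting ------------------------------------------------------
  ibdSamples <- if (identical(config$ibd$samples, "wild"))
    colnames(cohort)[sampleInfo(cohort)$status == "wild" &
                       sampleInfo(cohort)$group != "admixed"]
  else config$ibd$samples
  P <- ibdMatrix(cohort, ibdSamples)
  emit("ibd", config$ibd, c(fp("ibd_pij.tsv"), fp("aver_ibd.tsv")),
       function(outs) {
         writeTsv(data.frame(sample_id = rownames(P), P,
                             check.names = FALSE), outs[1])
         grp <- groupOf(cohort)[ibdSamples]
         summ <- do.call(rbind, lapply(unique(grp), function(g)
           averIbd(P, ibdSamples[grp == g], ibdSamples, group = g)))
         writeTsv(summ, outs[2])
       })
  paintRes <- NULL
  if (!is.null(config$paint$target) &&
      config$paint$target %in% colnames(cohort)) {
    paintRes <- paintAncestry(cohort, config$paint$target,
                              config$paint$donors[1], config$paint$donors[2])
    emit("paint", config$paint, fp("painted_blocks.bed"), function(outs) {
      w <- paintRes$windows
      w <- w[!is.na(w$label) & w$label != "unassigned"]
      writeBed(withName(w, function(g) g$label), outs)
    })
  }

  ## bootstrap NJ tree ---------------------------------------------------
  treeSamples <- setdiff(colnames(cohort), "adm01")
  treeCohort <- cohort
  if (nrow(treeCohort) > config$tree$max_sites) {
    stride <- ceiling(nrow(treeCohort) / config$tree$max_sites)
    treeCohort <- treeCohort[seq(1L, nrow(treeCohort), by = stride), ]
  }
  tree <- bootstrapConsensus(treeCohort, treeSamples,
                             nReplicates = config$tree$replicates,
                             seed = stageSeed(config$seed, "tree"))
  emit("tree", config$tree, fp("tree.nwk"),
       function(outs) ape::write.tree(tree, outs))

  ## QTL enrichment ------------------------------------------------------
  sl <- seqlengths(rowRanges(cohort))
  qtl <- readBed(fp("qtl.bed"), sl)
  sweepWindows <- granges(fstW)[!is.na(fstW$fst)]
  ovQ <- findOverlaps(granges(fstW), sweeps)
  sweepWindows <- granges(fstW)[unique(S4Vectors::queryHits(ovQ))]
  enr <- permutationEnrichment(sweepWindows, qtl, sl,
    windowBp = config$diversity$window,
    nPermutations = config$enrichment$n_permutations,
    seed = stageSeed(config$seed, "enrichment"))
  emit("enrichment", config$enrichment, fp("enrichment.json"),
       function(outs)
         jsonlite::write_json(list(observed = enr@observed,
                                   n_permutations = enr@nPermutations,
                                   p_value = enr@pValue, seed = enr@seed),
                              outs, auto_unbox = TRUE, digits = NA))

  manifest$stages <- manifest$stages[order(names(manifest$stages))]
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(manifest = manifest, cohort = cohort, truth = truth,
                 sweeps = sweeps, balancing = balancing,
                 fstWindows = fstW, rodWindows = rodW, divCul = divCul,
                 divWild = divWild, divTabs = divTabs, ldProfile = ldProf,
                 ibdMatrix = P, paint = paintRes, tree = tree,
                 enrichment = enr))
}

validateRunConfig <- function(config) {
  stopifnot(is.numeric(config$seed))
  if (!is.null(config$enrichment) &&
      is.null(config$fixture$qtl_overlap_fraction))
    stop("enrichment enabled but no QTL fixture configured")
  if (config$diversity$step > config$diversity$window)
    stop("diversity step exceeds window")
  invisible(TRUE)
}

digestConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
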