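#' @describeIn GenotypeCohort-class the sites-by-samples dosage matrix
#' @param x a `GenotypeCohort`
#' @export
setMethod("dosages", "GenotypeCohort", function(x) assay(x, "dosage"))

#' @describeIn GenotypeCohort-class accession metadata as a `DataFrame`
#' @export
setMethod("sampleInfo", "GenotypeCohort", function(x) colData(x))

#' @describeIn GenotypeCohort-class site coordinates and alleles as `GRanges`
#' @export
setMethod("siteRanges", "GenotypeCohort", function(x) rowRanges(x))

#' @describeIn GenotypeCohort-class group label per sample (named character)
#' @export
setMethod("groupOf", "GenotypeCohort", function(x) {
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
})

#' @describeIn GenotypeCohort-class sample ids belonging to a group label
#' @param group a group label such as `"cultivated_Asian"`
#' @export
setMethod("samplesInGroup", "GenotypeCohort", function(x, group) {
  ids <- colnames(x)[colData(x)$group %in% group]
  if (!length(ids))
    stop("no samples in group '", paste(group, collapse = ","), "'")
  ids
})

setMethod("show", "GenotypeCohort", function(object) {
  d <- assay(object, "dosage")
  cat(sprintf("GenotypeCohort: %d SNP sites x %d samples (%.1f%% missing)\n",
              nrow(object), ncol(object), 100 * mean(is.na(d))))
  tab <- table(colData(object)$group)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  chroms <- table(as.character(seqnames(rowRanges(object))))
  cat("chromosomes:",
      paste(sprintf("%s (%d sites)", names(chroms), chroms), collapse = ", "),
      "\n")
})

# per-site alternate-allele count and called allele copies within a sample set
siteCounts <- function(dosage) {
  called <- !is.na(dosage)
  list(C = 2L * as.integer(rowSums(called)),
       c = as.integer(rowSums(dosage, na.rm = TRUE)))
}
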