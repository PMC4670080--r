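#' @describeIn ChromosomeSet-class genetic lengths in cM
#' @param x object
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @describeIn ChromosomeSet-class chromosome names
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @describeIn ChromosomeSet-class total genetic length (cM)
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

setMethod("chromLengths", "ChromosomeSet", function(x) x@lengths)
setMethod("chromNames", "ChromosomeSet", function(x) names(x@lengths))
setMethod("genomeLength", "ChromosomeSet", function(x) sum(x@lengths))
setMethod("length", "ChromosomeSet", function(x) length(x@lengths))

setMethod("show", "ChromosomeSet", function(object) {
  cat("ChromosomeSet:", length(object@lengths), "chromosomes,",
      format(sum(object@lengths)), "cM total\n")
})

#' @describeIn MigrationSchedule-class the migration matrix (generations x sources)
#' @param x object
#' @export
setGeneric("migrationMatrix", function(x) standardGeneric("migrationMatrix"))

#' @describeIn MigrationSchedule-class number of generations (founding time)
#' @export
setGeneric("nGenerations", function(x) standardGeneric("nGenerations"))

#' @describeIn MigrationSchedule-class source population labels
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

setMethod("migrationMatrix", "MigrationSchedule", function(x) x@m)
setMethod("nGenerations", "MigrationSchedule", function(x) nrow(x@m))
setMethod("populations", "MigrationSchedule", function(x) colnames(x@m))

setMethod("show", "MigrationSchedule", function(object) {
  m <- object@m
  cat("MigrationSchedule:", nrow(m), "generations, sources",
      paste(colnames(m), collapse = "/"), "\n")
  ev <- which(rowSums(m) > 0)
  for (t in rev(ev))
    cat(sprintf("  gen %2d: %s\n", t,
                paste(sprintf("%s=%.4g", colnames(m)[m[t, ] > 0], m[t, m[t, ] > 0]),
                      collapse = ", ")))
  pr <- scheduleProportions(object)
  cat("  implied proportions:",
      paste(sprintf("%s=%.3f", names(pr), pr), collapse = ", "), "\n")
})

#' @describeIn SimulatedCohort-class true ancestry tracts (data.frame)
#' @param x object
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))

#' @describeIn SimulatedCohort-class phased 0/1 allele matrix or NULL
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @describeIn SimulatedCohort-class number of diploid individuals
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @describeIn SimulatedCohort-class individual-to-haplotype pairing
#' @export
setGeneric("haplotypePairs", function(x) standardGeneric("haplotypePairs"))

setMethod("tracts", "SimulatedCohort", function(x) x@tracts)
setMethod("alleles", "SimulatedCohort", function(x) x@alleles)
setMethod("nIndividuals", "SimulatedCohort", function(x) max(x@tracts$hap) %/% 2L)
setMethod("haplotypePairs", "SimulatedCohort", function(x) {
  n <- nIndividuals(x)
  data.frame(individual = seq_len(n), hapA = 2L * seq_len(n) - 1L,
             hapB = 2L * seq_len(n))
})

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort:", nIndividuals(object), "individuals,",
      length(object@chroms), "chromosomes,", nrow(object@tracts), "tracts",
      if (!is.null(object@alleles)) sprintf(", %d painted loci", ncol(object@alleles)) else "",
      "\n")
})

#' @describeIn TractSpectrum-class bin edges in cM
#' @param x object
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @describeIn TractSpectrum-class ancestry x bin count matrix
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @describeIn TractSpectrum-class whole-chromosome tract counts
#' @export
setGeneric("fullChromCounts", function(x) standardGeneric("fullChromCounts"))

setMethod("binEdges", "TractSpectrum", function(x) x@edges)
setMethod("spectrumCounts", "TractSpectrum", function(x) x@counts)
setMethod("fullChromCounts", "TractSpectrum", function(x) x@full)

setMethod("show", "TractSpectrum", function(object) {
  cat(sprintf("TractSpectrum (%s): %d ancestries x %d bins, %s haplotypes\n",
              object@type, nrow(object@counts), ncol(object@counts),
              format(object@nHaplotypes)))
  tot <- rowSums(object@counts) + rowSums(object@full)
  cat("  tracts per ancestry:",
      paste(sprintf("%s=%.5g", rownames(object@counts), tot), collapse = ", "), "\n")
})

#' @describeIn TractModelFit-class fitted parameter vector
#' @param x object
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))

setMethod("fittedParams", "TractModelFit", function(x) x@params)

#' Log-likelihood of a fitted tract model
#' @param object a [TractModelFit-class]
#' @param ... unused
#' @export
setMethod("logLik", "TractModelFit", function(object, ...) {
  val <- object@logLik
  attr(val, "df") <- length(object@params)
  class(val) <- "logLik"
  val
})

#' Bayesian information criterion for a tract-model fit
#'
#' Convenience only: the number of "observations" is taken as the total tract
#' count. Model choice in this package follows the simulation-calibrated
#' likelihood-gain test, not BIC.
#' @param object a [TractModelFit-class]
#' @param ... unused
#' @export
setMethod("BIC", "TractModelFit", function(object, ...) {
  n <- sum(object@expected@counts) + sum(object@expected@full)
  length(object@params) * log(max(n, 1)) - 2 * object@logLik
})

setMethod("show", "TractModelFit", function(object) {
  cat(sprintf("TractModelFit [%s]%s\n", object@model,
              if (object@converged) "" else " (NOT converged)"))
  cat("  params:", paste(sprintf("%s=%.3f", names(object@params), object@params),
                         collapse = ", "), "\n")
  cat(sprintf("  logLik: %.3f (%d starts)\n", object@logLik, object@nStarts))
})

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf("ModelComparison: BASE vs %s\n", object@fitAlt@model))
  cat(sprintf("  observed delta-logLik: %.3f | null sims: %d | p = %.4g | %s\n",
              object@observedDelta, object@nSim, object@pValue,
              if (object@rejected) "BASE rejected" else "BASE retained"))
})

setMethod("show", "MaskedHaplotypes", function(object) {
  mr <- mean(is.na(object@alleles))
  cat(sprintf("MaskedHaplotypes: %d haplotypes x %d loci (%.1f%% missing, %d reference)\n",
              nrow(object@alleles), ncol(object@alleles), 100 * mr,
              sum(object@isReference)))
})

setMethod("show", "ASPCAResult", function(object) {
  cat(sprintf("ASPCAResult: %d haplotypes (%d reference), %d components%s\n",
              nrow(object@scores), sum(object@isReference), ncol(object@scores),
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SharingMatrix", function(object) {
  cat("SharingMatrix over", nrow(object@normalized), "populations (cM per pair)\n")
  print(round(object@normalized, 4))
})
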