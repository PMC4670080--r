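#' @useDynLib admixtract, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats optim rbinom rbeta runif rpois rnorm quantile median lm
#'   coef pchisq wilcox.test cor setNames var approx qnorm
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics points lines legend abline hist text
NULL

#' Chromosome set
#'
#' Ordered set of chromosomes with genetic lengths in centimorgans. Carries the
#' genome size used by both the forward simulator and the analytic tract model.
#'
#' @slot lengths Named numeric vector of genetic lengths (cM), all positive,
#'   names unique.
#' @export
setClass("ChromosomeSet", representation(lengths = "numeric"))

setValidity("ChromosomeSet", function(object) {
  L <- object@lengths
  if (length(L) == 0) return("at least one chromosome required")
  if (any(!is.finite(L)) || any(L <= 0)) return("chromosome lengths must be positive")
  if (is.null(names(L)) || anyDuplicated(names(L)) || any(names(L) == ""))
    return("chromosome names must be present and unique")
  TRUE
})

#' Create a chromosome set
#'
#' @param lengths Numeric vector of genetic lengths in cM. If unnamed,
#'   chromosomes are named \code{chr1, chr2, ...}.
#' @return A [ChromosomeSet-class] object.
#' @examples
#' chroms <- chromosomeSet(rep(150, 10))
#' genomeLength(chroms)
#' @export
chromosomeSet <- function(lengths) {
  if (is.null(names(lengths))) names(lengths) <- paste0("chr", seq_along(lengths))
  new("ChromosomeSet", lengths = lengths)
}

#' Migration schedule
#'
#' Per-generation, per-source replacement fractions: the demographic hypothesis
#' object. Generation 1 is the sampled generation (no migration); the highest
#' generation is the founding event and is fully specified (fractions sum to 1).
#'
#' @slot m Numeric matrix, generations x source populations; \code{m[t, p]} is
#'   the fraction of the admixed population replaced by migrants from source
#'   \code{p} at generation \code{t} before present.
#' @export
setClass("MigrationSchedule", representation(m = "matrix"))

setValidity("MigrationSchedule", function(object) {
  m <- object@m
  if (nrow(m) < 2) return("schedule needs a founding generation >= 2")
  if (is.null(colnames(m))) return("source populations must be named")
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) return("fractions must lie in [0, 1]")
  if (any(abs(m[1, ]) > 1e-12)) return("no migration at generation 1 (the sample)")
  if (abs(sum(m[nrow(m), ]) - 1) > 1e-9)
    return("founding generation fractions must sum to 1")
  rs <- rowSums(m)[-nrow(m)]
  if (any(rs > 1 + 1e-9)) return("per-generation replacement fractions must sum to <= 1")
  TRUE
})

#' Create a migration schedule
#'
#' @param m Generations x populations matrix of replacement fractions (row 1 =
#'   sampled generation, last row = founding).
#' @param populations Optional column names.
#' @return A [MigrationSchedule-class].
#' @examples
#' m <- matrix(0, 12, 3, dimnames = list(NULL, c("EUR", "NAT", "AFR")))
#' m[12, ] <- c(0.65, 0.35, 0) / 1
#' m[6, "AFR"] <- 0.05
#' m[12, ] <- m[12, ] / sum(m[12, ])
#' sched <- migrationSchedule(m)
#' scheduleProportions(sched)
#' @export
migrationSchedule <- function(m, populations = colnames(m)) {
  m <- as.matrix(m)
  if (!is.null(populations)) colnames(m) <- populations
  new("MigrationSchedule", m = m)
}

#' Simulated admixed cohort
#'
#' Output of the forward pedigree simulator: true ancestry tracts for every
#' sampled haplotype, optionally painted with alleles drawn from
#' ancestry-specific frequencies, plus any planted IBD ground truth.
#' Haplotypes are numbered \code{1..2n}; individual \code{i} carries haplotypes
#' \code{2i - 1} and \code{2i}.
#'
#' @slot tracts data.frame with columns \code{hap}, \code{chrom},
#'   \code{start}, \code{end} (cM, 0-based half-open), \code{ancestry},
#'   \code{posterior} (1 for simulator truth).
#' @slot chroms [ChromosomeSet-class].
#' @slot alleles 0/1 matrix (haplotypes x loci) or NULL before painting.
#' @slot loci data.frame with \code{chrom}, \code{cM} per locus, or NULL.
#' @slot schedule the generating [MigrationSchedule-class].
#' @slot seed integer seed used.
#' @slot plantedIBD data.frame of planted segments (\code{hapA}, \code{hapB},
#'   \code{chrom}, \code{start}, \code{end}).
#' @export
setClass("SimulatedCohort",
         representation(tracts = "data.frame", chroms = "ChromosomeSet",
                        alleles = "ANY", loci = "ANY",
                        schedule = "MigrationSchedule", seed = "integer",
                        plantedIBD = "data.frame"))

setValidity("SimulatedCohort", function(object) {
  tr <- object@tracts
  need <- c("hap", "chrom", "start", "end", "ancestry", "posterior")
  if (!all(need %in% names(tr))) return("tracts missing required columns")
  if (any(tr$end <= tr$start)) return("tracts must have end > start")
  TRUE
})

#' Ancestry-specific allele frequencies
#'
#' Loci x source-population allele-frequency matrix under a Balding-Nichols
#' model, with genetic positions for painting simulated haplotypes.
#'
#' @slot freq loci x populations matrix of frequencies in (0, 1).
#' @slot chrom chromosome name per locus.
#' @slot cM genetic position per locus, nondecreasing within chromosome.
#' @slot fst the drift parameter used.
#' @export
setClass("AncestralFrequencies",
         representation(freq = "matrix", chrom = "character", cM = "numeric",
                        fst = "numeric"))

setValidity("AncestralFrequencies", function(object) {
  if (nrow(object@freq) != length(object@cM)) return("loci dimension mismatch")
  if (nrow(object@freq) > 0 && (any(object@freq <= 0) || any(object@freq >= 1)))
    return("frequencies must lie in (0, 1)")
  for (ch in unique(object@chrom)) {
    x <- object@cM[object@chrom == ch]
    if (is.unsorted(x)) return("positions must be nondecreasing within chromosome")
  }
  TRUE
})

#' Local-ancestry calls
#'
#' Per-window local-ancestry calls with posteriors for a set of haplotypes, the
#' RFMix-style input consumed by masking and tract construction.
#'
#' @slot calls data.frame with columns \code{hap}, \code{chrom}, \code{start},
#'   \code{end} (cM, half-open), \code{ancestry}, \code{posterior}.
#' @export
setClass("LocalAncestryCalls", representation(calls = "data.frame"))

setValidity("LocalAncestryCalls", function(object) {
  cl <- object@calls
  need <- c("hap", "chrom", "start", "end", "ancestry", "posterior")
  if (!all(need %in% names(cl))) return("calls missing required columns")
  if (nrow(cl) == 0) return(TRUE)
  if (any(cl$end <= cl$start)) return("windows must have end > start")
  if (any(cl$posterior < 0 | cl$posterior > 1)) return("posteriors must lie in [0, 1]")
  o <- order(cl$hap, cl$chrom, cl$start)
  cl <- cl[o, ]
  same <- cl$hap[-1] == cl$hap[-nrow(cl)] & cl$chrom[-1] == cl$chrom[-nrow(cl)]
  if (any(same & cl$start[-1] < cl$end[-nrow(cl)] - 1e-9))
    return("windows of one haplotype/chromosome must not overlap")
  TRUE
})

#' Cohort filter thresholds
#'
#' The fixed exclusion rules applied before each analysis stage. Comparisons
#' are strict: a unit is excluded when its
#' value falls strictly beyond the threshold.
#'
#' @slot minTargetAncestry haplotypes with less than this fraction of the
#'   target ancestry are excluded from ancestry-specific PCA (default 0.25).
#' @slot minPosterior local-ancestry calls below this posterior are masked
#'   (default 0.95).
#' @slot maxReferenceContamination reference individuals with more than this
#'   European fraction are excluded (default 0.10).
#' @slot maxSingleAncestry individuals above this fraction of any one
#'   continental ancestry are excluded from tract-model fitting (default 0.95).
#' @export
setClass("CohortFilters",
         representation(minTargetAncestry = "numeric", minPosterior = "numeric",
                        maxReferenceContamination = "numeric",
                        maxSingleAncestry = "numeric"),
         prototype(minTargetAncestry = 0.25, minPosterior = 0.95,
                   maxReferenceContamination = 0.10, maxSingleAncestry = 0.95))

setValidity("CohortFilters", function(object) {
  v <- c(object@minTargetAncestry, object@minPosterior,
         object@maxReferenceContamination, object@maxSingleAncestry)
  if (length(v) != 4 || any(v < 0 | v > 1)) return("all thresholds must lie in [0, 1]")
  TRUE
})

#' @rdname CohortFilters-class
#' @param minTargetAncestry,minPosterior,maxReferenceContamination,maxSingleAncestry
#'   thresholds in \code{[0, 1]}; see slots.
#' @return A [CohortFilters-class].
#' @export
cohortFilters <- function(minTargetAncestry = 0.25, minPosterior = 0.95,
                          maxReferenceContamination = 0.10,
                          maxSingleAncestry = 0.95) {
  new("CohortFilters", minTargetAncestry = minTargetAncestry,
      minPosterior = minPosterior,
      maxReferenceContamination = maxReferenceContamination,
      maxSingleAncestry = maxSingleAncestry)
}

#' Tract-length spectrum
#'
#' Binned counts of ancestry tract lengths, the statistic the pulse-model
#' likelihood is computed on. Holds either observed integer counts or expected
#' real-valued counts from the analytic model. Tracts covering a whole
#' chromosome are tallied separately per chromosome; the final length bin is
#' open-ended.
#'
#' @slot counts ancestry x bin matrix (counts of tracts shorter than their
#'   chromosome).
#' @slot full ancestry x chromosome matrix of whole-chromosome tract counts.
#' @slot edges bin edges in cM (length \code{ncol(counts) + 1}, last may be Inf).
#' @slot chroms [ChromosomeSet-class].
#' @slot nHaplotypes number of haplotypes the spectrum was computed over.
#' @slot type "observed" or "expected".
#' @slot lengthMass ancestry x bin matrix of expected total tract length (cM)
#'   per bin, including the whole-chromosome column; NULL for observed spectra.
#' @export
setClass("TractSpectrum",
         representation(counts = "matrix", full = "matrix", edges = "numeric",
                        chroms = "ChromosomeSet", nHaplotypes = "numeric",
                        type = "character", lengthMass = "ANY"))

setValidity("TractSpectrum", function(object) {
  if (length(object@edges) != ncol(object@counts) + 1) return("edges/bins mismatch")
  if (is.unsorted(object@edges, strictly = TRUE)) return("edges must be strictly increasing")
  if (any(object@counts < -1e-9) || any(object@full < -1e-9)) return("counts must be >= 0")
  if (!object@type %in% c("observed", "expected")) return("type must be observed/expected")
  TRUE
})

#' Fitted pulse-migration model
#'
#' @slot model one of "BASE", "EUR_PULSE", "AFR_PULSE".
#' @slot params named fitted parameters: \code{t0} (founding time), \code{t_afr}
#'   (African pulse time) and, for pulse models, \code{t_pulse}, \code{m_pulse}.
#' @slot proportions observed final ancestry proportions used to pin magnitudes.
#' @slot logLik Poisson composite log-likelihood at the optimum.
#' @slot converged logical.
#' @slot nStarts number of optimizer restarts.
#' @slot expected [TractSpectrum-class] at the optimum.
#' @slot startLogLik per-start best log-likelihoods.
#' @export
setClass("TractModelFit",
         representation(model = "character", params = "numeric",
                        proportions = "numeric", logLik = "numeric",
                        converged = "logical", nStarts = "integer",
                        expected = "TractSpectrum", startLogLik = "numeric"))

#' Simulation-calibrated model comparison
#'
#' Result of the likelihood-gain test between the two-parameter base model and
#' a nested pulse model, calibrated by refitting both models to cohorts
#' simulated under the fitted null.
#'
#' @slot fitNull,fitAlt [TractModelFit-class] objects.
#' @slot observedDelta observed log-likelihood gain.
#' @slot simDeltas simulated gains under the null, one per replicate.
#' @slot pValue add-one empirical p-value.
#' @slot rejected TRUE when the observed gain exceeds the empirical 95th
#'   percentile of the simulated gains.
#' @slot nSim number of null simulations.
#' @slot seed master seed.
#' @export
setClass("ModelComparison",
         representation(fitNull = "TractModelFit", fitAlt = "TractModelFit",
                        observedDelta = "numeric", simDeltas = "numeric",
                        pValue = "numeric", rejected = "logical",
                        nSim = "integer", seed = "integer"))

#' Masked haplotype matrix
#'
#' Haplotypes x loci allele matrix with structured missingness from local-
#' ancestry masking; the input to ancestry-specific PCA. Reference haplotypes
#' are fully observed.
#'
#' @slot alleles 0/1/NA matrix, rownames = haplotype ids.
#' @slot chrom,cM locus annotation.
#' @slot labels population label per haplotype.
#' @slot isReference logical per haplotype.
#' @export
setClass("MaskedHaplotypes",
         representation(alleles = "matrix", chrom = "character", cM = "numeric",
                        labels = "character", isReference = "logical"))

setValidity("MaskedHaplotypes", function(object) {
  if (nrow(object@alleles) != length(object@labels)) return("labels/rows mismatch")
  if (length(object@isReference) != nrow(object@alleles)) return("isReference/rows mismatch")
  if (ncol(object@alleles) != length(object@cM)) return("loci dimension mismatch")
  if (any(object@isReference) &&
      anyNA(object@alleles[object@isReference, , drop = FALSE]))
    return("reference haplotypes must be fully observed")
  TRUE
})

#' Ancestry-specific PCA result
#'
#' @slot scores haplotypes x components coordinate matrix; admixed and
#'   reference haplotypes share the same basis.
#' @slot loadings loci x components right singular vectors.
#' @slot varShare variance share per component.
#' @slot labels,isReference per-haplotype annotation.
#' @slot iterations iterations used by the low-rank completion.
#' @slot converged logical.
#' @slot delta final imputed-entry change.
#' @slot exclusions data.frame log of excluded units (unit, rule, value).
#' @export
setClass("ASPCAResult",
         representation(scores = "matrix", loadings = "matrix",
                        varShare = "numeric",
                        labels = "character", isReference = "logical",
                        iterations = "integer", converged = "logical",
                        delta = "numeric", exclusions = "data.frame"))

#' IBD sharing matrix
#'
#' Population x population totals of IBD sharing (cM) normalized by pair
#' counts: off-diagonal cells by n_P * n_Q, diagonal cells by n_P (n_P - 1) / 2.
#'
#' @slot total raw summed segment lengths (cM).
#' @slot normalized pair-count normalized sharing.
#' @slot n haplotype count per population.
#' @slot se chromosome-weighted jackknife standard errors (or NULL).
#' @export
setClass("SharingMatrix",
         representation(total = "matrix", normalized = "matrix", n = "numeric",
                        se = "ANY"))
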