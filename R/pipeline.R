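# Orchestration: configuration, named seed substreams, the full analysis
# pipeline, the X-vs-autosome sex-bias comparison and the A/B run comparison.

#' Read an analysis configuration (YAML)
#'
#' The configuration mirrors the package's function arguments: input paths
#' (tracts/calls/map/labels/reference), ancestry labels, cohort-filter
#' thresholds, tract-model settings (bin count, optimizer restarts),
#' model-selection settings (nSim, alpha), ASPCA settings (k, tol, maxIter),
#' IBD settings (sliceMarkers, maxMismatchPerSlice, minCM), master seed and
#' output directory. Unspecified fields fall back to package defaults
#' (the analysis constants listed in the vignette).
#'
#' @param path YAML file.
#' @return A validated config list (class "admixtractConfig").
#' @export
readAnalysisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    ancestries = c("EUR", "NAT", "AFR"),
    filters = list(minTargetAncestry = 0.25, minPosterior = 0.95,
                   maxReferenceContamination = 0.10, maxSingleAncestry = 0.95),
    tract_model = list(nBins = 50, minLength = 0.2, nStarts = 10),
    model_select = list(nSim = 200, alpha = 0.05),
    aspca = list(k = 2, tol = 1e-6, maxIter = 200),
    ibd = list(sliceMarkers = 128, maxMismatchPerSlice = 2, minCM = 3.0),
    seed = 1L,
    outdir = "admixtract_out")
  cfg <- utils::modifyList(defaults, cfg)
  fl <- unlist(cfg$filters)
  if (any(fl < 0 | fl > 1)) stop("filter thresholds must lie in [0, 1]")
  if (is.null(cfg$seed)) stop("config must set a master seed")
  if (!is.null(cfg$inputs)) {
    for (f in unlist(cfg$inputs))
      if (!file.exists(f)) stop("configured input does not exist: ", f)
  }
  class(cfg) <- c("admixtractConfig", "list")
  cfg
}

#' Serialize a configuration back to YAML
#' @param config Config list.
#' @param path Output file.
#' @export
writeAnalysisConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Deterministic named seed substream
#'
#' Stage seeds are derived from the master seed and the stage name so every
#' stage is independently reproducible and insensitive to execution order.
#'
#' @param seed Master seed.
#' @param name Stage name.
#' @return Integer seed below 2^31.
#' @export
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (31 ^ (seq_len(nchar(name)) %% 8)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Run the full tract / model-selection / ASPCA / IBD analysis
#'
#' Executes the pipeline stages on configured inputs: read tracts (or derive
#' them from local-ancestry calls), compute ancestry proportions and apply the
#' tract-analysis filter, build the tract-length spectrum, fit the base model
#' and run the simulation-calibrated comparison against the configured
#' alternative; optionally run ASPCA (when a reference panel is configured)
#' and IBD detection with ancestry overlay (when phased alleles are
#' configured). Stage failures are recorded and dependent stages skipped.
#' All outputs are written under \code{config$outdir}; the report is
#' idempotent for a fixed config + seed.
#'
#' @param config From [readAnalysisConfig()], or a path to a YAML file.
#' @return A run report (list, class "admixtractReport") with per-stage
#'   outputs, seeds and exclusion logs.
#' @export
runFullAnalysis <- function(config) {
  if (is.character(config)) config <- readAnalysisConfig(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), stages = list(),
                 seed = config$seed)
  filters <- cohortFilters(config$filters$minTargetAncestry,
                           config$filters$minPosterior,
                           config$filters$maxReferenceContamination,
                           config$filters$maxSingleAncestry)
  stage <- function(name, fun) {
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    report$stages[[name]] <<- res
    res
  }

  st_in <- stage("inputs", function() {
    if (is.null(config$inputs$tracts)) stop("config$inputs$tracts is required")
    tr <- readTractsBed(config$inputs$tracts, ancestries = config$ancestries)
    chroms <- if (!is.null(config$chromosomes))
      chromosomeSet(unlist(config$chromosomes))
    else {
      L <- tapply(tr$end, tr$chrom, max)
      chromosomeSet(setNames(as.numeric(L), names(L)))
    }
    list(tracts = tr, chroms = chroms)
  })
  if (!st_in$ok) return(.finish_report(report, config))

  tr <- st_in$value$tracts
  chroms <- st_in$value$chroms

  st_prop <- stage("proportions", function() {
    pr <- ancestryProportions(tr, chroms, "individual")
    keep <- applyCohortFilters(pr, filters, "tracts")
    write.table(keep$exclusions, file.path(config$outdir, "tract_exclusions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(proportions = pr, retained = keep$retained,
         exclusions = keep$exclusions)
  })
  if (!st_prop$ok) return(.finish_report(report, config))

  st_fit <- stage("tract_model", function() {
    keep_ind <- st_prop$value$retained
    keep_hap <- c(2L * keep_ind - 1L, 2L * keep_ind)
    trf <- tr[tr$hap %in% keep_hap, , drop = FALSE]
    edges <- defaultBinEdges(chroms, config$tract_model$nBins,
                             config$tract_model$minLength)
    sp <- tractLengthSpectrum(trf, chroms, edges,
                              ancestries = config$ancestries,
                              nHaplotypes = length(keep_hap))
    pr <- st_prop$value$proportions
    pm <- colMeans(pr[pr$unit %in% keep_ind, config$ancestries, drop = FALSE])
    pm <- pm / sum(pm)
    cmp <- compareModels(sp, pm, altModel = config$model_select$alt %||% "EUR_PULSE",
                         nSim = config$model_select$nSim,
                         seed = substreamSeed(config$seed, "model_select"),
                         nStarts = config$tract_model$nStarts,
                         alpha = config$model_select$alpha)
    jsonlite::write_json(
      list(null = list(model = cmp@fitNull@model,
                       params = as.list(cmp@fitNull@params),
                       logLik = cmp@fitNull@logLik),
           alt = list(model = cmp@fitAlt@model,
                      params = as.list(cmp@fitAlt@params),
                      logLik = cmp@fitAlt@logLik),
           observedDelta = cmp@observedDelta, pValue = cmp@pValue,
           rejected = cmp@rejected, nSim = cmp@nSim),
      file.path(config$outdir, "model_comparison.json"),
      auto_unbox = TRUE, digits = NA)
    write.table(data.frame(delta = cmp@simDeltas),
                file.path(config$outdir, "null_deltas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cmp
  })

  if (!is.null(config$inputs$alleles) && !is.null(config$inputs$loci)) {
    st_ibd <- stage("ibd", function() {
      al <- as.matrix(read.table(config$inputs$alleles))
      loci <- read.table(config$inputs$loci, header = TRUE,
                         stringsAsFactors = FALSE)
      segs <- findIBDHaploid(al, loci,
                             sliceMarkers = config$ibd$sliceMarkers,
                             maxMismatchPerSlice = config$ibd$maxMismatchPerSlice,
                             minCM = config$ibd$minCM)
      segs <- segmentAncestryProfile(segs, tractsToCalls(tr))
      write.table(segs, file.path(config$outdir, "ibd_segments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      labels <- if (!is.null(config$inputs$labels))
        readPopulationLabels(config$inputs$labels)
      else setNames(rep("cohort", nrow(al)), seq_len(nrow(al)))
      sm <- if (length(chroms) >= 2) jackknifeSE(segs, chroms, labels)
      else sharingMatrix(segs, labels)
      write.table(sm@normalized, file.path(config$outdir, "ibd_sharing.tsv"),
                  sep = "\t", quote = FALSE)
      list(segments = segs, sharing = sm)
    })
  }

  .finish_report(report, config)
}

.finish_report <- function(report, config) {
  report$ok <- all(vapply(report$stages, function(s) isTRUE(s$ok), TRUE))
  ser <- serialize(list(report$config, lapply(report$stages, function(s) s$ok)),
                   NULL)
  report$hash <- paste(format(sum(as.integer(ser[seq(1, length(ser), 7)])
                                  * 2654435761) %% 2^31), length(ser))
  class(report) <- c("admixtractReport", "list")
  path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(
    list(ok = report$ok, seed = report$seed, hash = report$hash,
         stages = lapply(report$stages, function(s)
           if (isTRUE(s$ok)) "ok" else paste("failed:", s$error))),
    path, auto_unbox = TRUE)
  report
}

#' X-vs-autosome sex-bias comparison
#'
#' Paired two-sided Wilcoxon signed-rank test of the per-individual difference
#' between X-chromosome and autosomal ancestry fractions for one ancestry.
#' Uses the exact null distribution for 25 or fewer informative pairs (no
#' ties), otherwise the normal approximation with tie correction. A surplus of
#' the chosen ancestry on X relative to the autosomes is the classic signature
#' of sex-biased admixture.
#'
#' @param autosomalProps,xProps [ancestryProportions()]-style tables over the
#'   same individuals.
#' @param ancestry Column to compare.
#' @return list with \code{medianDiff} (X minus autosome), \code{statistic},
#'   \code{pValue}, \code{n}.
#' @export
sexbiasCompare <- function(autosomalProps, xProps, ancestry) {
  if (!setequal(autosomalProps$unit, xProps$unit))
    stop("the two tables must cover the same individuals")
  m <- match(autosomalProps$unit, xProps$unit)
  a <- autosomalProps[[ancestry]]
  x <- xProps[[ancestry]][m]
  if (length(a) < 2) stop("need at least two paired individuals")
  d <- x - a
  if (all(d == 0)) {
    warning("all paired differences are zero")
    return(list(medianDiff = 0, statistic = NA_real_, pValue = 1,
                n = length(d)))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(wilcox.test(x, a, paired = TRUE, exact = exact,
                                     correct = TRUE))
  list(medianDiff = median(d), statistic = unname(wt$statistic),
       pValue = wt$p.value, n = length(d))
}

#' Compare two pipeline runs
#'
#' Stage-by-stage deltas between two completed reports: difference in fitted
#' admixture times, Spearman correlation of the IBD segment-length
#' distributions per majority ancestry, and the Procrustes distance between
#' ASPCA coordinate sets after sign alignment. Used for A/B designs such as
#' trio-phased versus population-phased inputs run through the identical
#' pipeline.
#'
#' @param runA,runB Reports from [runFullAnalysis()].
#' @return data.frame with \code{stage}, \code{metric}, \code{value};
#'   stages missing from either run yield a warning and are skipped.
#' @export
abCompare <- function(runA, runB) {
  out <- list()
  both <- intersect(names(runA$stages), names(runB$stages))
  missing <- setdiff(union(names(runA$stages), names(runB$stages)), both)
  if (length(missing))
    warning("stages not present in both runs: ", paste(missing, collapse = ", "))
  getv <- function(run, st) if (isTRUE(run$stages[[st]]$ok)) run$stages[[st]]$value else NULL
  if ("tract_model" %in% both) {
    ca <- getv(runA, "tract_model"); cb <- getv(runB, "tract_model")
    if (!is.null(ca) && !is.null(cb)) {
      pa <- ca@fitNull@params; pb <- cb@fitNull@params
      for (p in names(pa))
        out[[length(out) + 1]] <- data.frame(stage = "tract_model",
                                             metric = paste0("delta_", p),
                                             value = unname(pb[p] - pa[p]))
    }
  }
  if ("ibd" %in% both) {
    sa <- getv(runA, "ibd")$segments; sb <- getv(runB, "ibd")$segments
    if (!is.null(sa) && !is.null(sb) && nrow(sa) && nrow(sb)) {
      anc_cols <- setdiff(names(sa), c("hapA", "hapB", "chrom", "start", "end",
                                       "length", "nMarkers", "discordant"))
      maj_a <- anc_cols[max.col(as.matrix(sa[, anc_cols, drop = FALSE]))]
      maj_b <- anc_cols[max.col(as.matrix(sb[, anc_cols, drop = FALSE]))]
      brks <- seq(0, max(sa$length, sb$length) + 1e-9, length.out = 11)
      for (a in intersect(unique(maj_a), unique(maj_b))) {
        ha <- hist(sa$length[maj_a == a], breaks = brks, plot = FALSE)$counts
        hb <- hist(sb$length[maj_b == a], breaks = brks, plot = FALSE)$counts
        out[[length(out) + 1]] <- data.frame(
          stage = "ibd", metric = paste0("spearman_", a),
          value = suppressWarnings(cor(ha, hb, method = "spearman")))
      }
    }
  }
  if ("aspca" %in% both) {
    ra <- getv(runA, "aspca"); rb <- getv(runB, "aspca")
    if (!is.null(ra) && !is.null(rb))
      out[[length(out) + 1]] <- data.frame(stage = "aspca",
                                           metric = "procrustes",
                                           value = procrustesDistance(ra@scores,
                                                                      rb@scores))
  }
  if (length(out) == 0) {
    warning("no comparable completed stages")
    return(data.frame(stage = character(), metric = character(),
                      value = numeric()))
  }
  do.call(rbind, out)
}

#' Procrustes distance between two coordinate sets
#'
#' Sign-aligns columns, then reports the symmetric Procrustes sum of squares
#' (via vegan when available, otherwise a direct orthogonal-rotation fit).
#'
#' @param a,b Matrices with matching rows.
#' @return Scalar distance (0 for identical configurations).
#' @export
procrustesDistance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in shape")
  for (j in seq_len(ncol(b)))
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  if (requireNamespace("vegan", quietly = TRUE))
    return(vegan::procrustes(a, b, symmetric = TRUE)$ss)
  sa <- scale(a, scale = FALSE); sb <- scale(b, scale = FALSE)
  sa <- sa / sqrt(sum(sa^2)); sb <- sb / sqrt(sum(sb^2))
  s <- svd(crossprod(sb, sa))
  1 - sum(s$d)^2
}
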