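#' Read ancestry tracts from BED-like TSV
#'
#' Expects the six columns written by [writeTractsBed()]: haplotype_id, chrom,
#' start_cM, end_cM, ancestry, posterior. Intervals are half-open cM.
#'
#' @param path File path.
#' @param ancestries Optional allowed ancestry labels; unknown labels raise an
#'   error listing the allowed set.
#' @return data.frame of validated tracts (hap, chrom, start, end, ancestry,
#'   posterior).
#' @export
readTractsBed <- function(path, ancestries = NULL) {
  first <- readLines(path, n = 1)
  if (length(first) == 0)
    return(data.frame(hap = integer(), chrom = character(), start = numeric(),
                      end = numeric(), ancestry = character(),
                      posterior = numeric(), stringsAsFactors = FALSE))
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("haplotype_id", "chrom", "start_cM", "end_cM", "ancestry", "posterior")
  if (!all(need %in% names(x)))
    stop("tract file ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  tr <- data.frame(hap = x$haplotype_id, chrom = as.character(x$chrom),
                   start = x$start_cM, end = x$end_cM,
                   ancestry = as.character(x$ancestry), posterior = x$posterior,
                   stringsAsFactors = FALSE)
  bad <- which(tr$end <= tr$start)
  if (length(bad))
    stop("tract with end <= start at line ", bad[1] + 1, " of ", path)
  if (any(tr$posterior < 0 | tr$posterior > 1))
    stop("tract posteriors must lie in [0, 1]")
  if (!is.null(ancestries) && !all(tr$ancestry %in% ancestries))
    stop("unknown ancestry label(s) ",
         paste(setdiff(tr$ancestry, ancestries), collapse = ", "),
         "; allowed: ", paste(ancestries, collapse = ", "))
  o <- order(tr$hap, tr$chrom, tr$start)
  tr <- tr[o, , drop = FALSE]
  if (nrow(tr) > 1) {
    same <- tr$hap[-1] == tr$hap[-nrow(tr)] & tr$chrom[-1] == tr$chrom[-nrow(tr)]
    ov <- which(same & tr$start[-1] < tr$end[-nrow(tr)] - 1e-9)
    if (length(ov))
      stop("overlapping tracts on haplotype ", tr$hap[ov[1] + 1], " (line ",
           o[ov[1] + 1] + 1, " of ", path, ")")
  }
  rownames(tr) <- NULL
  tr
}

#' Read RFMix-style local-ancestry calls
#'
#' Supports the RFMix v2 \code{msp.tsv} dialect (comment line with ancestry
#' codes, then rows chrom, spos, epos, sgpos, egpos, nsnps followed by one
#' column per haplotype) and the legacy per-marker Viterbi matrix (one row per
#' marker, one column per haplotype, 1-based ancestry codes) combined with a
#' genetic map. The dialect is auto-detected from the header. Posteriors come
#' from a companion forward-backward file when given, else 1.
#'
#' @param path msp.tsv or Viterbi matrix file.
#' @param map For Viterbi input: data.frame with \code{chrom}, \code{cM} per
#'   marker row (see [readGeneticMap()]).
#' @param ancestries Labels for ancestry codes; for msp input, defaults to the
#'   codes declared in the header.
#' @param fbPath Optional forward-backward posterior file (markers/windows x
#'   haplotypes).
#' @return A [LocalAncestryCalls-class]; per-marker input is collapsed to
#'   windows of constant call, posteriors take the window minimum.
#' @export
readRFMixCalls <- function(path, map = NULL, ancestries = NULL, fbPath = NULL) {
  lines1 <- readLines(path, n = 2)
  if (length(lines1) == 0) stop("empty local-ancestry file: ", path)
  is_msp <- grepl("^#", lines1[1]) || grepl("spos", lines1[1], ignore.case = TRUE)
  if (is_msp) {
    codes <- NULL
    if (grepl("^#Subpopulation order", lines1[1], ignore.case = TRUE)) {
      body <- sub("^#[^:]*:\\s*", "", lines1[1])
      parts <- strsplit(trimws(body), "[\t ]+")[[1]]
      codes <- sub("=.*$", "", parts)
      names(codes) <- sub("^.*=", "", parts)
    }
    skip <- sum(grepl("^#", lines1))
    x <- tryCatch(read.table(path, header = FALSE, sep = "\t", skip = skip,
                             stringsAsFactors = FALSE),
                  error = function(e) stop("malformed msp file ", path, ": ",
                                           conditionMessage(e)))
    if (ncol(x) < 7) stop("truncated msp header/rows in ", path)
    nh <- ncol(x) - 6
    if (nh %% 2 != 0) stop("odd haplotype count in ", path)
    if (is.null(ancestries)) {
      ancestries <- if (!is.null(codes)) codes else
        as.character(sort(unique(unlist(x[, -(1:6)]))))
    }
    recs <- lapply(seq_len(nh), function(h) {
      code <- x[[6 + h]]
      data.frame(hap = h, chrom = as.character(x[[1]]), start = x[[4]],
                 end = x[[5]],
                 ancestry = .map_code(code, ancestries),
                 posterior = 1.0, stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, recs)
  } else {
    if (is.null(map)) stop("legacy per-marker input needs a genetic map")
    x <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(x) != nrow(map))
      stop("marker count (", nrow(x), ") does not match map rows (",
           nrow(map), ")")
    nh <- ncol(x)
    if (nh %% 2 != 0) stop("odd haplotype count in ", path)
    if (is.null(ancestries))
      ancestries <- as.character(sort(unique(unlist(x))))
    post <- NULL
    if (!is.null(fbPath)) {
      post <- as.matrix(read.table(fbPath, header = FALSE))
      if (!all(dim(post) == dim(x))) stop("forward-backward file dimension mismatch")
    }
    # per-marker windows: midpoints between adjacent markers per chromosome
    calls <- do.call(rbind, lapply(split(seq_len(nrow(map)), map$chrom), function(ix) {
      cm <- map$cM[ix]
      lo <- c(cm[1], (cm[-1] + cm[-length(cm)]) / 2)
      hi <- c((cm[-1] + cm[-length(cm)]) / 2, cm[length(cm)] + (cm[length(cm)] - lo[length(cm)]))
      if (length(cm) == 1) { lo <- cm; hi <- cm + 1e-6 }
      do.call(rbind, lapply(seq_len(nh), function(h) {
        data.frame(hap = h, chrom = map$chrom[ix[1]], start = lo, end = hi,
                   ancestry = .map_code(x[ix, h], ancestries),
                   posterior = if (is.null(post)) 1.0 else post[ix, h],
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(calls) <- NULL
  }
  res <- new("LocalAncestryCalls", calls = .collapse_runs(calls))
  validObject(res)
  res
}

.map_code <- function(code, ancestries) {
  if (!is.null(names(ancestries))) {
    out <- unname(ancestries[as.character(code)])
  } else if (is.numeric(code) || all(grepl("^[0-9]+$", code))) {
    ix <- as.integer(code)
    if (min(ix) == 0) ix <- ix + 1L   # msp codes are 0-based
    out <- ancestries[ix]
  } else out <- as.character(code)
  if (anyNA(out)) stop("ancestry code outside declared set")
  out
}

# merge consecutive equal-call windows (keeps min posterior)
.collapse_runs <- function(calls) {
  o <- order(calls$hap, calls$chrom, calls$start)
  calls <- calls[o, , drop = FALSE]
  n <- nrow(calls)
  if (n < 2) return(calls)
  newrun <- c(TRUE, !(calls$hap[-1] == calls$hap[-n] &
                      calls$chrom[-1] == calls$chrom[-n] &
                      calls$ancestry[-1] == calls$ancestry[-n] &
                      calls$start[-1] <= calls$end[-n] + 1e-9))
  gid <- cumsum(newrun)
  data.frame(hap = calls$hap[newrun], chrom = calls$chrom[newrun],
             start = calls$start[newrun],
             end = as.numeric(tapply(calls$end, gid, max)),
             ancestry = calls$ancestry[newrun],
             posterior = as.numeric(tapply(calls$posterior, gid, min)),
             stringsAsFactors = FALSE)
}

#' Merge local-ancestry calls into tracts
#'
#' Maximal runs of identical ancestry become single tracts; the tract posterior
#' is the minimum window posterior in the run. Adjacent windows separated by a
#' gap smaller than one window width are treated as contiguous.
#'
#' @param calls A [LocalAncestryCalls-class].
#' @return data.frame of tracts (hap, chrom, start, end, ancestry, posterior).
#' @export
callsToTracts <- function(calls) {
  stopifnot(is(calls, "LocalAncestryCalls"))
  cl <- calls@calls
  if (nrow(cl) == 0)
    return(data.frame(hap = integer(), chrom = character(), start = numeric(),
                      end = numeric(), ancestry = character(),
                      posterior = numeric(), stringsAsFactors = FALSE))
  o <- order(cl$hap, cl$chrom, cl$start)
  cl <- cl[o, , drop = FALSE]
  n <- nrow(cl)
  w <- cl$end - cl$start
  gap_ok <- c(FALSE, cl$start[-1] - cl$end[-n] < pmin(w[-1], w[-n]))
  samerun <- c(FALSE, cl$hap[-1] == cl$hap[-n] & cl$chrom[-1] == cl$chrom[-n] &
               cl$ancestry[-1] == cl$ancestry[-n]) & gap_ok
  gid <- cumsum(!samerun)
  out <- data.frame(hap = cl$hap[!samerun], chrom = cl$chrom[!samerun],
                    start = cl$start[!samerun],
                    end = as.numeric(tapply(cl$end, gid, max)),
                    ancestry = cl$ancestry[!samerun],
                    posterior = as.numeric(tapply(cl$posterior, gid, min)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert tracts to synthetic single-window calls
#'
#' Utility for treating simulator truth tracts as local-ancestry calls (one
#' window per tract).
#'
#' @param tracts Tract data.frame.
#' @return A [LocalAncestryCalls-class].
#' @export
tractsToCalls <- function(tracts) {
  new("LocalAncestryCalls", calls = tracts[, c("hap", "chrom", "start", "end",
                                               "ancestry", "posterior")])
}

#' Per-unit ancestry proportions from tracts
#'
#' Fraction of each unit's genome assigned to each ancestry, computed as summed
#' tract length over summed chromosome length. Individual-level proportions
#' average the unit's two haplotypes.
#'
#' @param tracts Tract data.frame (must tile each haplotype's chromosomes).
#' @param chroms A [ChromosomeSet-class].
#' @param level "haplotype" or "individual" (haplotypes 2i-1, 2i belong to
#'   individual i).
#' @return data.frame with \code{unit} and one fraction column per ancestry;
#'   rows sum to 1.
#' @export
ancestryProportions <- function(tracts, chroms, level = c("haplotype", "individual")) {
  level <- match.arg(level)
  stopifnot(is(chroms, "ChromosomeSet"))
  G <- genomeLength(chroms)
  len <- tracts$end - tracts$start
  tot <- tapply(len, tracts$hap, sum)
  bad <- names(tot)[abs(tot - G) > 1e-6 * G]
  if (length(bad))
    stop("tracts do not tile the genome for haplotype(s) ",
         paste(head(bad, 3), collapse = ", "))
  unit <- if (level == "haplotype") tracts$hap else (as.integer(tracts$hap) + 1L) %/% 2L
  anc <- sort(unique(tracts$ancestry))
  agg <- tapply(len, list(unit, factor(tracts$ancestry, levels = anc)), sum,
                default = 0)
  denom <- if (level == "haplotype") G else 2 * G
  out <- data.frame(unit = as.integer(rownames(agg)), agg / denom,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Mask haplotype alleles by local ancestry
#'
#' A locus is kept only where the overlapping local-ancestry call equals the
#' target ancestry and its posterior is at or above the threshold; everywhere
#' else the allele becomes missing. Masking only changes observability, never
#' an observed allele value.
#'
#' @param haplotypes 0/1 allele matrix (haplotypes x loci).
#' @param loci data.frame with \code{chrom}, \code{cM} per column of
#'   \code{haplotypes}.
#' @param calls A [LocalAncestryCalls-class] covering every locus of every
#'   haplotype row.
#' @param target Target ancestry label.
#' @param minPosterior Posterior threshold (default 0.95); calls strictly
#'   below it are masked.
#' @param labels Optional per-haplotype population labels.
#' @return A [MaskedHaplotypes-class] (all rows flagged non-reference).
#' @export
maskHaplotypes <- function(haplotypes, loci, calls, target, minPosterior = 0.95,
                           labels = NULL) {
  stopifnot(is(calls, "LocalAncestryCalls"))
  cl <- calls@calls
  al <- as.matrix(haplotypes)
  nhap <- nrow(al)
  if (is.null(labels)) labels <- rep("admixed", nhap)
  keymap <- split(seq_len(nrow(cl)), paste0(cl$chrom, "|", cl$hap))
  for (h in seq_len(nhap)) {
    for (ch in unique(loci$chrom)) {
      sel <- which(loci$chrom == ch)
      idx <- keymap[[paste0(ch, "|", h)]]
      if (is.null(idx))
        stop("no local-ancestry calls for haplotype ", h, " on ", ch)
      idx <- idx[order(cl$start[idx])]
      ti <- findInterval(loci$cM[sel], cl$start[idx])
      if (any(ti == 0) || any(loci$cM[sel] >= cl$end[idx][ti] + 1e-9))
        stop("locus not covered by any call (haplotype ", h, ", ", ch, ")")
      keep <- cl$ancestry[idx][ti] == target &
              cl$posterior[idx][ti] >= minPosterior
      al[h, sel[!keep]] <- NA
    }
  }
  new("MaskedHaplotypes", alleles = al, chrom = as.character(loci$chrom),
      cM = loci$cM, labels = labels, isReference = rep(FALSE, nhap))
}

#' Apply cohort exclusion filters
#'
#' Implements the cohort exclusion rules on a table of per-unit
#' ancestry fractions. Modes: \code{aspca_admixed} keeps units with target
#' ancestry fraction at or above \code{minTargetAncestry} (excluded iff
#' strictly less than 25\% by default); \code{aspca_reference} keeps units
#' whose European fraction does not exceed \code{maxReferenceContamination}
#' (excluded iff strictly greater than 10\%); \code{tracts} keeps units whose
#' largest single-ancestry fraction does not exceed \code{maxSingleAncestry}
#' (excluded iff strictly greater than 95\%).
#'
#' @param proportions data.frame from [ancestryProportions()] (column
#'   \code{unit} plus one column per ancestry).
#' @param filters A [CohortFilters-class].
#' @param mode One of "aspca_admixed", "aspca_reference", "tracts".
#' @param target Target ancestry (aspca_admixed mode).
#' @param contaminant Contaminating ancestry for reference filtering (default
#'   "EUR").
#' @return list with \code{retained} (unit ids) and \code{exclusions}
#'   (data.frame unit, rule, value).
#' @export
applyCohortFilters <- function(proportions, filters = cohortFilters(),
                               mode = c("aspca_admixed", "aspca_reference", "tracts"),
                               target = NULL, contaminant = "EUR") {
  mode <- match.arg(mode)
  anc_cols <- setdiff(names(proportions), "unit")
  rs <- rowSums(proportions[, anc_cols, drop = FALSE])
  if (any(abs(rs - 1) > 1e-6)) stop("proportions must sum to 1 per unit")
  if (mode == "aspca_admixed") {
    if (is.null(target) || !(target %in% anc_cols))
      stop("aspca_admixed mode needs a target ancestry column")
    val <- proportions[[target]]
    drop <- val < filters@minTargetAncestry
    rule <- sprintf("%s < %g", target, filters@minTargetAncestry)
  } else if (mode == "aspca_reference") {
    val <- if (contaminant %in% anc_cols) proportions[[contaminant]] else
      rep(0, nrow(proportions))
    drop <- val > filters@maxReferenceContamination
    rule <- sprintf("%s > %g", contaminant, filters@maxReferenceContamination)
  } else {
    val <- do.call(pmax, proportions[, anc_cols, drop = FALSE])
    drop <- val > filters@maxSingleAncestry
    rule <- sprintf("max ancestry > %g", filters@maxSingleAncestry)
  }
  list(retained = proportions$unit[!drop],
       exclusions = data.frame(unit = proportions$unit[drop],
                               rule = rep(rule, sum(drop)),
                               value = val[drop]))
}

#' Observed tract-length spectrum
#'
#' Bins tract lengths per ancestry into \code{[edge_i, edge_{i+1})} counts.
#' Tracts spanning a whole chromosome go into a dedicated per-chromosome
#' category rather than a length bin; tracts shorter than the first edge are
#' excluded (local-ancestry resolution floor). The final bin is open-ended
#' when the last edge is \code{Inf}.
#'
#' @param tracts Tract data.frame.
#' @param chroms A [ChromosomeSet-class].
#' @param edges Strictly increasing bin edges in cM; append \code{Inf} for an
#'   open final bin. Default: [defaultBinEdges()].
#' @param ancestries Ancestry labels (rows of the spectrum); defaults to those
#'   present.
#' @param nHaplotypes Number of haplotypes (default: distinct \code{hap} ids).
#' @return A [TractSpectrum-class] with \code{type = "observed"}.
#' @export
tractLengthSpectrum <- function(tracts, chroms, edges = defaultBinEdges(chroms),
                                ancestries = sort(unique(tracts$ancestry)),
                                nHaplotypes = length(unique(tracts$hap))) {
  stopifnot(is(chroms, "ChromosomeSet"))
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  nb <- length(edges) - 1
  len <- tracts$end - tracts$start
  L <- chromLengths(chroms)[tracts$chrom]
  isfull <- abs(len - L) < 1e-9 & abs(tracts$start) < 1e-9
  counts <- matrix(0, length(ancestries), nb,
                   dimnames = list(ancestries, NULL))
  full <- matrix(0, length(ancestries), length(chroms),
                 dimnames = list(ancestries, chromNames(chroms)))
  for (a in ancestries) {
    selc <- tracts$ancestry == a & !isfull
    b <- findInterval(len[selc], edges)
    b <- b[b >= 1 & b <= nb]
    counts[a, ] <- tabulate(b, nb)
    self <- tracts$ancestry == a & isfull
    full[a, ] <- tabulate(match(tracts$chrom[self], chromNames(chroms)),
                          length(chroms))
  }
  new("TractSpectrum", counts = counts, full = full, edges = as.numeric(edges),
      chroms = chroms, nHaplotypes = as.numeric(nHaplotypes),
      type = "observed", lengthMass = NULL)
}

#' Default tract-length bin edges
#'
#' 50 equal-width bins from 0.2 cM (the local-ancestry window resolution
#' floor) to the longest chromosome, with an open-ended final bin.
#'
#' @param chroms A [ChromosomeSet-class].
#' @param nBins Number of finite bins.
#' @param minLength Lower limit in cM.
#' @return Numeric edge vector (last element Inf).
#' @export
defaultBinEdges <- function(chroms, nBins = 50, minLength = 0.2) {
  c(seq(minLength, max(chromLengths(chroms)), length.out = nBins), Inf)
}

#' Read a genetic map
#'
#' PLINK-style 4-column map (chrom, id, cM, bp) or 3-column HapMap-format
#' (chrom, bp, cM or position/rate/cM); auto-detected by column count and
#' header.
#'
#' @param path File path.
#' @return data.frame with \code{chrom}, \code{bp}, \code{cM}, sorted.
#' @export
readGeneticMap <- function(path) {
  x <- read.table(path, header = .has_header(path), stringsAsFactors = FALSE)
  if (ncol(x) == 4) {
    out <- data.frame(chrom = as.character(x[[1]]), bp = as.numeric(x[[4]]),
                      cM = as.numeric(x[[3]]))
  } else if (ncol(x) == 3) {
    out <- data.frame(chrom = as.character(x[[1]]), bp = as.numeric(x[[2]]),
                      cM = as.numeric(x[[3]]))
  } else stop("unrecognized genetic map format (", ncol(x), " columns)")
  out[order(out$chrom, out$bp), ]
}

.has_header <- function(path) {
  l1 <- readLines(path, n = 1)
  any(grepl("[A-Za-z]{2}", strsplit(l1, "[\t ]+")[[1]][-1]))
}

#' Interpolate genetic position from physical position
#'
#' Linear interpolation on the genetic map; positions beyond the map ends are
#' clamped to the terminal cM values (with a warning listing how many).
#'
#' @param chrom,bp Vectors of positions to convert.
#' @param map data.frame from [readGeneticMap()].
#' @return Numeric cM positions.
#' @export
interpolateCM <- function(chrom, bp, map) {
  out <- numeric(length(bp))
  clamped <- 0
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    mm <- map[map$chrom == ch, ]
    if (nrow(mm) < 2) stop("genetic map has < 2 points for ", ch)
    clamped <- clamped + sum(bp[sel] < min(mm$bp) | bp[sel] > max(mm$bp))
    out[sel] <- approx(mm$bp, mm$cM, xout = bp[sel], rule = 2, ties = "ordered")$y
  }
  if (clamped > 0)
    warning(clamped, " position(s) beyond map ends clamped to terminal cM")
  out
}

#' Read a two-column population label table
#'
#' @param path TSV with columns id, population (header optional).
#' @return Named character vector (population per id).
#' @export
readPopulationLabels <- function(path) {
  x <- read.table(path, header = .has_header(path), stringsAsFactors = FALSE)
  setNames(as.character(x[[2]]), as.character(x[[1]]))
}
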