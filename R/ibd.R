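# Haploid IBD detection and ancestry overlay.
#
# Detection follows the seed-and-extend hashing design of GERMLINE run in
# haploid mode: markers are partitioned into fixed-size slices, exact slice
# matches between haplotype pairs are found by hashing, matches are extended
# across adjacent slices while each slice carries at most a small number of
# allele mismatches (the haploid analogue of the err_hom budget; the diploid
# err_hom/err_het distinction has no haploid counterpart), and maximal runs of
# at least the minimum genetic length are reported.

#' Detect IBD segments between haplotypes (haploid mode)
#'
#' @param haplotypes 0/1 allele matrix (haplotypes x markers), phased, no
#'   missing entries.
#' @param map data.frame with \code{chrom}, \code{cM} per marker column,
#'   positions sorted within chromosome.
#' @param sliceMarkers Markers per hashing slice (GERMLINE "bits", default 128).
#' @param maxMismatchPerSlice Allele mismatches tolerated per slice during
#'   extension (default 2); seed slices must match exactly.
#' @param minCM Minimum reported genetic length (default 3 cM).
#' @return data.frame of segments: \code{hapA}, \code{hapB}, \code{chrom},
#'   \code{start}, \code{end}, \code{length} (cM), \code{nMarkers}.
#' @export
findIBDHaploid <- function(haplotypes, map, sliceMarkers = 128,
                           maxMismatchPerSlice = 2, minCM = 3.0) {
  X <- as.matrix(haplotypes)
  if (nrow(X) < 2) stop("need at least two haplotypes")
  if (ncol(X) != nrow(map)) stop("map rows must match marker columns")
  segs <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    pos <- map$cM[sel]
    if (is.unsorted(pos)) stop("genetic map not sorted on ", ch)
    nm <- length(sel)
    sm <- sliceMarkers
    if (sm > nm) {
      warning("sliceMarkers (", sm, ") exceeds marker count on ", ch,
              "; using a single slice")
      sm <- nm
    }
    slice_id <- ((seq_len(nm) - 1L) %/% sm) + 1L
    ns <- max(slice_id)
    Xc <- X[, sel, drop = FALSE]
    # seed pairs per slice via exact hashing
    cand <- new.env(hash = TRUE)
    for (s in seq_len(ns)) {
      cols <- which(slice_id == s)
      key <- do.call(paste0, as.data.frame(Xc[, cols, drop = FALSE]))
      for (grp in split(seq_len(nrow(X)), key)) {
        if (length(grp) < 2) next
        prs <- utils::combn(grp, 2)
        for (j in seq_len(ncol(prs))) {
          k <- paste0(prs[1, j], "_", prs[2, j])
          cand[[k]] <- TRUE
        }
      }
    }
    for (k in ls(cand)) {
      ij <- as.integer(strsplit(k, "_")[[1]])
      d <- Xc[ij[1], ] != Xc[ij[2], ]
      mism <- as.integer(tapply(d, slice_id, sum))
      ok <- mism <= maxMismatchPerSlice
      # maximal runs of tolerated slices containing >= 1 exact slice
      r <- rle(ok)
      endsl <- cumsum(r$lengths)
      startsl <- endsl - r$lengths + 1L
      pair_segs <- list()
      for (ri in which(r$values)) {
        s1 <- startsl[ri]; s2 <- endsl[ri]
        if (!any(mism[s1:s2] == 0)) next
        m1 <- which(slice_id == s1)[1]
        m2 <- max(which(slice_id == s2))
        # marker-level extension into the flanking slices (stop at the first
        # mismatching marker), as in the reference seed-and-extend design
        while (m1 > 1 && !d[m1 - 1]) m1 <- m1 - 1L
        while (m2 < nm && !d[m2 + 1]) m2 <- m2 + 1L
        pair_segs[[length(pair_segs) + 1]] <- c(m1, m2)
      }
      if (length(pair_segs) == 0) next
      # merge overlapping/adjacent extents from neighbouring seed runs
      pair_segs <- pair_segs[order(vapply(pair_segs, `[`, 0, 1))]
      merged <- list(pair_segs[[1]])
      for (pseg in pair_segs[-1]) {
        last <- merged[[length(merged)]]
        if (pseg[1] <= last[2] + 1L)
          merged[[length(merged)]] <- c(last[1], max(last[2], pseg[2]))
        else merged[[length(merged) + 1]] <- pseg
      }
      for (pseg in merged) {
        m1 <- pseg[1]; m2 <- pseg[2]
        len <- pos[m2] - pos[m1]
        if (len < minCM) next
        segs[[length(segs) + 1]] <- data.frame(
          hapA = ij[1], hapB = ij[2], chrom = ch,
          start = pos[m1], end = pos[m2], length = len,
          nMarkers = m2 - m1 + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(segs) == 0)
    return(data.frame(hapA = integer(), hapB = integer(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      nMarkers = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  out[order(out$chrom, out$hapA, out$hapB, out$start), , drop = FALSE]
}

#' Read a GERMLINE .match file
#'
#' Standard 15-column GERMLINE output (family/individual ids for both members,
#' chromosome, bp start/end, marker ids, marker count, length, unit, ...).
#' Lengths in cM pass through unchanged; other units are converted from the bp
#' coordinates via the genetic map and flagged in the \code{converted} column.
#'
#' @param path .match file.
#' @param map Genetic map from [readGeneticMap()] (needed for non-cM units).
#' @return data.frame of segments with ids, cM coordinates and length.
#' @export
readGermlineMatch <- function(path, map = NULL) {
  if (file.size(path) == 0)
    return(data.frame(idA = character(), idB = character(), chrom = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      nMarkers = integer(), converted = logical(),
                      stringsAsFactors = FALSE))
  x <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                error = function(e) stop("malformed GERMLINE match file ", path,
                                         ": ", conditionMessage(e)))
  if (ncol(x) < 12)
    stop("malformed GERMLINE match file ", path, ": expected >= 12 columns")
  unit <- toupper(as.character(x[[12]]))
  conv <- unit != "CM"
  start <- end <- numeric(nrow(x))
  if (any(conv)) {
    if (is.null(map)) stop("non-cM units present; a genetic map is required")
    start[conv] <- interpolateCM(as.character(x[[5]][conv]), x[[6]][conv], map)
    end[conv] <- interpolateCM(as.character(x[[5]][conv]), x[[7]][conv], map)
  }
  if (any(!conv)) {
    if (!is.null(map)) {
      start[!conv] <- interpolateCM(as.character(x[[5]][!conv]), x[[6]][!conv], map)
      end[!conv] <- start[!conv] + x[[11]][!conv]
    } else {
      # package bp convention: bp = round(cM * 1e6)
      start[!conv] <- x[[6]][!conv] / 1e6
      end[!conv] <- start[!conv] + x[[11]][!conv]
    }
  }
  data.frame(idA = paste(x[[1]], x[[2]], sep = "."),
             idB = paste(x[[3]], x[[4]], sep = "."),
             chrom = as.character(x[[5]]), start = start, end = end,
             length = end - start, nMarkers = x[[10]], converted = conv,
             stringsAsFactors = FALSE)
}

#' Write segments in GERMLINE .match layout
#'
#' @param segments data.frame from [findIBDHaploid()].
#' @param path Output file.
#' @export
writeGermlineMatch <- function(segments, path) {
  out <- data.frame(f1 = "FAM", i1 = segments$hapA, f2 = "FAM",
                    i2 = segments$hapB, chrom = segments$chrom,
                    s = as.integer(round(segments$start * 1e6)),
                    e = as.integer(round(segments$end * 1e6)),
                    m1 = ".", m2 = ".", n = segments$nMarkers,
                    len = segments$length, unit = "cM", mm = 0, h1 = 0, h2 = 0)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Ancestry profile of IBD segments
#'
#' For each segment, length-weighted local-ancestry proportions over
#' \code{[start, end)} are computed separately for the two haplotypes and
#' averaged; a discordance flag marks segments whose two haplotypes disagree
#' in majority ancestry (the profile is still the average of the two).
#'
#' @param segments data.frame with \code{hapA}, \code{hapB}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param calls A [LocalAncestryCalls-class] covering both haplotypes of every
#'   segment.
#' @return \code{segments} with one proportion column per ancestry plus
#'   \code{discordant}.
#' @export
segmentAncestryProfile <- function(segments, calls) {
  stopifnot(is(calls, "LocalAncestryCalls"))
  cl <- calls@calls
  anc <- sort(unique(cl$ancestry))
  idx <- split(seq_len(nrow(cl)), paste0(cl$chrom, "|", cl$hap))
  one <- function(h, ch, s, e) {
    ix <- idx[[paste0(ch, "|", h)]]
    if (is.null(ix)) stop("no ancestry calls for haplotype ", h, " on ", ch)
    ix <- ix[order(cl$start[ix])]
    ov <- pmin(cl$end[ix], e) - pmax(cl$start[ix], s)
    ov[ov < 0] <- 0
    if (abs(sum(ov) - (e - s)) > 1e-6 * (e - s))
      stop("calls do not cover [", s, ", ", e, ") for haplotype ", h, " on ", ch)
    vapply(anc, function(a) sum(ov[cl$ancestry[ix] == a]), 0) / (e - s)
  }
  prof <- matrix(0, nrow(segments), length(anc), dimnames = list(NULL, anc))
  disc <- logical(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    pa <- one(segments$hapA[i], segments$chrom[i], segments$start[i], segments$end[i])
    pb <- one(segments$hapB[i], segments$chrom[i], segments$start[i], segments$end[i])
    prof[i, ] <- (pa + pb) / 2
    disc[i] <- anc[which.max(pa)] != anc[which.max(pb)]
  }
  cbind(segments, as.data.frame(prof), discordant = disc)
}

#' Population-level normalized IBD sharing
#'
#' Sums IBD segment lengths between (and within) populations and normalizes by
#' the number of haplotype pairs: \code{n_P * n_Q} for distinct populations,
#' \code{n_P (n_P - 1) / 2} within a population.
#'
#' @param segments data.frame with \code{hapA}, \code{hapB}, \code{length}.
#' @param labels Named vector: population per haplotype id.
#' @param level "both" (default), "within" or "between" (cells outside the
#'   chosen level are NA).
#' @return A [SharingMatrix-class].
#' @export
sharingMatrix <- function(segments, labels, level = c("both", "within", "between")) {
  level <- match.arg(level)
  la <- labels[as.character(segments$hapA)]
  lb <- labels[as.character(segments$hapB)]
  if (anyNA(la) || anyNA(lb))
    stop("unlabeled haplotype(s): ",
         paste(unique(c(segments$hapA[is.na(la)], segments$hapB[is.na(lb)])),
               collapse = ", "))
  pops <- sort(unique(labels))
  npop <- table(factor(labels, levels = pops))
  tot <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  if (nrow(segments)) {
    p1 <- pmin(la, lb); p2 <- pmax(la, lb)
    agg <- tapply(segments$length, list(factor(p1, pops), factor(p2, pops)),
                  sum, default = 0)
    agg[is.na(agg)] <- 0
    tot <- agg + t(agg)
    diag(tot) <- diag(agg)
  }
  denom <- outer(as.numeric(npop), as.numeric(npop))
  diag(denom) <- as.numeric(npop) * (as.numeric(npop) - 1) / 2
  norm <- tot / denom
  norm[!is.finite(norm)] <- 0
  if (level == "within") norm[row(norm) != col(norm)] <- NA
  if (level == "between") diag(norm) <- NA
  new("SharingMatrix", total = tot, normalized = norm,
      n = setNames(as.numeric(npop), pops), se = NULL)
}

#' Chromosome-weighted jackknife SEs for normalized sharing
#'
#' Delete-one-chromosome jackknife with blocks weighted by genetic length
#' (delete-m weighted jackknife): pseudovalues
#' \code{tau_j = h_j theta - (h_j - 1) theta_(j)} with \code{h_j = M / m_j},
#' variance \code{(1/g) sum_j (tau_j - theta_J)^2 / (h_j - 1)}.
#'
#' @param segments Segment data.frame with \code{chrom}, \code{length}.
#' @param chroms A [ChromosomeSet-class] (needs >= 2 chromosomes).
#' @param labels Named population labels per haplotype.
#' @return A [SharingMatrix-class] with the \code{se} slot filled.
#' @export
jackknifeSE <- function(segments, chroms, labels) {
  stopifnot(is(chroms, "ChromosomeSet"))
  if (length(chroms) < 2)
    stop("chromosome-weighted jackknife needs at least two chromosomes")
  full <- sharingMatrix(segments, labels)
  mj <- chromLengths(chroms)
  M <- sum(mj)
  g <- length(mj)
  theta <- full@normalized
  thJ <- g * theta
  taus <- vector("list", g)
  for (j in seq_len(g)) {
    thj <- sharingMatrix(segments[segments$chrom != chromNames(chroms)[j], ,
                                  drop = FALSE], labels)@normalized
    hj <- M / mj[j]
    taus[[j]] <- hj * theta - (hj - 1) * thj
    thJ <- thJ - (1 - mj[j] / M) * thj
  }
  v <- matrix(0, nrow(theta), ncol(theta), dimnames = dimnames(theta))
  for (j in seq_len(g)) {
    hj <- M / mj[j]
    v <- v + (taus[[j]] - thJ)^2 / (hj - 1)
  }
  full@se <- sqrt(v / g)
  full
}

#' Regression of European ancestry on IBD segment length
#'
#' Ordinary least squares of the per-segment European ancestry proportion on
#' segment genetic length, optionally within groups (e.g. within- vs
#' between-population segments).
#'
#' @param segments data.frame from [segmentAncestryProfile()].
#' @param ancestry Profile column to regress (default "EUR").
#' @param by Optional grouping column name.
#' @return data.frame with \code{group}, \code{slope}, \code{se},
#'   \code{pValue}, \code{n}.
#' @export
lengthAncestryRegression <- function(segments, ancestry = "EUR", by = NULL) {
  if (!(ancestry %in% names(segments)))
    stop("no ancestry profile column '", ancestry, "'")
  groups <- if (is.null(by)) list(all = seq_len(nrow(segments))) else
    split(seq_len(nrow(segments)), segments[[by]])
  out <- lapply(names(groups), function(gn) {
    ix <- groups[[gn]]
    if (length(ix) < 3) stop("need at least 3 segments (group ", gn, ")")
    x <- segments$length[ix]; y <- segments[[ancestry]][ix]
    if (var(x) == 0) stop("zero variance in segment length (group ", gn, ")")
    fit <- summary(lm(y ~ x))
    data.frame(group = gn, slope = fit$coefficients["x", 1],
               se = fit$coefficients["x", 2],
               pValue = fit$coefficients["x", 4], n = length(ix),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
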