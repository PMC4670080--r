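# Ancestry-specific PCA: subspace PCA over masked admixed haplotypes joined
# with an unmasked subcontinental reference panel in one coordinate space.

#' Join masked admixed haplotypes with a reference panel
#'
#' Row-concatenates the masked admixed matrix and the fully observed reference
#' panel on their shared locus set (matched on chromosome + cM position).
#' Loci observed in less than 1\% of rows overall are dropped and logged; a
#' locus masked in every admixed row but present in the reference is retained.
#'
#' @param masked A [MaskedHaplotypes-class] of admixed haplotypes.
#' @param reference 0/1 allele matrix for reference haplotypes (no missing
#'   entries).
#' @param referenceLoci data.frame with \code{chrom}, \code{cM} per reference
#'   column.
#' @param referenceLabels Population label per reference haplotype.
#' @return A [MaskedHaplotypes-class] with reference rows flagged.
#' @export
assembleASPCAMatrix <- function(masked, reference, referenceLoci,
                                referenceLabels) {
  stopifnot(is(masked, "MaskedHaplotypes"))
  reference <- as.matrix(reference)
  if (anyNA(reference)) stop("reference panel must be fully observed")
  if (nrow(reference) != length(referenceLabels))
    stop("referenceLabels length mismatch")
  keyA <- paste0(masked@chrom, ":", signif(masked@cM, 10))
  keyR <- paste0(referenceLoci$chrom, ":", signif(referenceLoci$cM, 10))
  shared <- intersect(keyA, keyR)
  if (length(shared) == 0)
    stop("no shared loci between admixed and reference panels (intersection 0)")
  ia <- match(shared, keyA); ir <- match(shared, keyR)
  al <- rbind(masked@alleles[, ia, drop = FALSE],
              reference[, ir, drop = FALSE])
  labels <- c(masked@labels, referenceLabels)
  isref <- c(masked@isReference, rep(TRUE, nrow(reference)))
  obs_frac <- colMeans(!is.na(al))
  drop <- obs_frac < 0.01
  if (any(drop)) {
    message(sum(drop), " loci with >99% missingness dropped")
    al <- al[, !drop, drop = FALSE]
    ia <- ia[!drop]
  }
  new("MaskedHaplotypes", alleles = al, chrom = masked@chrom[ia],
      cM = masked@cM[ia], labels = labels, isReference = isref)
}

#' Subspace PCA with structured missingness
#'
#' Iterative rank-k completion: columns are centered on their observed
#' entries, missing entries start at the column mean, and the algorithm
#' alternates a truncated rank-k decomposition with re-imputation of the
#' missing entries from the rank-k reconstruction until the imputed entries
#' change by less than \code{tol} (RMS) or \code{maxIter} is reached. With no
#' missing entries this reduces exactly to standard PCA. Component signs are
#' fixed so the first reference population's centroid is nonnegative on every
#' component (falling back to the largest-magnitude loading when no reference
#' rows are present).
#'
#' @param masked A [MaskedHaplotypes-class] (typically from
#'   [assembleASPCAMatrix()]).
#' @param k Number of components (default 2).
#' @param maxIter,tol Iteration cap and RMS convergence tolerance for the
#'   imputed entries.
#' @param minObserved Rows with a smaller observed fraction are excluded and
#'   logged.
#' @param seed Seed for the randomized subspace initialization.
#' @return An [ASPCAResult-class] with scores for all retained rows.
#' @export
subspacePCA <- function(masked, k = 2, maxIter = 200, tol = 1e-6,
                        minObserved = 0.005, seed = 1) {
  stopifnot(is(masked, "MaskedHaplotypes"))
  X <- masked@alleles
  storage.mode(X) <- "double"
  if (k < 1) stop("k must be >= 1")
  if (k >= min(dim(X))) stop("k must be smaller than both matrix dimensions")
  obs_frac <- rowMeans(!is.na(X))
  dropped <- which(obs_frac < pmax(minObserved, .Machine$double.eps))
  exclusions <- data.frame(unit = if (is.null(rownames(X))) as.character(dropped)
                           else rownames(X)[dropped],
                           rule = rep(sprintf("observed fraction < %g", minObserved),
                                      length(dropped)),
                           value = obs_frac[dropped])
  if (length(dropped)) {
    X <- X[-dropped, , drop = FALSE]
    labels <- masked@labels[-dropped]
    isref <- masked@isReference[-dropped]
  } else {
    labels <- masked@labels; isref <- masked@isReference
  }
  if (nrow(X) <= k) stop("fewer than k + 1 rows after exclusions")
  miss <- is.na(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  Xc <- sweep(X, 2, mu)
  Xc[miss] <- 0
  set.seed(as.integer(seed))
  if (!any(miss)) {
    sv <- svd(Xc, nu = k, nv = k)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
    tot <- sum(sv$d^2)
    vshare <- sv$d[seq_len(k)]^2 / tot
    it <- 0L; conv <- TRUE; delta <- 0
  } else {
    V <- matrix(rnorm(ncol(Xc) * k), ncol = k)
    d <- rep(1, k)
    delta <- Inf; it <- 0L
    imput_old <- Xc[miss]
    repeat {
      it <- it + 1L
      # rank-k subspace by orthogonal (block power) iteration, warm-started
      inner <- if (it <= 2) 30L else 6L
      for (j in seq_len(inner)) {
        U <- Xc %*% V
        U <- qr.Q(qr(U))
        V <- crossprod(Xc, U)
        d <- sqrt(colSums(V^2))
        V <- sweep(V, 2, pmax(d, 1e-12), "/")
      }
      recon <- (Xc %*% V) %*% t(V)
      imput <- recon[miss]
      delta <- sqrt(mean((imput - imput_old)^2))
      Xc[miss] <- imput
      imput_old <- imput
      # re-center on the completed matrix to keep columns mean-zero
      cm <- colMeans(Xc)
      Xc <- sweep(Xc, 2, cm)
      if (delta < tol || it >= maxIter) break
    }
    conv <- delta < tol
    if (!conv) warning("subspace PCA did not converge (delta = ",
                       format(delta), ")")
    sv <- svd(Xc, nu = k, nv = k)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
    tot <- sum(sv$d^2)
    vshare <- sv$d[seq_len(k)]^2 / tot
  }
  # sign convention
  refpops <- unique(labels[isref])
  sign_flip <- logical(k)
  for (j in seq_len(k)) {
    s <- if (length(refpops)) mean(scores[isref & labels == refpops[1], j]) else
      scores[which.max(abs(scores[, j])), j]
    sign_flip[j] <- is.finite(s) && s < 0
    if (sign_flip[j]) scores[, j] <- -scores[, j]
  }
  loadings <- sv$v
  for (j in seq_len(k)) if (sign_flip[j]) loadings[, j] <- -loadings[, j]
  colnames(scores) <- colnames(loadings) <- paste0("ASPC", seq_len(k))
  rownames(scores) <- rownames(X)
  new("ASPCAResult", scores = scores, loadings = loadings,
      varShare = vshare, labels = labels,
      isReference = isref, iterations = it, converged = conv, delta = delta,
      exclusions = exclusions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full ancestry-specific PCA pipeline
#'
#' Masks admixed haplotypes to the target ancestry (posterior threshold from
#' \code{filters}), applies the cohort filters (admixed haplotypes need at
#' least 25\% target ancestry; reference individuals with more than 10\%
#' European ancestry are excluded when reference proportions are supplied),
#' joins the surviving haplotypes with the reference panel and runs
#' [subspacePCA()]. The exclusion log is carried in the result.
#'
#' @param haplotypes Admixed 0/1 allele matrix (haplotypes x loci).
#' @param loci data.frame with \code{chrom}, \code{cM}.
#' @param calls [LocalAncestryCalls-class] for the admixed haplotypes.
#' @param reference,referenceLoci,referenceLabels Reference panel (see
#'   [assembleASPCAMatrix()]).
#' @param target Target ancestry label.
#' @param filters A [CohortFilters-class].
#' @param k Number of components.
#' @param chroms A [ChromosomeSet-class] for ancestry-fraction computation.
#' @param referenceProportions Optional [ancestryProportions()]-style table
#'   for the reference panel (unit = reference row index) used for the
#'   contamination filter.
#' @param labels Optional per-haplotype population labels for the admixed rows.
#' @param ... Passed to [subspacePCA()].
#' @return An [ASPCAResult-class].
#' @export
aspcaPipeline <- function(haplotypes, loci, calls, reference, referenceLoci,
                          referenceLabels, target, chroms,
                          filters = cohortFilters(), k = 2,
                          referenceProportions = NULL, labels = NULL, ...) {
  masked <- maskHaplotypes(haplotypes, loci, calls, target,
                           minPosterior = filters@minPosterior, labels = labels)
  props <- ancestryProportions(callsToTracts(calls), chroms, "haplotype")
  keep <- applyCohortFilters(props, filters, "aspca_admixed", target = target)
  excl <- keep$exclusions
  sel <- props$unit %in% keep$retained
  masked@alleles <- masked@alleles[sel, , drop = FALSE]
  masked@labels <- masked@labels[sel]
  masked@isReference <- masked@isReference[sel]
  if (!is.null(referenceProportions)) {
    rkeep <- applyCohortFilters(referenceProportions, filters,
                                "aspca_reference")
    excl <- rbind(excl, rkeep$exclusions)
    rsel <- referenceProportions$unit %in% rkeep$retained
    reference <- reference[rsel, , drop = FALSE]
    referenceLabels <- referenceLabels[rsel]
  }
  joint <- assembleASPCAMatrix(masked, reference, referenceLoci,
                               referenceLabels)
  res <- subspacePCA(joint, k = k, ...)
  res@exclusions <- rbind(excl[, c("unit", "rule", "value")],
                          res@exclusions)
  res
}

#' Write ASPCA coordinates to TSV
#'
#' Columns: haplotype, population, is_reference, ASPC1..k.
#' @param result An [ASPCAResult-class].
#' @param path Output file.
#' @export
writeASPCACoords <- function(result, path) {
  out <- data.frame(haplotype = rownames(result@scores) %||%
                      seq_len(nrow(result@scores)),
                    population = result@labels,
                    is_reference = result@isReference,
                    result@scores, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
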