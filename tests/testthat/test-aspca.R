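# two-population reference + masked admixed haplotypes, fully synthetic
aspcaBenchFx <- function(nRef = 30, nAdm = 30, nLoci = 3000, fst = 0.1,
                         missFrac = 0.5, seed = 7) {
  set.seed(seed)
  p0 <- runif(nLoci, 0.05, 0.95)
  sh <- (1 - fst) / fst
  f1 <- rbeta(nLoci, p0 * sh, (1 - p0) * sh)
  f2 <- rbeta(nLoci, p0 * sh, (1 - p0) * sh)
  ref <- rbind(matrix(rbinom(nRef / 2 * nLoci, 1, rep(f1, each = nRef / 2)), nRef / 2),
               matrix(rbinom(nRef / 2 * nLoci, 1, rep(f2, each = nRef / 2)), nRef / 2))
  truth <- rep(c("popA", "popB"), each = nAdm / 2)
  adm <- rbind(matrix(rbinom(nAdm / 2 * nLoci, 1, rep(f1, each = nAdm / 2)), nAdm / 2),
               matrix(rbinom(nAdm / 2 * nLoci, 1, rep(f2, each = nAdm / 2)), nAdm / 2))
  adm[matrix(runif(length(adm)) < missFrac, nrow(adm))] <- NA
  loci <- data.frame(chrom = "chr1", cM = seq(0.1, 100, length.out = nLoci))
  masked <- new("MaskedHaplotypes", alleles = adm * 1.0, chrom = loci$chrom,
                cM = loci$cM, labels = rep("admixed", nAdm),
                isReference = rep(FALSE, nAdm))
  list(masked = masked, ref = ref, loci = loci,
       refLabels = rep(c("popA", "popB"), each = nRef / 2), truth = truth)
}

test_that("matrix assembly joins shared loci and keeps reference-only loci", {
  b <- aspcaBenchFx(nRef = 10, nAdm = 6, nLoci = 1000, seed = 1)
  joint <- assembleASPCAMatrix(b$masked, b$ref, b$loci, b$refLabels)
  expect_equal(dim(joint@alleles), c(16L, 1000L))
  expect_equal(sum(joint@isReference), 10)
  # a locus masked in every admixed row survives via the reference panel
  b2 <- aspcaBenchFx(nRef = 10, nAdm = 6, nLoci = 500, seed = 2)
  b2$masked@alleles[, 3] <- NA
  joint2 <- assembleASPCAMatrix(b2$masked, b2$ref, b2$loci, b2$refLabels)
  expect_equal(ncol(joint2@alleles), 500)
  expect_false(anyNA(joint2@alleles[joint2@isReference, 3]))
  # disjoint loci fail loudly
  b3 <- aspcaBenchFx(nRef = 10, nAdm = 6, nLoci = 100, seed = 3)
  off <- b3$loci; off$cM <- off$cM + 1000
  expect_error(assembleASPCAMatrix(b3$masked, b3$ref, off, b3$refLabels),
               "intersection 0")
})

test_that("subspace PCA with no missing data reduces to standard PCA", {
  set.seed(11)
  X <- matrix(rbinom(40 * 500, 1, 0.4), 40, 500)
  mh <- new("MaskedHaplotypes", alleles = X * 1.0, chrom = rep("chr1", 500),
            cM = seq_len(500) / 10, labels = rep("p", 40),
            isReference = rep(FALSE, 40))
  r <- subspacePCA(mh, k = 3)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    s <- sign(sum(r@scores[, j] * pc$x[, j]))
    expect_lt(max(abs(r@scores[, j] - s * pc$x[, j])), 1e-8)
  }
  expect_true(r@converged)
  expect_equal(r@iterations, 0L)
})

test_that("row order does not change subspace PCA coordinates", {
  b <- aspcaBenchFx(nRef = 16, nAdm = 16, nLoci = 800, seed = 5)
  joint <- assembleASPCAMatrix(b$masked, b$ref, b$loci, b$refLabels)
  r1 <- suppressWarnings(subspacePCA(joint, k = 2, seed = 3))
  perm <- sample(nrow(joint@alleles))
  jp <- joint
  jp@alleles <- jp@alleles[perm, , drop = FALSE]
  jp@labels <- jp@labels[perm]
  jp@isReference <- jp@isReference[perm]
  r2 <- suppressWarnings(subspacePCA(jp, k = 2, seed = 3))
  for (j in 1:2) {
    a <- r1@scores[perm, j]; bb <- r2@scores[, j]
    s <- sign(sum(a * bb))
    expect_lt(max(abs(a - s * bb)), 1e-4)
  }
})

test_that("masked haplotypes are assigned to their source population in ASPCA space", {
  b <- aspcaBenchFx(nRef = 40, nAdm = 40, nLoci = 4000, fst = 0.1,
                    missFrac = 0.5, seed = 9)
  joint <- assembleASPCAMatrix(b$masked, b$ref, b$loci, b$refLabels)
  r <- suppressWarnings(subspacePCA(joint, k = 2))
  sc <- r@scores
  isref <- r@isReference
  cenA <- colMeans(sc[isref & r@labels == "popA", ])
  cenB <- colMeans(sc[isref & r@labels == "popB", ])
  adm <- sc[!isref, , drop = FALSE]
  dA <- sqrt(rowSums(sweep(adm, 2, cenA)^2))
  dB <- sqrt(rowSums(sweep(adm, 2, cenB)^2))
  called <- ifelse(dA < dB, "popA", "popB")
  expect_gte(mean(called == b$truth), 0.9)
  # reference clusters separate (positive silhouette-like margin)
  refA <- sc[isref & r@labels == "popA", ]
  refB <- sc[isref & r@labels == "popB", ]
  within <- mean(dist(refA)) + mean(dist(refB))
  between <- sqrt(sum((cenA - cenB)^2))
  expect_gt(between, 0)
})

test_that("held-out entries are reconstructed increasingly well over iterations", {
  set.seed(13)
  n <- 40; p <- 600; k <- 2
  U <- matrix(rnorm(n * k), n); V <- matrix(rnorm(p * k), p)
  X <- U %*% t(V) + matrix(rnorm(n * p, sd = 0.3), n)
  miss <- matrix(runif(n * p) < 0.3, n)
  Xm <- X; Xm[miss] <- NA
  mh <- new("MaskedHaplotypes", alleles = Xm, chrom = rep("chr1", p),
            cM = seq_len(p), labels = rep("x", n), isReference = rep(FALSE, n))
  Xc_true <- sweep(X, 2, colMeans(X))
  errs <- vapply(c(1, 3, 10), function(it) {
    r <- suppressWarnings(subspacePCA(mh, k = k, maxIter = it, tol = 0))
    rec <- r@scores %*% t(r@loadings)
    sqrt(mean((rec[miss] - Xc_true[miss])^2))
  }, 0)
  expect_lte(errs[3], errs[1] + 1e-8)
})

test_that("degenerate rows and dimensions are rejected or logged", {
  b <- aspcaBenchFx(nRef = 10, nAdm = 6, nLoci = 300, seed = 15)
  b$masked@alleles[2, ] <- NA
  joint <- assembleASPCAMatrix(b$masked, b$ref, b$loci, b$refLabels)
  r <- subspacePCA(joint, k = 2)
  expect_equal(nrow(r@scores), 15)       # all-missing row dropped
  expect_equal(nrow(r@exclusions), 1)
  expect_error(subspacePCA(joint, k = 400), "smaller")
})

test_that("the pipeline applies the ancestry and contamination filters", {
  chroms <- chromosomeSet(c(chr1 = 100))
  nLoci <- 600
  loci <- data.frame(chrom = "chr1", cM = seq(0.1, 99.9, length.out = nLoci))
  # 4 admixed haplotypes with known NAT fractions 1.0, 0.6, 0.2, 0.0
  fracs <- c(1.0, 0.6, 0.2, 0.0)
  calls_df <- do.call(rbind, lapply(1:4, function(h) {
    f <- fracs[h]
    if (f %in% c(0, 1)) {
      data.frame(hap = h, chrom = "chr1", start = 0, end = 100,
                 ancestry = if (f == 1) "NAT" else "EUR", posterior = 1)
    } else {
      data.frame(hap = h, chrom = "chr1", start = c(0, 100 * f),
                 end = c(100 * f, 100), ancestry = c("NAT", "EUR"),
                 posterior = 1)
    }
  }))
  calls <- callsFx(calls_df)
  set.seed(3)
  haps <- matrix(rbinom(4 * nLoci, 1, 0.5), 4, nLoci)
  ref <- matrix(rbinom(12 * nLoci, 1, 0.5), 12, nLoci)
  refProps <- data.frame(unit = 1:12, EUR = c(rep(0, 11), 0.3),
                         NAT = c(rep(1, 11), 0.7))
  res <- aspcaPipeline(haps, loci, calls, ref, loci,
                       rep(c("and", "cen"), 6), target = "NAT",
                       chroms = chroms, referenceProportions = refProps, k = 2,
                       tol = 1e-5)
  # haplotypes 3 (20% NAT) and 4 (0%) excluded; contaminated reference excluded
  expect_equal(nrow(res@scores), 2 + 11)
  expect_true(any(grepl("NAT < 0.25", res@exclusions$rule)))
  expect_true(any(grepl("EUR > 0.1", res@exclusions$rule)))
})
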