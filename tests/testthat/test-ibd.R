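# noiseless random haplotypes at a fixed marker density, with planted sharing
ibdFixtureFx <- function(nHap = 8, markersPerCM = 20, lenCM = 60, seed = 3) {
  set.seed(seed)
  nm <- markersPerCM * lenCM
  X <- matrix(rbinom(nHap * nm, 1, runif(nm, 0.2, 0.8)), nHap, nm, byrow = FALSE)
  map <- data.frame(chrom = "chr1", cM = seq(0, lenCM, length.out = nm))
  list(X = X, map = map)
}

plantFx <- function(f, a, b, startCM, endCM) {
  sel <- f$map$cM >= startCM & f$map$cM < endCM
  f$X[b, sel] <- f$X[a, sel]
  f
}

test_that("identical haplotypes share one segment covering the chromosome", {
  f <- ibdFixtureFx(nHap = 3, lenCM = 50, seed = 1)
  f$X[2, ] <- f$X[1, ]
  segs <- findIBDHaploid(f$X, f$map, sliceMarkers = 128, minCM = 3)
  s12 <- segs[segs$hapA == 1 & segs$hapB == 2, ]
  expect_equal(nrow(s12), 1)
  expect_lt(s12$start, 1e-9)
  expect_gt(s12$end, 49.9)
})

test_that("planted segments are recovered with slice-level endpoint accuracy", {
  f <- ibdFixtureFx(nHap = 10, lenCM = 60, seed = 2)
  f <- plantFx(f, 2, 7, 20, 25)     # 5 cM
  slice_cm <- 32 / 20               # slice span in cM
  segs <- findIBDHaploid(f$X, f$map, sliceMarkers = 32, minCM = 3)
  hit <- segs[segs$hapA == 2 & segs$hapB == 7, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$start - 20), slice_cm)
  expect_lt(abs(hit$end - 25), slice_cm)
  # no false segments between unrelated haplotypes
  expect_equal(nrow(segs[!(segs$hapA == 2 & segs$hapB == 7), ]), 0)
})

test_that("segments below the 3 cM floor are not reported", {
  f <- ibdFixtureFx(nHap = 6, lenCM = 60, seed = 4)
  f <- plantFx(f, 1, 5, 30, 32)     # 2 cM
  segs <- findIBDHaploid(f$X, f$map, sliceMarkers = 16, minCM = 3)
  expect_equal(nrow(segs), 0)
  segs2 <- findIBDHaploid(f$X, f$map, sliceMarkers = 16, minCM = 1.5)
  expect_gt(nrow(segs2), 0)
  expect_true(all(segs2$length >= 1.5))
})

test_that("a switched slice interrupts a haploid match", {
  f <- ibdFixtureFx(nHap = 4, lenCM = 60, seed = 5)
  f$X[2, ] <- f$X[1, ]
  # corrupt a 32-marker block in the middle (flip all its alleles)
  mid <- 600:631
  f$X[2, mid] <- 1 - f$X[2, mid]
  segs <- findIBDHaploid(f$X, f$map, sliceMarkers = 32, minCM = 3)
  s12 <- segs[segs$hapA == 1 & segs$hapB == 2, ]
  expect_equal(nrow(s12), 2)        # split into two matches
  expect_true(all(s12$length >= 3))
})

test_that("round trip through the match-file format and unit conversion", {
  td <- withr::local_tempdir()
  f <- ibdFixtureFx(nHap = 6, lenCM = 60, seed = 6)
  f <- plantFx(f, 1, 4, 10, 22)
  segs <- findIBDHaploid(f$X, f$map, sliceMarkers = 32, minCM = 3)
  p <- file.path(td, "x.match")
  writeGermlineMatch(segs, p)
  map_bp <- data.frame(chrom = "chr1", bp = f$map$cM * 1e6, cM = f$map$cM)
  back <- readGermlineMatch(p)
  expect_equal(nrow(back), nrow(segs))
  expect_equal(back$length, segs$length, tolerance = 1e-6)
  # MB-unit record converted through the genetic map
  writeLines(paste("F", "1", "F", "2", "chr1", 5e6, 9e6, ".", ".", "80",
                   "4.0", "MB", "0", "0", "0", sep = "\t"), p)
  conv <- readGermlineMatch(p, map_bp)
  expect_true(conv$converted)
  expect_equal(conv$start, 5, tolerance = 1e-6)
  expect_equal(conv$length, 4, tolerance = 1e-6)
  empty <- file.path(td, "empty.match")
  file.create(empty)
  expect_equal(nrow(readGermlineMatch(empty)), 0)
})

test_that("segment ancestry profiles average the two haplotypes", {
  calls <- callsFx(hap = rep(1:2, each = 2), chrom = "chr1",
                   start = c(0, 50, 0, 50), end = c(50, 100, 50, 100),
                   ancestry = c("EUR", "NAT", "EUR", "NAT"), posterior = 1)
  seg <- data.frame(hapA = 1, hapB = 2, chrom = "chr1", start = 10, end = 30)
  pr <- segmentAncestryProfile(seg, calls)
  expect_equal(pr$EUR, 1); expect_equal(pr$NAT, 0)
  expect_false(pr$discordant)
  seg2 <- data.frame(hapA = 1, hapB = 2, chrom = "chr1", start = 25, end = 75)
  pr2 <- segmentAncestryProfile(seg2, calls)
  expect_equal(pr2$EUR, 0.5); expect_equal(pr2$NAT, 0.5)
  expect_false(pr2$discordant)
  # haplotype A all EUR, B all NAT over the segment: averaged + flagged
  calls3 <- callsFx(hap = rep(1:2, each = 1), chrom = "chr1",
                    start = c(0, 0), end = c(100, 100),
                    ancestry = c("EUR", "NAT"), posterior = 1)
  pr3 <- segmentAncestryProfile(seg, calls3)
  expect_equal(pr3$EUR, 0.5); expect_equal(pr3$NAT, 0.5)
  expect_true(pr3$discordant)
  expect_error(segmentAncestryProfile(
    data.frame(hapA = 1, hapB = 9, chrom = "chr1", start = 0, end = 10), calls),
    "no ancestry calls")
})

test_that("sharing matrix normalizes by pair counts", {
  labels <- c("1" = "A", "2" = "A", "3" = "B", "4" = "B", "5" = "B")
  segs <- data.frame(hapA = c(1, 1, 2), hapB = c(3, 4, 5),
                     chrom = "chr1", length = c(10, 12, 8))
  sm <- sharingMatrix(segs, labels)
  expect_equal(sm@normalized["A", "B"], 30 / 6)
  expect_equal(sm@normalized["B", "A"], 30 / 6)
  # within-population: n (n - 1) / 2 unordered pairs
  segs2 <- data.frame(hapA = 1, hapB = 2, chrom = "chr1", length = 10)
  sm2 <- sharingMatrix(segs2, labels["1" == names(labels) | names(labels) == "2"])
  expect_equal(sm2@normalized["A", "A"], 10 / 1)
  # empty segment set gives all-zero sharing
  none <- sharingMatrix(segs[0, ], labels)
  expect_true(all(none@normalized == 0))
  expect_error(sharingMatrix(data.frame(hapA = 9, hapB = 1, chrom = "chr1",
                                        length = 5), labels), "unlabeled")
  # invariance to relabeling haplotypes within a population
  segs3 <- segs; segs3$hapA <- c(2, 2, 1); segs3$hapB <- c(4, 3, 5)
  expect_equal(sharingMatrix(segs3, labels)@normalized, sm@normalized)
})

test_that("chromosome-weighted jackknife matches a hand-worked example", {
  chroms <- chromosomeSet(c(chr1 = 100, chr2 = 50))
  labels <- c("1" = "A", "2" = "B")
  segs <- data.frame(hapA = 1, hapB = 2, chrom = c("chr1", "chr1", "chr2"),
                     length = c(6, 4, 2))
  sm <- jackknifeSE(segs, chroms, labels)
  # hand computation, delete-m weighted jackknife with m_j = (100, 50):
  # theta = 12, theta_(1) = 2, theta_(2) = 10, M = 150
  # h = (1.5, 3); theta_J = 2*12 - (1/3)*2 - (2/3)*10 = 16.666667
  # tau_1 = 1.5*12 - 0.5*2  = 17;  tau_2 = 3*12 - 2*10 = 16
  # var = (1/2) [ (17 - 50/3)^2 / 0.5 + (16 - 50/3)^2 / 2 ] = 0.222222
  expect_equal(sm@normalized["A", "B"], 12)
  expect_equal(sm@se["A", "B"], sqrt(2/9), tolerance = 1e-9)
  # identical per-chromosome rates across equal-length chromosomes -> SE 0
  chroms_eq <- chromosomeSet(c(chr1 = 100, chr2 = 100))
  segs_eq <- data.frame(hapA = 1, hapB = 2, chrom = c("chr1", "chr2"),
                        length = c(5, 5))
  sm_eq <- jackknifeSE(segs_eq, chroms_eq, labels)
  expect_equal(sm_eq@se["A", "B"], 0, tolerance = 1e-12)
  expect_error(jackknifeSE(segs, chromosomeSet(c(chr1 = 100)), labels),
               "at least two")
})

test_that("length-ancestry regression matches the closed-form normal equations", {
  segs <- data.frame(length = c(5, 10, 15, 20), EUR = 0.01 * c(5, 10, 15, 20))
  r <- suppressWarnings(lengthAncestryRegression(segs))
  expect_equal(r$slope, 0.01, tolerance = 1e-12)
  expect_lt(r$pValue, 1e-10)
  segs2 <- data.frame(length = c(5, 10, 15, 20), EUR = rep(0.4, 4))
  expect_equal(suppressWarnings(lengthAncestryRegression(segs2))$slope, 0)
  set.seed(8)
  x <- runif(30, 3, 25); y <- 0.2 + 0.01 * x + rnorm(30, sd = 0.05)
  seg3 <- data.frame(length = x, EUR = pmin(pmax(y, 0), 1),
                     kind = rep(c("within", "between"), 15))
  r3 <- lengthAncestryRegression(seg3, by = "kind")
  expect_equal(nrow(r3), 2)
  for (g in c("within", "between")) {
    sel <- seg3$kind == g
    bx <- cov(seg3$length[sel], seg3$EUR[sel]) / var(seg3$length[sel])
    expect_equal(r3$slope[r3$group == g], bx, tolerance = 1e-10)
  }
  expect_error(lengthAncestryRegression(seg3[1:2, ]), "at least 3")
  expect_error(lengthAncestryRegression(
    data.frame(length = rep(2, 5), EUR = runif(5))), "variance")
})

test_that("planted segments in a painted cohort are recovered end to end", {
  coh <- paintedCohortFx(nInd = 8, nLoci = 2000, fst = 0.15, seed = 40)
  coh <- plantIBDSegment(coh, 2, 11, "chr1", 40, 46)
  map <- data.frame(chrom = coh@loci$chrom, cM = coh@loci$cM)
  segs <- findIBDHaploid(alleles(coh), map, sliceMarkers = 32, minCM = 3)
  hit <- segs[segs$hapA == 2 & segs$hapB == 11, ]
  expect_equal(nrow(hit), 1)
  expect_lt(abs(hit$start - 40), 32 / 20)
  expect_lt(abs(hit$end - 46), 32 / 20)
  expect_true(all(segs$length >= 3))
  prof <- segmentAncestryProfile(hit, tractsToCalls(tracts(coh)))
  anc_cols <- intersect(c("EUR", "NAT", "AFR"), names(prof))
  expect_equal(sum(unlist(prof[1, anc_cols])), 1, tolerance = 1e-9)
})
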