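test_that("single-source founding yields whole-chromosome tracts", {
  m <- matrix(0, 2, 2, dimnames = list(NULL, c("EUR", "NAT")))
  m[2, "EUR"] <- 1
  coh <- simulateCohort(migrationSchedule(m), chromosomeSet(c(chr1 = 100)),
                        10, seed = 1)
  tr <- tracts(coh)
  expect_equal(nrow(tr), 20)
  expect_true(all(tr$ancestry == "EUR"))
  expect_equal(tr$start, rep(0, 20))
  expect_equal(tr$end, rep(100, 20))
})

test_that("symmetric founding gives half-and-half genome fractions", {
  m <- matrix(0, 2, 2, dimnames = list(NULL, c("EUR", "NAT")))
  m[2, ] <- c(0.5, 0.5)
  coh <- simulateCohort(migrationSchedule(m), chromosomeSet(c(chr1 = 100)),
                        1000, seed = 2)
  tr <- tracts(coh)
  frac <- sum(tr$end[tr$ancestry == "EUR"] - tr$start[tr$ancestry == "EUR"]) /
    sum(tr$end - tr$start)
  # founders are diploid, so haplotype fractions are 0/1 with mean 1/2;
  # 3 Monte-Carlo SE on 2000 correlated haplotypes (1000 founders effective)
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(1000))
})

test_that("tracts tile every haplotype exactly and simulation is seed-deterministic", {
  coh <- smallCohortFx(nInd = 30, seed = 11)
  tr <- tracts(coh)
  tot <- tapply(tr$end - tr$start, list(tr$hap, tr$chrom), sum)
  expect_equal(unname(tot[, "chr1"]), rep(100, 60))
  expect_equal(unname(tot[, "chr2"]), rep(80, 60))
  expect_false(is.unsorted(tr$start[tr$hap == 1 & tr$chrom == "chr1"]))
  coh2 <- smallCohortFx(nInd = 30, seed = 11)
  expect_identical(tracts(coh2), tr)
  coh3 <- smallCohortFx(nInd = 30, seed = 12)
  expect_false(identical(tracts(coh3), tr))
})

test_that("ancestry switch points increase with founding depth", {
  chroms <- chromosomeSet(c(chr1 = 150))
  nsw <- vapply(c(2, 6, 12), function(T0) {
    m <- matrix(0, T0, 2, dimnames = list(NULL, c("EUR", "NAT")))
    m[T0, ] <- c(0.5, 0.5)
    coh <- simulateCohort(migrationSchedule(m), chroms, 150, seed = T0)
    nrow(tracts(coh))
  }, 0)
  expect_true(all(diff(nsw) > 0))
})

test_that("mean ancestry fractions match schedule proportions within Monte-Carlo error", {
  sched <- baseSchedFx()
  coh <- simulateCohort(sched, chromosomeSet(rep(150, 4)), 500, seed = 9)
  pr <- ancestryProportions(tracts(coh), coh@chroms, "haplotype")
  pm <- colMeans(pr[, names(basePropsFx)])
  se <- apply(pr[, names(basePropsFx)], 2, sd) / sqrt(nrow(pr))
  # the shared pedigree adds genome-wide drift on top of haplotype sampling
  drift <- sqrt(basePropsFx * (1 - basePropsFx) * 12 / (2 * 5000))
  expect_true(all(abs(pm - basePropsFx) < 3 * sqrt(se^2 + drift^2)))
})

test_that("Balding-Nichols frequencies behave in the low- and finite-drift regimes", {
  chroms <- chromosomeSet(c(chr1 = 100))
  fr0 <- drawAncestralFrequencies(3000, 2, 1e-6, chroms, seed = 3)
  expect_lt(mean(abs(fr0@freq[, 1] - fr0@freq[, 2])), 0.01)
  expect_false(is.unsorted(fr0@cM))

  # Hudson-style FST between two painted pure populations recovers the drift
  fr <- drawAncestralFrequencies(10000, 2, 0.1, chroms, seed = 4)
  n <- 300
  p1 <- colMeans(matrix(rbinom(n * 10000, 1, rep(fr@freq[, 1], each = n)), n))
  p2 <- colMeans(matrix(rbinom(n * 10000, 1, rep(fr@freq[, 2], each = n)), n))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n - 1) - p2 * (1 - p2) / (n - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_hat <- sum(num) / sum(den)
  expect_lt(abs(fst_hat - 0.1), 0.02)

  fr_empty <- drawAncestralFrequencies(0, 3, 0.1, chroms, seed = 5)
  expect_equal(nrow(fr_empty@freq), 0)
  expect_s4_class(fr_empty, "AncestralFrequencies")
  expect_error(drawAncestralFrequencies(10, 2, 0, chroms, seed = 1), "fst")
})

test_that("painting draws alleles from the tract's source frequencies", {
  chroms <- chromosomeSet(c(chr1 = 100))
  m <- matrix(0, 2, 2, dimnames = list(NULL, c("EUR", "NAT")))
  m[2, "EUR"] <- 1
  coh <- simulateCohort(migrationSchedule(m), chroms, 5, seed = 6)
  fr <- drawAncestralFrequencies(5000, 2, 0.2, chroms, seed = 7,
                                 populations = c("EUR", "NAT"))
  # force extreme frequencies to get deterministic loci
  fr@freq[1:100, "EUR"] <- 1 - 1e-12
  fr@freq[101:5000, "EUR"] <- 0.3
  coh <- paintHaplotypes(coh, fr, seed = 8)
  al <- alleles(coh)
  expect_true(all(al[, 1:100] == 1))
  f <- mean(al[, 101:5000])
  expect_lt(abs(f - 0.3), 3 * sqrt(0.3 * 0.7 / (10 * 4900)))
})

test_that("two-ancestry haplotypes have per-tract allele frequencies from each source", {
  coh <- paintedCohortFx(nInd = 40, nLoci = 6000, fst = 0.45, seed = 21)
  al <- alleles(coh)
  tr <- tracts(coh)
  fr_pos <- coh@loci$cM
  # stratify loci by true local ancestry of haplotype 1
  tr1 <- tr[tr$hap == 1 & tr$chrom == "chr1", ]
  anc_at <- tr1$ancestry[findInterval(fr_pos, tr1$start)]
  for (a in intersect(c("EUR", "NAT"), unique(anc_at))) {
    sel <- which(anc_at == a)
    if (length(sel) < 300) next
    # mean allele value should track this source's mean frequency
    fr <- drawAncestralFrequencies(6000, 3, 0.45, chromosomeSet(c(chr1 = 100)),
                                   seed = 22, populations = c("EUR", "NAT", "AFR"))
    expect_lt(abs(mean(al[1, sel]) - mean(fr@freq[sel, a])), 0.1)
  }
})

test_that("planted IBD segments copy alleles and reject overlaps", {
  coh <- paintedCohortFx(nInd = 5, nLoci = 1000, seed = 30)
  coh <- plantIBDSegment(coh, 1, 4, "chr1", 10, 15)
  sel <- coh@loci$cM >= 10 & coh@loci$cM < 15
  expect_equal(alleles(coh)[4, sel], alleles(coh)[1, sel])
  expect_equal(nrow(coh@plantedIBD), 1)
  expect_error(plantIBDSegment(coh, 1, 4, "chr1", 12, 20), "overlap")
  expect_error(plantIBDSegment(coh, 2, 3, "chr1", 15, 15), "greater than start")
  expect_error(plantIBDSegment(coh, 2, 3, "chr1", 95, 120), "outside")
})

test_that("cohort writers produce readable tract, VCF and truth files", {
  td <- withr::local_tempdir()
  coh <- paintedCohortFx(nInd = 4, nLoci = 200, seed = 31)
  coh <- plantIBDSegment(coh, 1, 3, "chr1", 20, 30)
  paths <- writeCohortTruth(coh, td)
  tr2 <- readTractsBed(paths[["tracts"]])
  expect_equal(nrow(tr2), nrow(tracts(coh)))
  expect_equal(sum(tr2$end - tr2$start), sum(tracts(coh)$end - tracts(coh)$start))
  vcf <- file.path(td, "cohort.vcf")
  writeCohortVCF(coh, vcf, file.path(td, "cohort.map"))
  lines <- readLines(vcf)
  expect_true(any(grepl("^#CHROM", lines)))
  body <- read.table(vcf, sep = "\t")
  expect_equal(nrow(body), 200)
  gt <- do.call(rbind, strsplit(as.character(body[[10]]), "|", fixed = TRUE))
  expect_equal(as.integer(gt[, 1]), unname(alleles(coh)[1, ]))
  expect_equal(as.integer(gt[, 2]), unname(alleles(coh)[2, ]))
})
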