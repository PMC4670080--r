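test_that("tract BED round trip preserves the tract set", {
  td <- withr::local_tempdir()
  coh <- smallCohortFx(nInd = 10, seed = 3)
  p <- file.path(td, "t.bed")
  writeTractsBed(coh, p)
  tr <- readTractsBed(p, ancestries = c("EUR", "NAT", "AFR"))
  orig <- tracts(coh)
  o1 <- orig[order(orig$hap, orig$chrom, orig$start), ]
  expect_equal(tr$start, o1$start)
  expect_equal(tr$end, o1$end)
  expect_equal(tr$ancestry, o1$ancestry)
})

test_that("malformed tract files are rejected with informative errors", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.bed")
  writeLines(c("haplotype_id\tchrom\tstart_cM\tend_cM\tancestry\tposterior",
               "1\tchr1\t5\t5\tEUR\t1"), p)
  expect_error(readTractsBed(p), "end <= start")
  writeLines(c("haplotype_id\tchrom\tstart_cM\tend_cM\tancestry\tposterior",
               "1\tchr1\t0\t10\tMARS\t1"), p)
  expect_error(readTractsBed(p, ancestries = c("EUR", "NAT")), "allowed")
  writeLines(c("haplotype_id\tchrom\tstart_cM\tend_cM\tancestry\tposterior",
               "1\tchr1\t0\t10\tEUR\t1", "1\tchr1\t5\t15\tEUR\t1"), p)
  expect_error(readTractsBed(p), "overlap")
  file.create(file.path(td, "empty.bed"))
  expect_equal(nrow(readTractsBed(file.path(td, "empty.bed"))), 0)
})

test_that("RFMix msp windows parse with declared ancestry codes", {
  td <- withr::local_tempdir()
  p <- file.path(td, "x.msp.tsv")
  writeLines(c("#Subpopulation order/codes: EUR=0\tNAT=1\tAFR=2",
               "#chm\tspos\tepos\tsgpos\tegpos\tn snps\th1\th2\th3\th4",
               "1\t1\t500000\t0\t50\t100\t1\t1\t1\t1",
               "1\t500000\t900000\t50\t90\t80\t0\t1\t0\t1"), p)
  calls <- readRFMixCalls(p)
  cl <- calls@calls
  expect_equal(sort(unique(cl$hap)), 1:4)
  h1 <- cl[cl$hap == 1, ]
  expect_equal(h1$ancestry, c("NAT", "EUR"))
  expect_equal(h1$start, c(0, 50))
  expect_equal(h1$end, c(50, 90))
  # haplotype 2 is NAT across both windows -> merged into one
  expect_equal(nrow(cl[cl$hap == 2, ]), 1)
  expect_equal(cl$end[cl$hap == 2], 90)
})

test_that("legacy per-marker Viterbi input collapses to constant-call windows", {
  td <- withr::local_tempdir()
  p <- file.path(td, "vit.txt")
  # 6 markers, 2 haplotypes; hap1 alternates every 2 markers
  write.table(cbind(c(1, 1, 2, 2, 1, 1), c(1, 1, 1, 1, 1, 1)), p,
              row.names = FALSE, col.names = FALSE)
  map <- data.frame(chrom = "chr1", cM = c(1, 2, 3, 4, 5, 6))
  calls <- readRFMixCalls(p, map = map, ancestries = c("EUR", "NAT"))
  cl <- calls@calls
  expect_equal(nrow(cl[cl$hap == 1, ]), 3)
  expect_equal(nrow(cl[cl$hap == 2, ]), 1)
  expect_error(readRFMixCalls(p, map = map[1:3, ], ancestries = c("EUR", "NAT")),
               "match")
  # odd haplotype count
  p2 <- file.path(td, "vit2.txt")
  write.table(cbind(c(1, 1, 1, 1, 1, 1)), p2, row.names = FALSE, col.names = FALSE)
  expect_error(readRFMixCalls(p2, map = map, ancestries = c("EUR")), "odd")
})

test_that("calls merge into maximal tracts with minimum-posterior rule", {
  calls <- callsFx(hap = 1, chrom = "chr1",
                   start = seq(0, 1.8, 0.2), end = seq(0.2, 2.0, 0.2),
                   ancestry = "NAT", posterior = 1)
  tr <- callsToTracts(calls)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$end - tr$start, 2.0)

  calls2 <- callsFx(hap = 1, chrom = "chr1", start = c(0, 1, 2), end = c(1, 2, 3),
                    ancestry = c("EUR", "NAT", "EUR"), posterior = 1)
  expect_equal(nrow(callsToTracts(calls2)), 3)

  calls3 <- callsFx(hap = 1, chrom = "chr1", start = c(0, 1, 2), end = c(1, 2, 3),
                    ancestry = "NAT", posterior = c(0.99, 0.90, 0.99))
  tr3 <- callsToTracts(calls3)
  expect_equal(tr3$posterior, 0.90)

  # sub-window gaps are treated as contiguous, larger gaps split
  calls4 <- callsFx(hap = 1, chrom = "chr1", start = c(0, 1.05, 5), end = c(1, 2, 6),
                    ancestry = "NAT", posterior = 1)
  expect_equal(nrow(callsToTracts(calls4)), 2)
  expect_equal(nrow(callsToTracts(callsFx(hap = integer(), chrom = character(),
                                          start = numeric(), end = numeric(),
                                          ancestry = character(),
                                          posterior = numeric()))), 0)
})

test_that("ancestry proportions are tract-length fractions summing to one", {
  chroms <- chromosomeSet(c(chr1 = 100))
  tr <- data.frame(hap = c(1, 1, 2), chrom = "chr1",
                   start = c(0, 60, 0), end = c(60, 100, 100),
                   ancestry = c("EUR", "NAT", "EUR"), posterior = 1)
  pr <- ancestryProportions(tr, chroms, "haplotype")
  expect_equal(pr$EUR, c(0.6, 1.0))
  expect_equal(pr$NAT, c(0.4, 0.0))
  pri <- ancestryProportions(tr, chroms, "individual")
  expect_equal(pri$EUR, 0.8)   # mean of the two haplotypes
  expect_equal(rowSums(pri[, c("EUR", "NAT")]), 1)
  bad <- tr[-2, ]
  expect_error(ancestryProportions(bad, chroms), "tile")
})

test_that("masking keeps only confident target-ancestry loci", {
  loci <- data.frame(chrom = "chr1", cM = c(5, 15, 25))
  haps <- matrix(c(1, 0, 1), nrow = 1)
  calls <- callsFx(hap = 1, chrom = "chr1", start = c(0, 10, 20),
                   end = c(10, 20, 30),
                   ancestry = c("NAT", "NAT", "EUR"),
                   posterior = c(0.96, 0.90, 1.0))
  mh <- maskHaplotypes(haps, loci, calls, target = "NAT")
  expect_equal(unname(mh@alleles[1, ]), c(1, NA, NA))
  # masking never flips an observed value
  expect_equal(mh@alleles[1, 1], haps[1, 1])
  expect_error(maskHaplotypes(haps, data.frame(chrom = "chr1", cM = 50),
                              calls, "NAT"), "not covered")
})

test_that("cohort filters reproduce the strict threshold rules", {
  pr <- data.frame(unit = 1:4,
                   EUR = c(0.50, 0.11, 0.96, 0.70),
                   NAT = c(0.24, 0.85, 0.03, 0.25),
                   AFR = c(0.26, 0.04, 0.01, 0.05))
  f <- cohortFilters()
  r1 <- applyCohortFilters(pr, f, "aspca_admixed", target = "NAT")
  expect_equal(r1$retained, c(2, 4))           # NAT 0.24 excluded, 0.25 kept
  expect_true(1 %in% r1$exclusions$unit)
  r2 <- applyCohortFilters(pr, f, "aspca_reference")
  expect_true(2 %in% r2$exclusions$unit)       # EUR 0.11 > 0.10 -> excluded
  expect_true(all(r2$exclusions$value > 0.10))
  expect_true(all(pr$EUR[pr$unit %in% r2$retained] <= 0.10))
  r3 <- applyCohortFilters(pr, f, "tracts")
  expect_false(3 %in% r3$retained)             # 0.96 > 0.95 excluded
  expect_true(all(c(1, 2, 4) %in% r3$retained))
  # degenerate thresholds: keep-all / drop-all
  keepall <- applyCohortFilters(pr, cohortFilters(0, 1, 1, 1), "aspca_admixed",
                                target = "NAT")
  expect_equal(keepall$retained, pr$unit)
  dropall <- applyCohortFilters(pr, cohortFilters(1.0, 1, 1, 1), "aspca_admixed",
                                target = "NAT")
  expect_equal(length(dropall$retained), 0)
  expect_error(applyCohortFilters(pr[, 1:3], f, "tracts"), "sum to 1")
})

test_that("spectrum binning uses half-open bins and a whole-chromosome category", {
  chroms <- chromosomeSet(c(chr1 = 50))
  tr <- data.frame(hap = 1, chrom = "chr1", start = c(0, 10),
                   end = c(5, 20), ancestry = "EUR", posterior = 1)
  sp <- tractLengthSpectrum(tr, chroms, edges = c(0, 10, 20, Inf),
                            nHaplotypes = 1)
  expect_equal(unname(spectrumCounts(sp)["EUR", ]), c(1, 1, 0))
  # length exactly at an edge goes to the upper bin
  tr2 <- data.frame(hap = 1, chrom = "chr1", start = 0, end = 10,
                    ancestry = "EUR", posterior = 1)
  sp2 <- tractLengthSpectrum(tr2, chroms, edges = c(0, 10, 20, Inf))
  expect_equal(unname(spectrumCounts(sp2)["EUR", ]), c(0, 1, 0))
  # full-chromosome tract counted separately, total conserved
  tr3 <- data.frame(hap = 1:2, chrom = "chr1", start = 0, end = 50,
                    ancestry = "EUR", posterior = 1)
  sp3 <- tractLengthSpectrum(tr3, chroms, edges = c(0, 10, 20, Inf))
  expect_equal(sum(spectrumCounts(sp3)), 0)
  expect_equal(unname(fullChromCounts(sp3)["EUR", "chr1"]), 2)
  coh <- smallCohortFx(nInd = 15, seed = 8)
  sp4 <- tractLengthSpectrum(tracts(coh), coh@chroms,
                             edges = c(0, seq(1, 99, 2), Inf))
  expect_equal(sum(spectrumCounts(sp4)) + sum(fullChromCounts(sp4)),
               nrow(tracts(coh)))
  expect_error(tractLengthSpectrum(tracts(coh), coh@chroms, edges = c(5, 5, 10)),
               "strictly increasing")
})

test_that("synthetic calls from truth tracts round-trip through callsToTracts", {
  coh <- smallCohortFx(nInd = 8, seed = 13)
  tr <- tracts(coh)
  back <- callsToTracts(tractsToCalls(tr))
  o <- tr[order(tr$hap, tr$chrom, tr$start), ]
  expect_equal(back$start, o$start)
  expect_equal(back$end, o$end)
  expect_equal(back$ancestry, o$ancestry)
})

test_that("genetic map interpolation clamps beyond map ends", {
  td <- withr::local_tempdir()
  p <- file.path(td, "map.txt")
  write.table(data.frame("chr1", paste0("s", 1:3), c(0, 10, 20),
                         c(1e6, 2e6, 3e6)), p,
              row.names = FALSE, col.names = FALSE, quote = FALSE, sep = "\t")
  map <- readGeneticMap(p)
  expect_equal(map$cM, c(0, 10, 20))
  expect_equal(interpolateCM("chr1", 1.5e6, map), 5)
  expect_warning(out <- interpolateCM("chr1", 5e6, map), "clamped")
  expect_equal(out, 20)
})
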