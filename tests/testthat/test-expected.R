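test_that("single-source schedule gives a degenerate whole-chromosome spectrum", {
  m <- matrix(0, 5, 2, dimnames = list(NULL, c("EUR", "NAT")))
  m[5, "EUR"] <- 1
  esp <- expectedTractSpectrum(migrationSchedule(m),
                               chromosomeSet(c(chr1 = 100, chr2 = 60)),
                               edges = c(0, 50, Inf), nHaplotypes = 10)
  expect_equal(sum(spectrumCounts(esp)), 0, tolerance = 1e-12)
  expect_equal(unname(fullChromCounts(esp)["EUR", ]), c(10, 10), tolerance = 1e-10)
  expect_equal(unname(fullChromCounts(esp)["NAT", ]), c(0, 0))
})

test_that("expected spectra conserve total tract length per ancestry", {
  set.seed(17)
  chroms <- chromosomeSet(c(chr1 = 120, chr2 = 90))
  edges <- c(seq(0, 120, length.out = 40), Inf)
  for (i in 1:25) {
    d <- randomModelFx()
    sched <- tryCatch(buildMigrationSchedule(d$model, d$par, d$props),
                      error = function(e) NULL)
    if (is.null(sched)) next
    esp <- expectedTractSpectrum(sched, chroms, edges, nHaplotypes = 7,
                                 depth = sample(0:2, 1))
    got <- rowSums(esp@lengthMass)
    want <- scheduleProportions(sched) * genomeLength(chroms) * 7
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("depth-0 chain equals the compiled Markov engine", {
  sched <- baseSchedFx()
  chroms <- chromosomeSet(c(chr1 = 150, chr2 = 100))
  edges <- defaultBinEdges(chroms, 30)
  esp <- expectedTractSpectrum(sched, chroms, edges, nHaplotypes = 1, depth = 0)
  mu <- admixtract:::expected_spectrum_markov_cpp(migrationMatrix(sched),
                                                  chromLengths(chroms), edges)
  expect_equal(unname(spectrumCounts(esp)), mu$counts, tolerance = 1e-9)
  expect_equal(unname(fullChromCounts(esp)), mu$full, tolerance = 1e-9)
})

test_that("analytic spectrum matches forward simulation (compact oracle run)", {
  # study-regime history: founding 12 generations back, African pulse at 6
  props <- c(EUR = 0.55, NAT = 0.35, AFR = 0.10)
  sched <- buildMigrationSchedule("BASE", c(12, 6), props)
  chroms <- chromosomeSet(c(chr1 = 150))
  nhap <- 6000
  coh <- simulateCohort(sched, chroms, nhap / 2, seed = 77,
                        pedigreeSize = 60000)
  edges <- c(seq(0, 150, by = 10), Inf)
  sp <- tractLengthSpectrum(tracts(coh), chroms, edges,
                            ancestries = names(props), nHaplotypes = nhap)
  esp <- expectedTractSpectrum(sched, chroms, edges, nHaplotypes = nhap,
                               depth = 2)
  o <- cbind(spectrumCounts(sp), fullChromCounts(sp))
  mu <- cbind(spectrumCounts(esp), fullChromCounts(esp))[names(props), ]
  sel <- mu >= 5
  z <- (o[sel] - mu[sel]) / sqrt(mu[sel])
  expect_lt(max(abs(z)), 4)
  chi <- sum(z^2)
  expect_gt(pchisq(chi, sum(sel), lower.tail = FALSE), 0.01)
})

test_that("Poisson composite log-likelihood follows the counting-process form", {
  chroms <- chromosomeSet(c(chr1 = 50))
  mk <- function(counts, full, type) {
    new("TractSpectrum",
        counts = matrix(counts, 1, length(counts), dimnames = list("EUR", NULL)),
        full = matrix(full, 1, 1, dimnames = list("EUR", "chr1")),
        edges = c(seq(0, 40, length.out = length(counts) + 1)),
        chroms = chroms, nHaplotypes = 1, type = type, lengthMass = NULL)
  }
  # all observations zero, all expectations one: log pmf(0; 1) = -1 per cell
  o <- mk(rep(0, 5), 0, "observed")
  e <- mk(rep(1, 5), 1, "expected")
  expect_equal(poissonLogLik(o, e), -6)
  # observed equal to integer expectation: sum of log pmf at the mode
  o2 <- mk(c(3, 7, 1, 0, 2), 4, "observed")
  e2 <- mk(c(3, 7, 1, 0.5, 2), 4, "expected")
  oracle <- sum(dpois(c(3, 7, 1, 0, 2, 4), c(3, 7, 1, 0.5, 2, 4), log = TRUE))
  expect_equal(poissonLogLik(o2, e2), oracle)
  # random spectra against the independent dpois oracle
  set.seed(1)
  for (r in 1:5) {
    mu <- runif(6, 0.1, 8)
    oc <- rpois(6, mu)
    os <- mk(oc[1:5], oc[6], "observed")
    es <- mk(mu[1:5], mu[6], "expected")
    expect_equal(poissonLogLik(os, es), sum(dpois(oc, mu, log = TRUE)))
  }
  # zero expectation with positive observation
  expect_identical(poissonLogLik(mk(c(1, 0, 0, 0, 0), 0, "observed"),
                                 mk(c(0, 1, 1, 1, 1), 1, "expected")), -Inf)
  expect_error(poissonLogLik(o, mk(rep(1, 4), 1, "expected")), "shape|edges")
})

test_that("spectrum expectation rejects degenerate bin specifications", {
  sched <- baseSchedFx()
  chroms <- chromosomeSet(c(chr1 = 100))
  expect_error(expectedTractSpectrum(sched, chroms, edges = c(5)), "one bin")
  expect_error(expectedTractSpectrum(sched, chroms, edges = c(5, 5, 10)),
               "strictly increasing")
})
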