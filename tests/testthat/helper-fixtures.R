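# Shared fixture builders; everything generated in code, seeded.

basePropsFx <- c(EUR = 0.65, NAT = 0.30, AFR = 0.05)

baseSchedFx <- function(t0 = 12, tafr = 6, props = basePropsFx)
  buildMigrationSchedule("BASE", c(t0 = t0, t_afr = tafr), props)

smallCohortFx <- function(nInd = 20, chroms = chromosomeSet(c(chr1 = 100, chr2 = 80)),
                          seed = 7, sched = baseSchedFx()) {
  simulateCohort(sched, chroms, nInd, seed = seed)
}

# painted two-population haplotype set on one chromosome
paintedCohortFx <- function(nInd = 10, nLoci = 2000, fst = 0.1, seed = 5) {
  chroms <- chromosomeSet(c(chr1 = 100))
  coh <- simulateCohort(baseSchedFx(), chroms, nInd, seed = seed)
  fr <- drawAncestralFrequencies(nLoci, 3, fst, chroms, seed = seed + 1,
                                 populations = c("EUR", "NAT", "AFR"))
  paintHaplotypes(coh, fr, seed = seed + 2)
}

# calls data.frame -> LocalAncestryCalls
callsFx <- function(...) {
  df <- data.frame(...)
  new("LocalAncestryCalls", calls = df)
}

# random feasible model parameter draw (for property tests)
randomModelFx <- function() {
  model <- sample(DEMOGRAPHIC_MODELS, 1)
  t0 <- runif(1, 4, 20)
  tafr <- runif(1, 2, floor(t0) - 1)
  par <- c(t0 = t0, t_afr = tafr)
  if (model != "BASE")
    par <- c(par, t_pulse = runif(1, 2, floor(t0) - 1),
             m_pulse = runif(1, 0.001, 0.4))
  pE <- runif(1, 0.2, 0.7); pA <- runif(1, 0.01, 0.2)
  list(model = model, par = par,
       props = c(EUR = pE, NAT = 1 - pE - pA, AFR = pA))
}
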