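---
title: "Pulse-migration inference from local-ancestry tracts: models, algorithms and design"
author: "admixtract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-migration inference from local-ancestry tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixtract)
```

# The problem

Recently admixed genomes are mosaics of chromosome segments inherited from
distinct continental source populations. Because recombination breaks ancestral
chromosomes apart at roughly one crossover per Morgan per generation, the
lengths of maximal single-ancestry segments ("ancestry tracts") carry a clock:
older admixture leaves many short tracts, recent admixture leaves few long
ones. This package infers the timing and structure of admixture from the
tract-length distribution, and provides the two companion analyses that a
full admixed-cohort study needs: ancestry-specific PCA of masked haplotypes
(to place each ancestry component against subcontinental reference panels),
and haploid identity-by-descent sharing with local-ancestry overlay.

Everything is exercised against a bundled forward pedigree simulator, so the
whole pipeline is testable without any restricted genotype data.

# The demographic model

A demographic hypothesis is a *migration schedule*: for generation $t$ before
present (the sampled generation is $t = 1$) and source population $p$, the
fraction $m_p(t)$ of the admixed population replaced by migrants from $p$.
The founding generation $T_0$ is fully specified
($\sum_p m_p(T_0) = 1$). Three nested hypotheses are built in:

* **BASE** — founding admixture between a European-like and a Native-like
  source at time $t_0$, followed by one African pulse at $t_{\mathrm{afr}}$.
  Free parameters: $(t_0, t_{\mathrm{afr}})$.
* **EUR_PULSE / AFR_PULSE** — BASE plus one later pulse of European or
  African migration with free time $t_{\mathrm{pulse}}$ and magnitude
  $m_{\mathrm{pulse}}$.

The probability that a sampled lineage's most recent migrant ancestor entered
at generation $t$ from source $p$ is
$a_{t,p} = m_p(t)\prod_{1<s<t}(1 - M(s))$ with $M(s)=\sum_q m_q(s)$; the final
ancestry proportion of source $p$ is $a_p=\sum_t a_{t,p}$. The founding split
and the African pulse magnitude are not free parameters: they are pinned so
that the schedule's implied $a_p$ equal the cohort's observed tract-length
ancestry fractions exactly. The African fraction is an exact quadratic in the
pulse magnitude and the European fraction is affine in the founding split, so
the pinning is solved in closed form (with a bisection fallback guarding
degenerate corners); `scheduleProportions()` provides the independent check
that the round trip reproduces the observed proportions to $10^{-10}$.

Non-integer times are mapped onto the integer generation grid by splitting an
event between the two adjacent generations proportionally to the fractional
part (the founding block splits analogously: full replacement at
$\lceil t_0\rceil$ plus a partial replacement at $\lfloor t_0\rfloor$ of
magnitude $1 - (t_0 - \lfloor t_0\rfloor)$, which is continuous in $t_0$ and
reduces to a single founding event at integer times). Rounding instead of
splitting would make the likelihood piecewise constant in time and stall the
optimizer, which is why splitting is the default and only implemented mode.

# Expected tract-length spectra

## The lineage process along the genome

Follow one sampled haplotype along a chromosome. At every position its
ancestry is decided by the path of meioses up the pedigree to the most recent
migrant ancestor; a state is the pair (entry generation $t$, source $p$).
Moving along the genome, crossovers in the $t-1$ meioses along that path
switch the path. Two derivations matter and both are validated against the
forward simulator:

* A crossover in the *topmost* meiosis switches between the migrant's two
  chromosomes, which carry the same ancestry, so the effective switch rate of
  a state with entry $t$ is $t-2$ per Morgan (not $t-1$).
* A crossover at meiosis level $s$ moves to the other parental chromosome at
  generation $s+1$, i.e. to a gamete of the co-parent at generation $s+2$:
  the replacement lineage enters at generation $u \ge s+2$ with probability
  $m_r(u)\prod_{s+2 \le g < u}(1 - M(g))$.

## Beyond the memoryless approximation

Treating each switch as a fresh draw (the classical Markov approximation used
by tract-fitting software) is measurably wrong at cohort scale: each meiosis
toggles between the *same two physical chromosomes*, so a crossover can
resume a previously visited lineage whose ancestry is frozen. The signature
is heavier tails on both ends of the tract-length distribution — repeated
visits to a differing partner chromosome emit repeated short tracts, repeated
visits to a matching one extend long tracts.

`expectedTractSpectrum()` therefore augments the state with a LIFO stack of
shelved lineages and their branch levels (`depth` shelves; a flip at a shelf's
branch level resumes it, a flip below a branch invalidates everything above).
Depth 0 recovers the memoryless chain; depth 2 (the default) brings the
expectation within Monte-Carlo error of the forward simulator at the time
depths the package targets (founding 9–14 generations ago). The chain is finite-state, so
per-ancestry spectra come from standard phase-type algebra: binned expected
counts include end-truncated tracts binned by observed length, and tracts
covering a whole chromosome form a separate per-chromosome category. Expected
per-bin total tract *lengths* are computed analytically alongside the counts,
and per ancestry they sum to $a_p \times$ genome length $\times$ cohort size
to first-order machine accuracy — the package's internal conservation check.

Known limitation: at very shallow time depths (founding around 6 generations
or less, or pulses 2–3 generations back) the truncated-stack chain still
deviates by a few percent from the pedigree process, because shelf-internal
dynamics are modelled memorylessly. All bundled analyses and defaults target
the 9–14 generation regime, where depth-2 agreement is statistically
indistinguishable at 20,000 chromosome-haplotypes.

## Numerical notes

The per-ancestry sub-generators are small at depth 0 (a handful of states)
and reach a few hundred states at depth 2. The exported spectrum evaluates
matrix exponentials and their first two moment integrals by uniformization —
Poisson-weighted powers of a substochastic matrix, with incomplete-gamma
weights for the integrals. All weights are nonnegative, so the evaluation is
unconditionally stable; an eigenbasis representation was tried first and
loses four to five digits when shelf states make the sub-generator nearly
defective. The compiled fitting engine, which only ever sees the small
depth-0 generators, uses a complex eigendecomposition with a
scaling-and-squaring fallback guarded by the reconstruction error. States
with entry generation 2 never switch ancestry (an infinite tract); they form
their own absorbing class and carry exactly their lineage entry mass, while
the main communicating class's stationary vector is solved as an exact null
vector of the generator. Finally the stationary mass is pinned per ancestry
to the exact marginal $a_p$, which keeps length conservation exact under
stack truncation (the truncated chain's stationary ancestry shares are
otherwise off by order $10^{-4}$).

# Fitting and simulation-calibrated model choice

The observed statistic is the binned tract-length spectrum (default: 50 equal
bins from 0.2 cM — the local-ancestry window resolution floor — to the longest
chromosome, plus the whole-chromosome category; all configurable). The fit
maximizes the Poisson composite log-likelihood
$\sum_b o_b\log\mu_b - \mu_b - \log o_b!$ over the free parameters with
multi-start Nelder–Mead (10 Latin-hypercube starts by default; times bounded
to (2, 25) generations, magnitudes to (0.001, 0.999); pulses constrained at
least one generation after founding through an infeasibility penalty). The
optimizer evaluates the memoryless (depth-0) spectrum for speed — the same
modelling choice as the field's standard tract-fitting software.

Tract counts are not independent, so likelihood-ratio comparisons between
nested models are anti-conservative. Model choice therefore uses the
simulation calibration: refit both models to cohorts simulated from the
fitted null with the forward pedigree simulator and reject the single-pulse
model only when the observed gain exceeds the empirical 95th percentile of
the simulated gains. Two design details matter:

* The add-one p-value $(1 + \#\{\Delta\ell_{sim} \ge \Delta\ell_{obs}\})/(n+1)$
  keeps $p > 0$ at the simulation resolution floor.
* The observed gain is computed with the *identical matched-effort fitting
  protocol* used inside every null replicate (same warm starts, same restart
  and iteration budgets). Giving the observed data a more thorough
  optimization than the replicates inflates the observed gain relative to the
  null distribution and measurably breaks calibration.

Both models are fully refit on every replicate (not just the extra
parameters), which is the conservative reading of the procedure. `BIC` is
available on fits as a convenience, but model choice follows the calibrated
test.

# The forward pedigree simulator

`simulateCohort()` is both the synthetic-data generator and the numerical
oracle for the analytic spectrum, so it deliberately does *not* implement the
Markov approximation: it simulates an explicit diploid pedigree forward in
time. Founders at $T_0$ are migrants drawn from the founding fractions; each
later-generation individual is a new migrant with probability $M(t)$ or the
child of a random monogamous pair (pairs re-drawn each generation, no
selfing); gametes have Poisson(length in Morgans) crossovers at uniform
positions with a fair-coin start and no interference, matching the analytic
model's crossover assumptions asymptotically. Only ancestors of the sample
are simulated, and identical seeds give byte-identical output.

The pedigree population size defaults to `max(200, 10 * nIndividuals)`. This
is a free modelling choice and it is deliberately configurable: at founding
depth 12 a chromosome's lineage visits ~17 ancestors, and in a pedigree of
10,000 those lineages revisit shared ancestors often enough to inflate both
tail counts by 1–2% relative to the infinite-population analytic law. The
oracle-equivalence checks therefore run the simulator at a pedigree size of
100,000, where collapse is negligible; cohort-scale analyses (null-replicate
simulation inside model selection) use the default, where the same effect is
far below sampling noise. The X chromosome is not simulated with
hemizygosity; sex-bias analyses use two autosome-like compartments with
different founding splits.

Ancestry-specific allele frequencies follow a Balding–Nichols model
(ancestral frequency Uniform(0.05, 0.95), population frequencies Beta-drifted
with parameter FST), haplotypes are painted Bernoulli from the frequency of
their local ancestry, and IBD ground truth is planted by copying allele
intervals between haplotypes.

# Ancestry-specific PCA

Admixed haplotypes are masked to one target ancestry: a locus survives only
where the local-ancestry call equals the target *and* its posterior is at
least 0.95. Haplotypes with less than 25% target ancestry are excluded, as
are reference individuals with more than 10% European contamination (all
thresholds strict, all configurable through `cohortFilters()`). The masked
admixed rows are joined with the fully observed reference panel on shared
loci and decomposed by subspace PCA: iterative rank-$k$ completion that
alternates a truncated decomposition with re-imputation of missing entries
until the imputed entries stabilize (RMS change below $10^{-6}$, cap 200
iterations). The truncated decomposition uses warm-started block power
iteration, so iterations after the first cost a few matrix-vector products.
With no missing entries the procedure is exactly standard PCA (verified to
$10^{-8}$ against `prcomp`), which pins down the many free choices the
missing-data generalization would otherwise leave open. Alleles stay 0/1 and
columns are centered but not variance-scaled (haploid data); each component's
sign is fixed so the first reference population's centroid is nonnegative.

The synthetic benchmark for this module is deliberately idealized: two
reference populations at FST 0.1 with 10,000 independent loci and 50%
missingness, where nearest-reference-centroid assignment recovers at least
90% of masked haplotype origins. Real panels have LD, masking is *not*
independent across loci (it follows ancestry tracts), and reference panels
are themselves structured — passing the benchmark shows the solver is
correct, not that real subcontinental assignment reaches any particular
accuracy.

# IBD detection and ancestry overlay

`findIBDHaploid()` mirrors the seed-and-extend hashing design of haploid-mode
GERMLINE: markers are cut into fixed slices (default 128 markers), exact
slice matches between haplotype pairs are hash seeds, matches extend across
adjacent slices while each slice carries at most 2 allele mismatches, and
maximal runs of at least 3 cM are reported. The diploid distinction between
homozygous and heterozygous mismatch budgets has no haploid counterpart; the
per-slice allele-mismatch budget mirrors the homozygous budget. Endpoints are
resolved at slice granularity, and a single corrupted slice splits a match —
the conservatism that makes haploid mode robust to phasing switch errors.

Detected (or ingested GERMLINE-format) segments get length-weighted
local-ancestry profiles, averaged over the two haplotypes with a discordance
flag when the haplotypes disagree in majority ancestry. Population-level
sharing sums segment lengths and normalizes by haplotype pair counts
($n_P n_Q$ between populations, $n_P(n_P-1)/2$ within), with standard errors
from the delete-one-chromosome weighted jackknife (genetic-length weights,
Busing-style pseudovalues). The regression of per-segment European proportion
on segment length is ordinary least squares through `lm`, groupable by
within/between-population status.

# Scales used by the bundled checks

The automated checks run at desk scale on one CPU, chosen as the smallest
sizes at which each property is statistically sharp: oracle equivalence at
2,000 haplotypes on 10 x 150 cM chromosomes; parameter recovery over 20
cohorts of 100 diploids; selection calibration over 100 cohorts of 40
diploids with 200 null simulations each (a scaled-down version of the
1000-replicate calibration a full study would run), with power measured at
pulse magnitudes 0.05/0.15/0.30; the ASPCA and IBD benchmarks as above. The
acceptance script repeats the same computations at slightly reduced replicate
counts.

# Known limitations

* The analytic spectrum is an approximation outside the 9–14 generation
  regime (see above); the simulation-calibrated test remains valid there
  because it compares like with like, but reported times for very recent
  histories inherit the approximation.
* Even in the target regime a small residual bias survives stack truncation,
  concentrated in the sparse extreme-length tail (expected counts below ~5
  per bin, well under 1% of tracts, underpredicted by roughly a third). The
  oracle-equivalence chi-square consequently averages slightly above its
  nominal mean over repeated simulations; bulk bins agree within Monte-Carlo
  noise.
* Crossover interference, non-uniform recombination maps and within-source
  LD are not modelled — synthetic panels are exchangeable-locus caricatures.
* The X chromosome is treated as an autosome-like compartment.
* Continuous (non-pulse) migration histories are out of scope.
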