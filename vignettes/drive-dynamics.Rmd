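---
title: "Modelling wtf meiotic drive under partial same-clone mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wtf meiotic drive under partial same-clone mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtfdrive)
```

## The biological problem

*wtf*-family meiotic drivers of fission yeast encode a poison delivered to
all four spores of a heterozygous ascus and an antidote that rescues only the
spores inheriting the driver. A heterozygote therefore transmits the driver
to a fraction $k > 1/2$ of its *surviving* spores, at the cost of killing
roughly half of them. Whether such a driver spreads depends not only on $k$
but on how often heterozygotes form at all: fission yeast mates largely
among the mitotic descendants of a single cell (same-clone mating), which
suppresses heterozygosity exactly where the driver earns its advantage.
This package implements the deterministic and stochastic population-genetic
machinery for that question, the estimators used to quantify mating
behaviour from count data, and a maximum-likelihood fit of fitness costs
linked to fluorescent markers in experimental evolution.

## The deterministic core

With driver allele frequency $p$ and inbreeding coefficient $F$, zygote
genotype frequencies are

$$f_{11} = p^2 + Fp(1-p), \qquad f_{12} = 2p(1-p)(1-F), \qquad
  f_{22} = (1-p)^2 + Fp(1-p),$$

and one round of mating, meiosis with transmission bias $k$, and selection
gives

$$p' = \frac{f_{11} w_{11} + f_{12}\,k\,w_{12}}{\bar W}, \qquad
  \bar W = f_{11} w_{11} + f_{12} w_{12} + f_{22} w_{22}.$$

`genotype_freqs()`, `mean_fitness()`, `next_freq()`, `delta_p()` and
`drive_trajectory()` expose these pieces. Two fitness constructions recur
throughout: `het_drive_fitness(k)` $= 1/(2k)$, the heterozygote fitness when
drive-induced spore death is the only cost (0.51 at the measured $k = 0.98$),
and `fitness_from_costs(c, h, k)`, which layers a linked deleterious allele
with homozygous cost $c$ and dominance $h$ on top of drive
($w = 1-c$ for the costly homozygote, a factor $1 - ch$ times $1/(2k)$ for
the heterozygote). At the fitted values $c = 0.234$, $h = 0.083$ these
reproduce the working fitnesses 0.766, 0.98, and (with drive) 0.5.

**Negative $F$.** The genotype polynomials go negative when heterozygote
excess exceeds what the allele frequency permits (e.g. $F = -1$ away from
$p = 1/2$). No convention exists for this regime, so the package makes
an explicit choice: negative frequencies are clamped to zero and the triple
renormalised, with a warning (`clamp = TRUE`, the default), which lets
strong-outcrossing curves be drawn over the whole frequency range; a strict
mode errors instead. All frequency-sum and fixed-point checks use an
absolute tolerance of $10^{-12}$.

**Transmission bias domain.** $k$ is restricted to $[0.5, 1]$; drive against
the focal allele is rejected rather than reinterpreted, since nothing
downstream is calibrated for it.

## Invasion of cost-linked drivers

Under complete drive ($k = 1$) with fitnesses $w_{11} = 1 - c$,
$w_{12} = (1 - ch)/2$, $w_{22} = 1$, the driver gains ground from frequency
$p$ exactly when $F$ lies below

$$F_{\mathrm{crit}} = \frac{ch(p-1) - cp + p}{c(h-1)(p-1) + p},$$

which `critical_inbreeding()` evaluates and `can_invade()` compares
against. Invasion here means a strictly positive single-generation
$\Delta p$ at the queried frequency, not long-run fixation.
`min_invasion_freq()` finds the smallest invading frequency by bisection on
the sign of $\Delta p$ (default precision $10^{-6}$, 200-iteration cap, a
1001-point scan to bracket the sign change); for $k < 1$ no closed form is
claimed and the numerical route is the only one. With no linked cost the
threshold is pinned to 1 exactly, so any $F < 1$ admits invasion at every
positive frequency.

## The finite-population model

`wf_step()`/`wf_run()` implement a Wright–Fisher generation for a haploid
population of size $N$: resample $N$ individuals with replacement (an
infinite-gamete assumption standing in for mitotic expansion before mating);
designate $\mathrm{round}(FN)$ of them same-clone maters, each fusing with a
clonal copy of itself to give a homozygote of its own allele; form the
remaining matings at Hardy–Weinberg proportions of the random maters' allele
frequency; give every mating four spores, thin each mating class binomially
by its fitness (heterozygotes default to 0.5, i.e. complete drive, and all
their surviving spores carry the driver); and draw the next $N$ haploids
uniformly from the surviving pool. Counts 0 and $N$ are absorbing.

Three design points deserve notice:

* **Integerising Hardy–Weinberg proportions.** Deterministic
  largest-remainder rounding looks innocuous but is not: it assigns the
  fractional matings to fixed genotype classes, which injects a per-state
  allele drift of up to one allele at particular counts (with ties broken
  by floating-point representation error, in an arbitrary direction). In a
  population of 20 that bias is strong enough to push the neutral fixation
  probability visibly away from $1/N$. The default (`hw_rounding =
  "stochastic"`) therefore floors the quotas and assigns the leftover
  matings multinomially in proportion to the fractional parts: counts still
  sum exactly, and the expected allele count is exact, so the neutral model
  is a true martingale. The deterministic variant remains available as
  `"largest-remainder"` for comparison.
* **Same-clone pairing.** A same-clone mater is modelled as fusing with a
  clonal copy of itself, which is what mating within a freshly divided
  clone produces. The alternative reading — pairing sampled like-genotype
  individuals with each other — is available via `pairing = "like"`.
* **"Maintained".** A driver is counted as maintained when it is not lost
  by the generation cap; fixed and still-segregating replicates are also
  tallied separately by `maintenance_probability()`, since either reading
  of "maintained" may be wanted.

Replicates draw sub-seeds deterministically from the master seed, so runs
are bit-reproducible, and configurations sharing a master seed share
replicate streams (common random numbers), which sharpens comparisons such
as maintenance across $N$ or $F$. Default horizons are 1000 generations and 1000 replicates.

## Estimators from count data

* `inbreeding_from_zygotes()`: $F = 1 - \mathrm{obs}/\mathrm{exp}$
  heterozygote frequency among mated units, the expectation being
  $2p(1-p)$ at the pre-mating parental frequency. Zygotes and asci each
  count once; free spores are not genotyped by the microscopy assay. The
  pre-mating census frequency is used by default; re-estimating $p$ from
  the zygote table is available for synthetic studies.
* `inbreeding_from_genetic()`: with $n$ unlinked markers a heterozygote's
  progeny fall into $2^n$ equally frequent genotype classes of which two
  are parental, so the observed recombinant fraction is divided by
  $(2^n - 2)/2^n$ (6/8 for three markers, 2/4 for two) before entering the
  same $F$ formula. Corrections that overshoot 1 through sampling noise are
  capped at 1 with a warning rather than erroring.
* `mating_efficiency()`: $(2Z + 2A + S/2)/(wV + 2Z + 2A + S/2) \times 100$.
  The vegetative weight $w$ defaults to 2 but is exposed as an argument,
  since a strict per-cell accounting would use $w = 1$; the synthetic census
  generator is calibrated to the default.
* `expected_mixed_cross()`: the additive model for crosses between isolates
  with their own inbreeding coefficients and mating efficiencies, taken
  literally, with the second homozygote class as the remainder (the
  remainder is provably non-negative over the whole parameter domain).
* `bootstrap_ci()`: percentile bootstrap by multinomial resampling of the
  count table; degenerate resamples are skipped and counted.

## Fitting the linked cost

Control crosses without drive ($k = 0.5$) still showed the focal marker
declining, attributed to a cost linked to the GFP insertion.
`fit_linked_cost()` estimates $(c, h)$ by bounded L-BFGS-B minimisation of a
negative log-likelihood over $[0,1]^2$, with a seeded Latin-hypercube of
eight starts and ties broken toward smaller $c$. The forward model is the
deterministic recursion started from each replicate's generation-0
observation; only generations 1 through `window` (default 6, matching the
point where fluorescent-marker loss overwhelms the signal) enter the
likelihood. The observation model is a documented choice, since gated cytometry
frequencies come with no canonical likelihood: the default treats each observed frequency as
a binomial count out of `effective_n` cytometry events (default 10,000),
with predictions floored to $[10^{-9}, 1 - 10^{-9}]$; a concentrated
Gaussian-residual alternative is available.

**What is and is not identified.** Over a six-generation decline, $c$ and
$h$ trade off along a likelihood ridge: lowering $h$ and nudging $c$ up
reproduces the trajectory to within a few $10^{-4}$, an order of magnitude
below the binomial noise floor at $n = 10^4$. Consequently $c$ is estimated
sharply (asymptotic SE below 0.01 at study-scale data) while single-dataset
estimates of $h$ scatter widely and pile on the $h = 0$ boundary; the
ensemble of fits is unbiased for $h$, but an individual fit pins down only
the $(c, h)$ combination that sets the trajectory. The tests therefore
check per-dataset recovery for $c$, trajectory-level (predictive) recovery
for the pair, and ensemble-mean recovery for $h$. Profile unimodality in
$c$ is verified on noise-free data.

## What the synthetic data do and do not emulate

`sim_zygote_counts()`, `sim_progeny_table()`, `sim_evolution_trajectories()`
and `sim_census()` generate exactly the observables the estimators assume:
multinomial genotype counts at the model's zygote frequencies, Mendelian
segregation of 2–3 unlinked markers through the same mating law,
deterministic drive/cost dynamics observed through optional per-generation
fluorescent-marker loss (opt-in, default rate 0, with the mCherry-type
marker historically the faster-losing one) and binomial measurement noise,
and a weighted mating census. Trajectories are truncated with a warning
once more than 95% of cells have lost fluorescence, mirroring the
practical stopping rule. Defaults describe a typical evolution experiment: starting frequency 0.5,
three replicates, six generations, 10,000 scored cells per observation.

Passing calibration tests on these generators shows that each estimator
inverts its own generative assumptions at the stated sample sizes. It does
not validate the assumptions themselves against real cultures — genuine
cytometry gating error, genotype-dependent marker loss, selection during
vegetative growth, and cross-to-cross variation in mating behaviour are all
outside the generators' scope.

## Problem sizes used by the tests and acceptance script

Checks were sized to make Monte-Carlo error negligible relative to each
tolerance while keeping the whole suite in the low tens of seconds: 20,000
replicates for the neutral fixation probability at $N = 20$; 200 replicates
of a single generation at $N = 10^5$ for the deterministic limit (agreement
within 3 standard errors); 1000 replicates per condition for maintenance
orderings; 5,000–20,000 observations per synthetic estimator calibration;
and 10–20 seeded datasets for cost-fit recovery. The exact one-generation
transition law is verified at $N = 10$ against full enumeration of every
stochastic layer.

## Known limitations

One locus, two alleles, one mating round per non-overlapping generation; no
suppressors, no multi-locus drive systems, no mutation, no spatial or deme
structure. The invasion analysis reports where single-generation gain
changes sign, not a stability analysis of interior equilibria. Confidence
intervals for the cost fit are limited to the bootstrap pattern; profile
likelihood intervals are not provided.
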