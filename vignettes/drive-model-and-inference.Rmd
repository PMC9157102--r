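---
title: "Homing suppression drive dynamics and fitness inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homing suppression drive dynamics and fitness inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological system

A homing suppression drive is a CRISPR construct inserted into a
haplosufficient gene required for female fertility.  In the germline of
drive/wild-type heterozygotes, Cas9 cleavage followed by homology-directed
repair copies the drive onto the wild-type chromosome ("drive
conversion"), pushing inheritance above the Mendelian 50%.  End-joining
repair instead produces resistance alleles: nonfunctional ones (r2) that
disrupt the target gene like the drive does, and functional ones (r1) that
preserve it and can ultimately outcompete the drive.  Maternally deposited
Cas9 additionally cleaves paternal wild-type alleles in early embryos of
drive mothers.  Females with no functional target-gene copy (no `WT` or
`R1` allele) are sterile; suppression works by accumulating them.  In the
split design modeled here, Cas9 sits at an unlinked locus, and we treat it
as fixed in the experimental populations (`cas9_present` switches the
whole cutting machinery off for control crosses).

## The deterministic recursion

`next_generation()` advances per-sex genotype frequency distributions over
60 states: 10 unordered drive-locus pairs of {`WT`, `DRIVE`, `R1`, `R2`},
3 unordered pairs at one off-target locus {`INTACT`, `DISRUPTED`}
(standing in for unlinked incidental cleavage sites), and 2 sexes.  One
generation consists of: sterile females removed from reproduction; females
weighted by fecundity, males by mating success (every female mates; mate
choice is proportional to frequency x mating success); gamete formation
with germline conversion, resistance formation, and off-target cutting;
embryo cutting keyed on the mother; viability weighting of offspring; and
1:1 sex assignment with per-sex renormalization.  Populations are
effectively infinite; the stochastic simulators add the finite-size layer.

Germline conversion and resistance formation are modeled as *competing
outcomes applied simultaneously* to each wild-type allele of a
Cas9-bearing drive heterozygote: conversion with probability `c`,
resistance with probability `g` (split `rho : 1 - rho` into r1 : r2), wild
type with the remainder.  With the measured `c = 0.767` and `g = 0.222`
only 1.1% of germline wild-type alleles escape both fates, which is what
the drive's observed near-complete germline processing requires.  The
alternative reading — resistance applied only to the non-converted residue
— would leave ~18% of germline alleles wild-type and is inconsistent with
that observation, so it is not used.

Embryo cutting is all-or-nothing per allele: each wild-type drive-locus
allele of an offspring of a drive-carrying mother independently becomes a
resistance allele with probability `embryo_cut_rate`.  Mosaic individuals,
which exist in the real data, are outside the model's genotype space; the
embryo rate is calibrated from a sterility assay, so it already counts
"mosaic enough to be sterile" as cut.  No off-target cutting happens at
the embryo stage; off-target cutting happens only in the germline of
Cas9-bearing drive carriers, at rate 1 by default (the simplest model of
many distant sites that are mostly cut when cleavage activity peaks).

## Parameters

| parameter | meaning | default | origin |
|---|---|---|---|
| `conversion_female`, `conversion_male` | P(germline WT -> DRIVE) per sex | 0.767 | cross-measured female 0.727 / male 0.807, averaged; the averaged value is used for both sexes by default |
| `germline_resistance_total` | P(germline WT -> r1 or r2) | 0.222 | set so that conversion + resistance leaves ~1% of germline WT alleles unprocessed |
| `embryo_cut_rate` | P(embryo WT -> resistance), drive mothers | 0.522 | solved from 54.5% observed vs 5% baseline sterility |
| `relative_r1_rate` | fraction of new resistance alleles that are r1 | 0 | profiled by `fit_relative_r1()` |
| `offtarget_germline_cut_rate` | P(INTACT -> DISRUPTED) in carrier germline | 1 | simplest off-target model |
| `initial_offtarget_cut_fraction` | disrupted fraction in founder carriers | 0.5 | founder carriers descend from male drive heterozygotes |

All rates are probabilities per allele per generation.  Fitness models
take a homozygote fitness `w > 0` with heterozygotes at `sqrt(w)`
(multiplicative costs); the somatic-cleavage model is the exception, its
`w` being directly the net fecundity of female drive/wild-type
heterozygotes, the only genotype somatic cleavage can harm.

## Equilibria, load, and the selection protocol

A suppression drive with imperfect conversion reaches an equilibrium
carrier frequency where homing gains balance removal through sterile
genotypes; fitness costs lower it.  `equilibrium_carrier_frequency()`
iterates until the carrier-frequency change drops below `tol = 1e-6` per
generation (`max_gens = 1000`), far below the ~1% resolution of any of the
quantities of interest; non-convergence is flagged, never silently
returned.  At the measured rates with no cost the model equilibrates at
90.3%; `solve_homozygote_cost_for_equilibrium()` bisects the cost (to
`1e-4`) and finds that an 18.9% homozygote viability cost drags the
equilibrium down to the 70% regime — the model's quantitative expression
of "a roughly 20% cost explains a 70% equilibrium".

`genetic_load()` is one minus the population's per-capita reproductive
output relative to an all-wild-type population: it combines the sterile
female fraction, fecundity and mating costs, and the viability (including
embryo cutting) of the offspring the current females would produce.  With
neutral fitness and no embryo cutting it reduces exactly to the sterile
female fraction, which the tests verify against the general computation.

`selection_load_trajectory()` is the deterministic limit of the
artificial-selection small-cage protocol: all non-carrier adults are
discarded before mating, every generation.  Under the measured rates and
the cage-fitted viability cost (`w = 0.8`) the load jumps to ~0.996 one
generation after release and equilibrates at 0.998.  The choice of fitted
cost model barely matters here (neutral: 0.9976; somatic fecundity
`w = 0.43`: 0.999); we use the direct-viability fit of the longer, more
informative cage.  A load this close to 1 means a handful of fertile
females per hundred; the stochastic protocol simulator accordingly drives
small cages extinct within a few generations.

`required_genetic_load(b, s)` is the replacement threshold
`1 - 2/(b*s)`: with 20 eggs per female and 80% egg-to-adult survival a
cage only shrinks once the load exceeds 0.875.

## The likelihood

Cage data are per-generation carrier/non-carrier counts (`DsRed`
phenotype; sexes are pooled because phenotyping does not distinguish
them).  For each transition the state at the earlier generation is
*reconstructed*: the model-predicted genotype distribution is rescaled so
its carrier mass matches the observed carrier frequency, preserving the
predicted within-phenotype genotype proportions (`reconstruct_state()`).
The state is advanced one generation and the next observed counts scored
with a binomial on the predicted carrier frequency.  The founder
transition (generation 0 to 1) is excluded — founder adults, raised
separately, had atypical fitness — but still seeds the reconstruction
chain.  A dataset of `T` generations therefore contributes `T - 2`
transitions, and a fit requires at least 3 generations.

Choices worth stating:

* **Per-transition conditioning** rather than a free-running trajectory:
  each step restarts from what was actually observed, which is how serial
  phenotype counts are usually treated and keeps late generations from
  being dominated by compounding early noise.  It is a composite
  (pseudo-)likelihood: only the carrier dimension is conditioned on, and
  genotype composition within phenotype classes is carried by the model.
* **Optimizer**: coarse grid plus golden-section refinement over
  `w in (0.05, 1.5]` — fully deterministic, so identical inputs give
  bit-identical fits.  A flat likelihood (range below 1e-6) is reported in
  the result, not raised.
* **AICc** `= 2k - 2lnL + 2k(k+1)/(n-k-1)` with `n` the number of
  transitions; the neutral model has `k = 0`.  Ties in
  `compare_models()` keep the declared model order.
* **Confidence intervals** are profile-likelihood at the 1.92 log-unit
  drop (chi-squared, 1 df).  The parameter-recovery tests confirm ~95%
  coverage over 100 simulated cages.
* **Pooling** multiple cages shares all parameters and sums
  log-likelihoods.  Per-cage fits are available by simply not pooling.

## The relative r1 rate

`fit_relative_r1()` profiles the fraction `rho` of resistance alleles
that are functional over `[0, 0.05]`, co-optimizing the fitness parameter
at every point, and reports the MLE plus the one-sided 95% upper bound.
`rho` multiplies into both the germline resistance rate and the embryo
cut rate, so a relative bound converts to absolute germline and embryo
formation rates as `rho * g` and `rho * e` (`r1_absolute_rates()`).  We
split the embryo cut rate `rho : 1 - rho` between r1 and r2 rather than
adding r1 on top of the nonfunctional rate; below `rho = 0.005` the two
parameterizations differ by under 0.5% relative, which is far inside
every tolerance used here.

`rho` lives on the boundary of its parameter space.  On noise-free
trajectories its MLE is exactly 0 and the profile is strictly decreasing
— the tests verify this in a deterministic-limit run — but on finite
cages the MLE is 0 only in roughly half of replicates (whenever the
observations do not happen to run above the one-step predictions on
average), and the AICc penalty argument against the extra parameter holds
on exactly those datasets.  The tests assert this two-sided behavior
rather than pretending the boundary MLE is certain.  How tightly the
upper bound closes depends strongly on the number of transitions and on
how long the cage sits near equilibrium, where an r1 allele's advantage
compounds; bounds from a small number of ~10-generation cages are
correspondingly loose.

## The stochastic simulators

`simulate_cage()` draws each generation's `N` adults multinomially from
the deterministic next-generation distribution conditioned on the
realized current tallies — pure demographic/observation noise, no
phenotyping error (none was reported for fluorescence scoring).
`simulate_artificial_selection()` is individual-based: after the discard
step each fertile female draws a mate, a Poisson number of eggs
(`eggs_per_female = 20` by default), and each egg survives with
probability `egg_to_adult_survival = 0.8` times its viability multiplier
— the two defaults being the values the cage husbandry supports.
`generate_cross_dataset()` samples offspring phenotypes and the sterility
assay for the estimator module.  Seeds fully determine every output.

What the generators deliberately do not emulate: vial-level batch
effects (the reason the real analyses also ran a GLMM variant), mosaic
phenotypes, age structure, overlapping generations, density-dependent
viability, and assortative mating.  Passing tests therefore demonstrate
internal consistency of estimator and generator under multinomial noise,
not robustness to those real-data features.

Test and acceptance runs use cages of N = 4,000 for 5-12 generations
(matching the design scale of the experiments), N = 1e5 for
law-of-large-numbers agreement between simulator and recursion, and 100
replicates for CI-coverage checks; these sizes give Monte-Carlo error
comfortably below the asserted tolerances.

## Degenerate inputs and extinction

Zero reproductive output (no fertile females, or zero offspring weight)
is signaled as a classed `drive_extinction` condition rather than
returned as NaNs, because the artificial-selection protocol reaches it by
design; simulators translate it into an `EXTINCT` termination flag.
Observations impossible under a parameter value yield `-Inf`
log-likelihood, not an error, so optimizers can move through them.

## Known limitations

The drive is modeled with a single effective cut site; multi-gRNA
bookkeeping would predict slightly better drive performance for the same
heterozygote parameters, so fitted fitness costs are, if anything,
conservative.  The off-target locus is a single unlinked stand-in for
many real sites of varying linkage.  The reconstruction-based composite
likelihood is not a full-information likelihood — genotype composition is
never observed — and CI coverage statements rest on the model generating
the data.  Functional-resistance bounds are only as good as the fitted
fitness model they condition on.
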