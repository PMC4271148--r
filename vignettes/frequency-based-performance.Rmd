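---
title: "Estimating variant-calling performance from population allele frequencies"
author: "callAccuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating variant-calling performance from population allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callAccuracy)
```

## The problem

Assessing a whole-exome or whole-genome sequencing experiment usually
means asking two questions: what fraction of truly present variants does
the pipeline call (sensitivity), and how often does it call a variant
where there is none (specificity)? The classical answer compares the call
set against an orthogonal platform, typically a genotyping array, at the
cost of extra experiments and with the caveat that array content is itself
a biased selection of "easy" polymorphisms. `callAccuracy` implements the
alternative: treat the presence of a variant at a known polymorphic site
as a random event with probability given by the site's population allele
frequency, and estimate sensitivity and specificity by maximum likelihood
from the call pattern alone.

## The model and its assumptions

Both parameters are **per-allele** probabilities: *s* is the probability
that a variant allele actually present in the sample is detected, and *u*
the probability that a reference allele is not miscalled as variant. For a
diploid site the two allele-level events combine into site-level call
probabilities — *s*(2−*s*) for a homozygous-alternate genotype,
*s* + (1−*s*)(1−*u*) for a heterozygote, 1 − *u*² for homozygous
reference — and the genotype is marginalized out under Hardy–Weinberg
equilibrium at the site's alternate-allele frequency *f*:

$$p(D) \;=\; f^2\,s(2-s)\;+\;2f(1-f)\,\bigl[s+(1-s)(1-u)\bigr]\;+\;(1-f)^2\,(1-u^2).$$

The per-allele parameterization is forced by these conditional forms
(note $s(2-s) = 1-(1-s)^2$); no per-site alternative is offered. Detection
is deliberately dichotomous at the site level — any non-reference call
counts, without matching the specific alternate allele — so genotype-level
(three-class) calling accuracy is out of scope.

The likelihood over a set of sites is the product of $p(D_i)$ over
detected sites and $1-p(D_j)$ over undetected ones. This assumes sites are
independent, which linkage disequilibrium violates for nearby sites. The
remedy is subsampling: a fit uses only sites pairwise separated by at
least 500 kb (or on different chromosomes), the fit is repeated over many
random such sets, and the median of the per-set estimates is reported.

Key assumptions a user should keep in mind:

* the panel frequencies describe the population the sample came from
  (misspecification biases the estimates; see below);
* Hardy–Weinberg equilibrium holds at panel sites;
* the individual is not strongly admixed (no mixture over populations or
  haplotypes is modelled).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nSets` | 1000 | random LD-thinned site sets per individual; the reference workflow uses 1000, smaller values trade precision of the median for speed |
| `minDistance` | 500000 bases | minimum within-chromosome spacing; the boundary is inclusive (exactly 500 kb is allowed) |
| `nBoot` | 2000 | bootstrap resamples for the percentile interval of the mean |
| `level` | 0.95 | bootstrap interval coverage |
| `assumedFrequency` | 1e-8 | frequency assigned to positions with no reported variant when they are folded into the panel; such sites contribute almost pure specificity information, which is how variant classes missing from frequency databases (e.g. indels) are assessed |

The point estimate is a **median** across site sets while the interval is
a percentile bootstrap for the **mean**; the two are reported side by side
and the interval is therefore not guaranteed to bracket the median,
although in practice it almost always does.

## Numerical choices

* **Optimizer.** The 2-D likelihood is maximized on $[0,1]^2$ by
  `optim(method = "L-BFGS-B")` with the analytic gradient, from five fixed
  starts — (0.5, 0.5), (0.9, 0.99), (0.99, 0.9), (0.99, 0.999),
  (0.5, 0.99) — keeping the best optimum. The surface can be nearly flat
  in *u* close to 1 when few rare sites are available; the multi-start
  guards against stalling on that ridge.
* **Clamping.** Site probabilities are clamped to
  $[10^{-12}, 1-10^{-12}]$ before logs, so boundary parameters yield
  large finite penalties instead of $-\infty$ and the bounded optimizer
  remains stable at the edges. Frequencies of exactly 0 or 1 are accepted
  without renormalization.
* **Site sets.** The specification of "random sets" is a uniform shuffle
  followed by a greedy pass that accepts each site if it lies at least
  `minDistance` from every accepted site on the same chromosome. This is
  simple, unbiased across shuffles, and reproducible: per-set seeds are
  derived from the master seed by a counter scheme, so the first *k* sets
  do not depend on how many sets are requested. Estimates across sets
  share sites and are therefore correlated; the median aggregation
  tolerates this.
* **Degenerate inputs.** All-detected or all-undetected observation
  vectors are allowed but trigger a warning, since the optimum then
  typically sits on the boundary of the parameter square. An empty
  panel, a panel/target overlap of zero, or calls sharing no chromosome
  names with the panel raise errors immediately.
* **Coordinates.** Panel/call/truth positions are 1-based; BED targets
  are 0-based half-open, so a site at position $p$ lies inside $[a,b)$
  iff $a < p \le b$.

## What the simulator emulates

`simulateCohort()` draws, for each individual and site, a Hardy–Weinberg
genotype at the site's frequency, then simulates detection **per allele**:
each variant allele fires with probability `sTrue`, each reference allele
with probability `1 - uTrue`, and the site is called when any allele
fires. Because the simulator never uses the closed-form site
probabilities, agreement between its empirical conditional detection
rates and the model formulas (checked at 100,000 sites in the test suite)
is a genuine cross-validation of both implementations.

Defaults are chosen to resemble a common-polymorphism panel: frequencies
Uniform(0.01, 0.5) and sites laid 600 kb apart across 22 synthetic
chromosomes, so the 500 kb thinning keeps every site and small tests stay
transparent; the `"dense"` layout (100 kb) exercises the thinning filter.
What the simulator deliberately does **not** model: read-level error
profiles, coverage variation, allele-frequency estimation error in the
panel, LD structure (sites are independent by construction), admixture,
and indel length spectra. Passing simulation tests therefore validates
the estimator under the model's own assumptions, not the behaviour of a
real pipeline on real genomes.

`perturbFrequencies()` supports the misspecification workflow: the
estimator is fed frequencies resampled from a Beta centred on the truth,
$f' \sim \mathrm{Beta}(\kappa f, \kappa(1-f))$ with concentration
$\kappa = 20$ by default, emulating the use of an inappropriate reference
population. Estimates shift, but the ranking of pipelines differing in
sensitivity is preserved — the property checked across 100 replicates in
the acceptance suite.

## Design utilities

Two back-of-envelope calculations that recur when planning validation
work:

* `requiredInvariantSites(u1, u2, power, alpha)` — the classical
  two-sided two-proportion normal-approximation sample size applied to
  false-positive rates $p_i = 1-u_i$. The formula is adopted because it
  reproduces the benchmark case (0.999 vs 0.9999 at 80% power,
  $\alpha = 0.05$: 10,652 positions, i.e. "at least 10,650"); the count
  is per method, and $\alpha$ and power are exposed rather than fixed.
* `fpTpRatio(specificity, variantRate, sensitivity = 1)` — expected
  false positives per true variant,
  $(1-u)(1-r)/(s\,r)$; sensitivity defaults to 1, matching the usual
  calculation that ignores missed variants.

## Problem sizes used in the shipped checks

The test suite validates the estimator at sizes chosen to make sampling
error small relative to the tolerances while keeping a laptop-scale run:
grid-search agreement on 20 instances of 50 sites against a 1001×1001
exhaustive grid; parameter recovery at 10,000 sites × 50 individuals
(median |ŝ−s| < 0.02, |û−u| < 0.002 at truth (0.95, 0.999));
simulator/model cross-validation at 100,000 sites; truth-vs-frequency
concordance over 30 individuals at 10,000 sites; rank preservation under
misspecification over 100 replicates at 2,000 sites.

## Known limitations

* Specificity estimates hinge on rare/invariant sites. With a
  common-polymorphism panel, information about *u* comes from a handful
  of expected false positives, so û is noisy and often sits exactly at 1
  for a single set; medians across many sets, or panels augmented with
  unreported sites at the $10^{-8}$ convention, mitigate this.
* At small site counts the likelihood develops a ridge coupling *s* and
  *u*; estimates remain consistent but individual fits can wander along
  it.
* Population misspecification biases both estimates (typically downward);
  rankings between pipelines are far more robust than absolute values.
* The method evaluates the pipeline's emitted call list; it cannot
  separate wet-lab from bioinformatic failure modes, and FILTER-failed
  VCF records are excluded by default (`keepFilters = c("PASS", ".")`).
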