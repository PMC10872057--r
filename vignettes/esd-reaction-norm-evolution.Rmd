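---
title: "Simulating the evolution of switchlike sex-determination reaction norms under warming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the evolution of switchlike sex-determination reaction norms under warming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdsim)
set.seed(1)
```

## The model

`esdsim` simulates a population of an ectotherm with type 1a
temperature-dependent sex determination: embryos developing at cool nest
temperatures become male, at warm nest temperatures female. The sexual
phenotype follows a switchlike (logistic) reaction norm. For an individual
with expressed phenotypes $T_{piv}$ (pivotal temperature), $s$
(reaction-norm slope, $s \le 0$ for functional ESD) and $h$ (shift
plasticity), developing at nest temperature $t_d$ in a year with mean
climate $T_{ann}$, the probability of developing male is

$$
r = \frac{1}{1 + e^{-\left(t_d - \left(T_{piv} + h\,(T_{ann} - T_{base})\right)\right)\, s}}
$$

with $T_{base} = 28$ °C the baseline climate the founders are adapted to.
Sex is assigned by comparing $r$ to an independent Uniform(0, 1) draw.

Two kinds of plasticity live inside this single curve:

* **Slope plasticity** (nonlinear): the steepness $|s|$. A steep slope
  makes sex nearly deterministic in temperature inside the historical
  range, so a warmed climate produces strongly biased (female-heavy)
  cohorts.
* **Shift plasticity** (linear): $h$ moves the expressed pivotal
  temperature in proportion to the annual climate anomaly, tracking warm
  years and buffering sex-ratio biases.

One algebraic choice deserves note: the slope enters as a *multiplier* of
the logistic exponent. Under this convention steepness grows with $|s|$,
the level ordering low/medium/high = $-0.5/-1.5/-5$ is monotone in
steepness, and a slope near zero is a flat norm — which is exactly why a
mean slope above $-0.1$ is classified as loss of ESD (genotypic sex
determination, GSD). The convention is recorded in every metadata file
written by `write_outputs()`.

### Genetics

Each individual carries three diploid loci — $T_{piv}$, slope, shift —
with two real-valued alleles each; the expressed phenotype at a locus is
the mean of its two alleles. Offspring receive one allele per locus from
each parent, drawn uniformly from that parent's pair, independently
across loci. Each hatchling is a mutant with probability 0.02 (one
Bernoulli draw per offspring); a mutant perturbs *both* alleles at every
evolvable locus with independent Gaussian deviates (SD 0.08 °C for
$T_{piv}$, 0.1 for shift, 0.02 for slope). Allele values are never
clamped: slope alleles may drift across zero, and the GSD classification
handles the resulting near-flat norms downstream. Clamping would hide the
loss-of-ESD outcome that is one of the model's three endpoints.

### Climate

Climate is a two-level Gaussian hierarchy: the annual mean $T_{ann} \sim
N(T_{glob}, SD_{bw})$, and each nest's temperature $t_d \sim N(T_{ann},
SD_{wi})$ with $SD_{wi} = 1.2$ °C. One nest temperature is drawn per
clutch and shared by all siblings; it becomes each offspring's
developmental temperature for life. Warming is abrupt: founders adapted
to 28 °C are dropped into a climate with $T_{glob} \in \{28, 30, 32\}$ °C
from year one. Draws are not truncated and there is no climate
autocorrelation, no gradual ramp, and no maternal nest-site choice.

### Demography

Each year: every adult female takes one male mate uniformly at random
(with replacement) and lays one clutch. Clutch size is

$$
CS = F_{scale}\, t_d^{\,\Phi}\; \frac{OSR}{OSR + M_{lim}}
$$

where $t_d$ is the *mother's own* developmental temperature
($F_{scale} = 0.02$, $\Phi = 2$ keeps clutches roughly 10–25 eggs over
22–35 °C), and $OSR$ is the proportion of males among adults at breeding
time. With $M_{lim} = 0.01$ male limitation only bites when males drop
below about 10% of adults. Warm-developing females are thereby more
fecund — the sex-differential fitness that maintains ESD — while
female-only populations cannot reproduce at all.

After breeding, each adult dies with probability 0.1; juveniles then
survive density-dependent first-year mortality
$1 - e^{-0.01\, n_{adults}}$ (using the post-mortality adult count — the
juveniles compete with the adults they are about to join) and recruits
mature into the adult pool. A replicate starts from 500 founders whose
developmental temperatures are drawn around the 28 °C baseline (an
established population that then experiences warming) and runs up to
`t_max` years, terminating early if the adult population becomes empty
or single-sex — under warming, in practice, 100% female.

The real-valued clutch size is rounded to the nearest integer by default;
`cs_rounding = "stochastic"` instead rounds up with probability equal to
the fractional part. The two are indistinguishable at the population
level; the option exists because rounding is the one place where a
real-valued model must commit to discreteness.

## Scenario design

`scenario_grid()` crosses 2 plasticity types × 3 levels × 3 climates × 2
variability treatments into 36 scenarios. In *slope* scenarios the
pivotal temperature and slope are evolvable, shift is fixed at 0; in
*shift* scenarios the pivotal temperature and shift are evolvable, slope
is fixed at −5. The fixed trait always sits at the level that least
buffers sex ratios, maximising the selective pressure under warming.
Replicates are enumerated deterministically with consecutive logged seeds
(`base_seed`, `base_seed + 1`, …) rather than sampling scenarios at
random — identical design coverage, strictly better reproducibility.
Every parameter (mutation rate and ranges, mortality, fecundity,
founder SDs, level values) is an explicit `esd_scenario()` knob, which is
what makes sensitivity analyses configuration-only.

One inconsistency in the source parameterisation is worth flagging: the
stated mutation SD for slope (0.02) does not equal 2% of the plausible
slope range (−5–0 would give 0.1). The tabulated value 0.02 is used as
the default; `mutvar_slope` overrides it.

## A worked run

A moderate-warming, high-slope-plasticity replicate, shortened to 1500
years:

```{r run, eval = FALSE}
sc <- esd_scenario("slope", "high", t_glob = 30, sd_bw = 0.75,
                   t_max = 1500)
rep1 <- run_replicate(sc, seed = 1)
rep1
tail(rep1$years[, c("year", "n_adults", "adult_male_fraction",
                    "mean_tpiv", "mean_slope")], 3)
```

Typical behaviour: cohorts are strongly female-biased immediately after
warming, frequency-dependent selection then drives the mean pivotal
temperature up to the new climatic mean (≈30 °C) and the adult sex ratio
back to parity. The same machinery exposes the study's other endpoints:
extinction (replicates that run out of males before the pivotal
temperature catches up, concentrated in hot, low-variability climates)
and loss of ESD (slope evolving above −0.1).

## Diagnostics and oracles

`expected_cohort_male_fraction()` integrates the reaction norm against
the within-year nest-temperature density with adaptive quadrature. For a
cohort of a single genotype this is the exact expected male fraction, so
simulated one-year cohorts can be checked against it to within binomial
sampling error — the package's own tests do exactly that, alongside
closed-form checks of the logistic (value 0.5 at the inflection,
point symmetry, monotonicity) and of the demographic formulas.

## Problem sizes and what the tests show

The full study design (36 scenarios × ~25 replicates × up to 50,000
years) is a cluster-scale computation. The package's tests and the
bundled acceptance script instead use deliberately scaled-down versions
chosen because the relevant dynamics resolve early: the pivotal
temperature under moderate warming plateaus well before 5000 years
(three replicates of 5000 years reproduce the final $T_{piv} \approx
30$ °C endpoint), and the extinction/variability contrast at 32 °C is
already decisive with 20 replicates of 3000 years per variability arm.
Long-horizon, mutation-limited endpoints — shift plasticity grinding past
0.8, pivotal temperatures completing the climb to 32 °C — are only
checked directionally at this scale.

Passing tests therefore show that the implemented mechanisms interact as
described under the stated distributions; they do not validate the model
against any real population, nor explore the supplementary sensitivity
sweeps, which are left to the configuration knobs.

## Known limitations

* No age structure beyond juvenile/adult, no linkage, dominance or sex
  chromosomes, no spatial structure or migration.
* Abrupt warming only; a gradual ramp would need assumptions about the
  relative pace of mutation supply and warming.
* Extinction is declared on the post-recruitment adult pool; a
  population rescued and lost within the same year differs by at most
  one year from a pre-recruitment rule, immaterial at these horizons.
* The operational sex ratio is evaluated at breeding time, before that
  year's adult mortality, since mortality follows breeding.
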