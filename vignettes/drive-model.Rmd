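---
title: "Modelling homing-based synthetic selfish elements: assumptions, parameters and validation"
author: "sseDrive authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling homing-based synthetic selfish elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sseDrive)
```

## The model

A homing drive is a nuclease cassette sitting inside its own recognition
site. In a drive/target heterozygote the nuclease cuts the homologous
chromosome; repair either copies the cassette into the break (homing) or
destroys the site by end-joining. `sseDrive` tracks the drive locus as four
allele classes — cleavable target `T` (GFP-marked), drive-capable donor
`D`, non-functional homed donor `DN`, and end-joining resistance allele
`N` — and all inheritance dynamics reduce to one non-Mendelian rule: the
gamete output of a `D/T` **male**. With cleavage rate $c$, homing fraction
$h$ and functional-homing fraction $\varphi$,

$$P(D) = \tfrac12 + \tfrac12 c h \varphi,\qquad
  P(D^N) = \tfrac12 c h (1-\varphi),\qquad
  P(N) = \tfrac12 c (1-h),\qquad
  P(T) = \tfrac12 (1-c).$$

Every other genotype, and every female, transmits its two alleles 1/2 :
1/2. `D`, `DN` and `N` are all refractory to further cleavage, so the `T`
frequency can only fall — the package's monotonicity tests rest on exactly
this.

Key modelling assumptions, all deliberate simplifications of the biology:

* **Male-limited homing.** The drive construct is expressed from a
  spermatogenesis promoter. Maternal crosses do show low residual activity
  (1.4–21.3% GFP loss depending on construct), but the population model
  excludes it: the rates entering the model are the paternal-cross
  estimates, and simulated females are always Mendelian. For constructs
  with substantial female activity this understates spread.
* **Phenotypic cleavage rate.** $c$ is the observed GFP-loss fraction.
  In-frame end-joining and sister-chromatid repair restore GFP invisibly,
  so $c$ underestimates true cutting; the model deliberately uses the
  observable rate because that is what the assay measures and what the
  trajectory data are scored against.
* **Homed and original donors are pooled.** A successfully homed cassette
  behaves exactly like a released one (class `D`); marker differences
  between them are not tracked.
* **No fitness costs,** no parent-of-origin effects, no co-conversion of
  flanking markers, no age or spatial structure, non-overlapping
  generations.

## The stochastic simulator and its oracle

One generation of `stepGeneration()`:

1. each female is assigned one father drawn uniformly at random from the
   males (with replacement across females — one male can sire several
   broods);
2. each female lays `eggsPerFemale` eggs (default 40, the measured brood
   size in this system); each egg draws one gamete from each parent and a
   sex with probability 1/2;
3. all offspring survive (equal survival and fertility across genotypes);
   if the pool exceeds `cap` a uniform random subset of exactly `cap`
   founds the next generation.

The caged experiments this emulates re-sampled ~100 (TALEN) or ~400 (ZFN)
flies per generation with some tolerance; the model uses an exact cap,
which changes nothing in expectation and little in variance. If a
generation ends with no males or no females the run is flagged extinct and
its trajectory padded with terminal records rather than raising an error,
since sex loss is a legitimate outcome of small-cage stochasticity.

The deterministic counterpart, `recursionStep()`, propagates genotype
frequencies through the identical mating scheme in an infinite population:
next-generation frequencies are the female-frequency x male-frequency
weighted sum of cross offspring distributions. Because every stochastic
ingredient (father choice, gamete draw, sex, capping) is unbiased, the
recursion is the exact expectation of the simulator; the test suite checks
this to within three standard errors over 500 single-generation replicates,
and checks the martingale property of neutral ($c = 0$) transmission.

**Sex-ratio convention.** Random mating weighs the two parental pools
equally, so when a release skews the sex ratio the expected next-generation
allele frequency is the *sex-averaged* one, not the count-based one. For
the refractory control (25 drive males added to 50 + 50 residents) the
count-based release frequency is 10.0% but the expectation from generation
1 onward is $(0 + 25/150)/2 = 1/12 \approx 8.3\%$; the flatness tests are
anchored there. `Population` objects report count-based frequencies (what
an experimenter scoring flies would measure); `SexStructuredState` reports
the sex-averaged ones, which coincide from generation 1 on.

**Seeding.** Each iteration derives its own substream seed from the master
seed and the iteration index via a multiplicative hash (kept below
$2^{31}$), so runs are reproducible bit-for-bit and iteration results do
not depend on how many iterations are requested.

## Assay estimation

`classifyPhenotype()` maps the marker readout (dominant `mini-white`,
recessive `curled`, GFP, and RFP-or-PCR) to chromosome fates; the `curled`
marker sits on the donor chromosome in the TALEN line and on the target
chromosome in the ZFN lines, which `markerMap()` encodes. The estimators
are then simple ratios over the white-eyed (target-chromosome) progeny:
$\hat c$ = GFP-loss fraction, $\hat h$ = homed fraction of the
homing-assayed subset, total homed $= \hat c \hat h$, resistance fraction
$= \hat c (1 - \hat h)$. The homing denominator is explicit
(`nHomingAssayed`) because PCR-based scoring covers only a subset of the
GFP-loss flies; zero denominators yield flagged `NA`s, never silent zeros.

Confidence intervals are Wilson score intervals: they are proper on
boundary estimates (0 or 1), never leave $[0,1]$, and have near-nominal
coverage at the assay's sample sizes (exact coverage by binomial
enumeration is 0.948–0.951 at the sizes used here; the suite verifies both
the enumeration and Monte-Carlo agreement with it). For the derived
products $\hat c\hat h$ and $\hat c(1-\hat h)$ no exact interval exists;
the package reports a Wilson interval on the implied count out of all
target chromosomes, an approximation adequate for the large assay counts
this readout uses.

The 1:1 segregation test is a plain one-degree-of-freedom chi-square
goodness-of-fit, $(n_A - n_B)^2/(n_A + n_B)$, with **no** continuity
correction — at the brood sizes involved (hundreds of progeny) the
correction is negligible and the uncorrected statistic matches the
control-cross arithmetic reported for this system. `functionalHomingFraction()` counts a
cross as drive-positive only when the deviation is significant *and* in
the GFP-deficit direction, since the biological readout is loss of GFP; a
symmetric count is available behind `directional = FALSE`.

## The synthetic-data generator

`simulateAssayProgeny()` draws the fates of $n$ target chromosomes as one
multinomial over (unmodified $1-c$, functionally homed $ch\varphi$,
non-functionally homed $ch(1-\varphi)$, misrepair $c(1-h)$) and can emit
the per-fly phenotype table the classifiers consume. Chromosome fates are
independent — the mass matings of the real assay provide no brood
structure worth emulating. `simulateF2Crosses()` emulates the
functional-homing readout as a two-component mixture: a cross is
functional with probability $\varphi$ and its progeny GFP-positive
fraction is binomial around 0.138 (the fraction observed in active
crosses, chosen so the simulated test power matches the observed regime);
non-functional crosses segregate 1:1.

What passing the synthetic-data tests does **not** show: robustness to
brood structure (family-correlated outcomes), scoring error, PCR dropout,
marker co-conversion, or fitness costs — none of which the generator
produces, because the model excludes them.

## Numerical and design choices

* Genotypes are unordered allele pairs in a fixed canonical order
  (`D < DN < N < T`); there are 10 pairs x 2 sexes.
* Distribution sanity is enforced at 1e-12 (gamete/offspring sums) and
  1e-9 (state frequency sums).
* Percentages in output tables are rounded to one decimal with R's
  round-half-even; the exact fractions are always emitted alongside, so
  rounding is presentation, not data.
* Extinction handling, the exact cap, Bernoulli(1/2) offspring sex, and
  sampling fathers with replacement are the simplest choices consistent
  with the stated mating scheme; none biases the expectation.
* Simulation problem sizes in the test suite (500 single-generation
  replicates; 200 replicate runs for martingale/control flatness; 300–500
  seeds for coverage) were chosen to put three-standard-error bands well
  inside scientifically meaningful deviations while keeping the full suite
  around a minute on a laptop core.

## A complete run

```{r example}
# measured ZFN-construct rates
params <- paramsZFN()

# deterministic expectation for the 100-into-400 release
s0 <- sexStructuredState(c("D/T" = 1/3, "T/T" = 2/3), c("T/T" = 1))
det <- runRecursion(s0, params, 15)
round(tail(trajectoryRecords(det), 3)[, c("generation", "gfp_negative")], 3)

# 30 stochastic replicates of the same regime
trajs <- runSimulation(releaseSpec(100, 200, 200), params, cap = 400,
                       generations = 15, iterations = 30, seed = 1)
round(tail(summarizeTrajectories(trajs), 1), 3)
```

The deterministic curve rises from 8–10% to ~75% GFP-negative alleles in 15
generations; stochastic replicates scatter around it, with occasional slow
invasions — the variability seen between replicate cages is a property of
the system, not noise in the method.

## Known limitations

* Maternal drive activity is excluded (above); constructs with leaky
  female expression will spread faster than predicted.
* $c$ is the phenotypic cleavage rate; true cutting rates are higher.
* The cap is exact; experimental re-sampling tolerance is not modelled.
* Wilson intervals on the product rates are approximate.
* No fitness costs: where drive loads are costly the model's invasion
  speeds are upper bounds.
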