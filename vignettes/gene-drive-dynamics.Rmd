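---
title: "Modelling homing gene drive dynamics with drivesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling homing gene drive dynamics with drivesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

drivesim simulates a CRISPR homing gene drive at a single locus in a large,
closed, randomly mating population of constant size, through discrete and
nonoverlapping generations. This vignette is the package's account of the
model: its assumptions, the conventions adopted where several readings were
defensible, the numerical choices, and what the simulations can and cannot
say about real populations.

## The life cycle

The state between generations is the vector of allele frequencies
$P = (p_D, p_W, p_R)$ for the drive, wild-type, and resistant alleles.
Each generation runs four modules in a fixed cycle:

**Zygote formation** (`form_zygotes()`). Diploid genotype frequencies are the
outer product of $P$ with itself, corrected for inbreeding $F$:
$G_{ii} = p_i^2 + F p_i (1 - p_i)$, heterozygotes
$H_{ij} = 2 (1 - F) p_i p_j$. The textbook two-allele form uses
$p_j = 1 - p_i$; with three alleles we use the standard multi-allele
generalization $F p_i (1 - p_i)$ for the homozygote excess, which reduces to
the two-allele form. Internally each heterozygote's mass is split across the
two symmetric cells of the genotype matrix, so `sum(G) == 1` and collapsing
back to allele frequencies is a row sum.

**Homing conversion** (`convert_heterozygotes()`). In drive heterozygotes a
mass $\Delta G = x / n$ with $x \sim \mathrm{Binomial}(n, c_j H)$ moves to
the drive homozygote class, where $c_j$ is the conversion efficiency $c$ on
wild-type and the resistance level $R \le c$ on resistant alleles. Two
conventions are worth stating. First, the binomial trial count is the
population size $n$, not the heterozygote count; the expectation
$c_j H n$ is the same under either reading and the variance differs only
marginally, but with $n$ trials the draw can, with small probability, exceed
the available heterozygote mass, so $\Delta G$ is clamped at $H$. Second,
$H$ is the *full* heterozygote frequency $2(1-F)p_i p_j$: with $c = 1$ and
no selection this yields the classic full-homing recursion
$1 - p' = (1 - p)^2$, which the test suite checks to machine precision.

**Selection** (`apply_selection()`). Genotypes with no drive allele have
fitness 1. A drive-carrying genotype of frequency $G$ loses mass $x/n$ with
$x \sim \mathrm{Binomial}(\mathrm{round}(e G n), d_{\mathrm{eff}} s)$:
$s$ is the fitness cost, $e$ the fraction of the population exposed to the
selective pressure, and $d_{\mathrm{eff}}$ the dominance weight — $d$ for
any genotype heterozygous for the drive (including drive/resistant) and 1
for the drive homozygote, since dominance is defined on heterozygotes and
homozygotes bear the full cost. We draw the *killed* mass with probability
$d_{\mathrm{eff}} s$ rather than survivors with probability
$1 - d_{\mathrm{eff}} s$; the two formulations are distributionally
complementary, and the killed reading has the property that a neutral drive
($s = 0$) is exactly untouched, which we take as non-negotiable. Fractional
trial counts are rounded to the nearest integer (unbiased to first order).
After removal all genotype frequencies are rescaled to sum to 1.

**Genetic drift** (`apply_drift()`). Wright–Fisher resampling of the gamete
pool: $p_i' = x_i / 2n$, $x_i \sim \mathrm{Binomial}(2n, p_i)$ independently
per allele. Independent binomial draws do not sum to 1, so the vector is
renormalized; a single-multinomial alternative (one draw of the $2n$
gametes, which sums to 1 by construction) is available via
`drift_method = "multinomial"`. Alleles at frequency exactly 0 or 1 are not
resampled: they are absorbing, as there is no mutation in the model.

### Module order and drive timing

The cycle is: zygote formation → (post-zygotic: conversion) → selection →
(prezygotic: conversion) → collapse to alleles → drift. A post-zygotic drive
homes in the newly formed zygote, so surviving drive carriers are
homozygous and selection sees them with full cost; a prezygotic drive homes
during gametogenesis, after selection has acted on the (still heterozygous)
parents. This ordering difference is the entire distinction between the two
timings and has a first-order effect on how much cost the drive pays per
generation of spread.

Generation 0 is an allele-frequency state: the drive enters at its release
frequency (default 0.001), the resistant allele at its initial frequency,
wild-type at the remainder; genotypes are first formed at the start of
generation 1. When the drive frequency hits exactly 0 or exactly 1 the rest
of the trajectory is frozen — both boundaries are absorbing, so this is a
pure optimization with identical semantics.

## Parameters

| parameter | range | default | meaning |
|---|---|---|---|
| `conversion` (c) | [0, 1] | — | homing probability on wild-type, per generation |
| `resistance_level` (R) | [0, c] | 0 | homing probability on the resistant allele; 0 = immune |
| `resistance_frequency` | [0, 0.4] | 0 | initial resistant-allele frequency (minor variants) |
| `fitness_cost` (s) | [0, 1] | 0 | selection coefficient against drive carriers |
| `exposure` (e) | [0, 1] | 1 | fraction of the population under selection each generation |
| `dominance` (d) | [0, 1] | 0.5 | weight of the cost in heterozygotes (0 recessive, 1 dominant) |
| `inbreeding` (F) | [0, 1] | 0 | excess homozygosity at zygote formation |
| `pop_size` (n) | ≥ 1 | 1e6 | constant diploid population size |
| `generations` | ≥ 1 | 500 | simulated horizon |
| `initial_drive_frequency` | (0, 1) | 0.001 | release frequency |

All rates are per generation and unitless. The scenario constructor stores
the *absolute* resistance level and enforces $R \le c$; the Monte Carlo
sampler constructs it as a uniform ratio times the conversion efficiency, so
the constraint holds by construction, and records the ratio alongside.

## Outcome classification

A trajectory is reduced to its maximum frequency, the first generation
attaining it, its final frequency, and the *gradient* over the last 20
generations. Thresholds: fixation (final > 0.90), loss (max < 0.10),
temporary (max > 0.30 and final < 0.10), equilibrium (final in
[0.10, 0.90) and |gradient| < 1e-4). The four rules are mutually exclusive
given final ≤ max — a brute-force enumeration over the threshold grid is
part of the test suite — and anything else, e.g. a peak between 0.10 and
0.30 or a trajectory still moving at the horizon, is unclassified. All
comparisons are strict except the lower equilibrium bound, so exact ties
fall to unclassified.

The gradient needed a convention: "change over the last 20 generations" does
not name an estimator. The default is the mean per-generation change
$(p_T - p_{T-20}) / 20$, which keeps the $10^{-4}$ plateau threshold
commensurate with drift noise at $n = 10^6$ (one generation of drift has
standard deviation $\approx 3.5 \times 10^{-4}$ at $p = 0.5$; the
20-generation mean change $\approx 8 \times 10^{-5}$). A least-squares slope
over the same window is available via `gradient_method = "slope"`; its
sampling variance on a random-walk plateau is slightly *larger* than the
difference estimator's, so the default is also the more stable choice. Note
that the equilibrium rate — by far the rarest outcome — is the one quantity
that is genuinely sensitive to this convention, because the |gradient|
threshold cuts through a smooth part of the gradient distribution: halving
the threshold roughly halves the equilibrium count in our batches. The
other outcome rates are insensitive to it.

## Stochastic and deterministic engines

Stochastic mode draws every binomial at population size $n = 10^6$, which
makes demographic noise small but not negligible over 500 generations.
Deterministic mode propagates expectations and is used for closed-form
validation: the neutral full-conversion recursion, the resistance ceiling
(with an immune resistant allele and no selection the drive converges to
$1 - p_R$ and never exceeds it), and monotonicity of the dynamics in the
selection and conversion parameters. The test suite also checks that the
mean of 200 stochastic replicates tracks the deterministic trajectory
pointwise within 3 Monte Carlo standard errors under the reference
equilibrium preset.

The generation loop exists twice: a compiled Rcpp loop used everywhere
performance matters, and a pure-R loop composed from the exported
per-operation functions. The two are mirrored arithmetic operation for
arithmetic operation (including long-double accumulation where R's `sum()`
and `rowSums()` use it) and make identical RNG calls in identical order, so
identical seeds produce bit-identical trajectories; the suite asserts this
across timings, modes, and drift methods. This parity is the package's main
guard against implementation drift between the readable specification of
the model (the R operations) and the fast path.

## Monte Carlo framework

`run_monte_carlo()` samples conversion, fitness cost, exposure, dominance,
and inbreeding uniformly on [0, 1], resistance frequency uniformly on
[0, 0.4], and the resistance level as a uniform ratio of conversion — a
deliberately prior-free exploration of the design space. Simulation $i$ of a
batch is wholly determined by (root seed, $i$): the RNG is reseeded with the
child seed for each index, so batches are reproducible, order-independent,
and prefix-consistent (a 30-draw batch is the first 30 rows of a 60-draw
batch). `balanced_sample()` uses the same scheme and simply keeps drawing
until each classified outcome reaches its quota, so its records are exactly
the quota-filtered rows of the equivalent plain batch — a property the test
suite asserts. Unclassified simulations stay in the denominators of
`outcome_frequencies()` (the total classified fraction is below 100%) but
are excluded from balanced samples and regressions.

`regress_within_outcome()` fits ordinary least squares with main effects and
an intercept on the raw variable scales; with seven bounded, independently
sampled regressors there is no collinearity in practice, and rank
deficiency (e.g. from degenerate user-supplied records) is an explicit
error. Regression on time-to-max within the equilibrium and temporary
outcomes recovers large negative conversion and large positive inbreeding
coefficients — fast homing shortens the climb, inbreeding starves the drive
of the heterozygotes it needs — while the equilibrium plateau height rises
with resistance level and falls with exposure, and the temporary peak falls
with resistance frequency (the immune fraction is the drive's ceiling).

Problem sizes in the tests are chosen to keep the whole suite in the
minutes range while leaving Monte Carlo tolerances (3 binomial standard
errors at the realized batch size) meaningful: 5,000 draws per timing for
outcome tables, 2,000 records per outcome for the balanced regressions,
10,000 replicates for module-level moment checks, and 200 seeds for the
stochastic-versus-deterministic comparison.

## What the generator does and does not emulate

The sampler explores drive *designs* under idealized population genetics:
one panmictic population of constant size, no spatial structure or
migration, no age structure or overlapping generations, no sex-specific
inheritance or homing, and — importantly — no de novo resistance: resistant
alleles exist only as standing variation at release, and neither
nonhomologous end joining after failed homing nor target-site mutation can
create new ones during a run. Consequently, passing tests demonstrate the
internal consistency of the sampling model and its classification layer,
not field-scale predictions: in real releases resistance generation,
spatially heterogeneous selection, and demographic feedback (suppression
shrinking $n$, strengthening drift) can all move outcomes, and all are out
of scope here. Population size is held constant even when selection removes
a large fraction of carriers each generation — the model describes a
replacement drive in a demographically buffered population.

## Numerical conventions

Frequency vectors and genotype matrices are validated to sum to 1 within
1e-9 at the module boundaries; internal steps conserve mass exactly up to
floating point. Binomial draws are clamped so no genotype mass goes
negative. Exact 0 and exact 1 are preserved through every module, which is
what makes the absorbing-boundary freeze sound. Ties at classification
thresholds go to unclassified. Child seeds are `(seed + index) mod 2^31-1`
so they stay within R's integer range. CSV and configuration output writes
doubles at shortest round-trip precision, so write → read → write is
byte-identical.
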