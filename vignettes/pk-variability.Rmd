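---
title: "Methods: hierarchical meta-analysis of PK variability and uncertainty factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical meta-analysis of PK variability and uncertainty factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `pkvar`, the
assumptions it makes, the defaults it ships, and the choices taken where
several reasonable designs existed.

## The data and what is assumed about them

The unit of observation is one published study's summary of one
pharmacokinetic parameter (AUC, Cmax or clearance) for one probe
substrate and route: a sample size `n`, a central statistic, a dispersion
statistic, and dosing information. Individual PK values are assumed
lognormal — the standard assumption for concentration-type parameters —
so the natural summaries are the geometric mean (GM) and geometric
standard deviation (GSD). Reported arithmetic summaries are converted by
exact lognormal moment matching:

$$\mathrm{GM} = \frac{X}{\sqrt{1+\mathrm{CV}^2}},\qquad
  \mathrm{GSD} = \exp\!\left(\sqrt{\ln(1+\mathrm{CV}^2)}\right),\qquad
  \mathrm{CV} = \mathrm{SD}/X,$$

with SE rescaled by $\sqrt{n}$ and CVs taken as fractions (percentages in
source files must be converted by the user; silent percent-vs-fraction
confusion is the dominant error mode in this literature, so no guessing
is done). `gm_gsd_to_am_sd()` is the exact inverse; the pair round-trips
to $10^{-12}$ relative error over CV $\in [0,5]$ (asserted in the test
suite).

Doses are normalised to mg/kg body weight before dividing AUC and Cmax by
dose. When a study reports no body weight, a continent-level default is
used. Those defaults are *configuration*, shipped as the regional mean
adult body masses of Walpole et al. (2012, BMC Public Health 12:439) and
editable via `normalization_config()`, because the appropriate values
depend on the geography labels of the database at hand. Substrates
conventionally dosed per body surface area (SN38 by default) divide by
the reported BSA instead, falling back to 1.79 m². Canonical units are
ng·h/mL per mg/kg (AUC), ng/mL per mg/kg (Cmax) and mL/min/kg
(clearance); clearance reported in L/h/kg is converted by the single
factor 1000/60.

## The hierarchical model

For substrate $j$ and study $i$ with $n_{ij}$ subjects, writing
$y_{ij} = \ln \mathrm{GM}_{ij}$ and $s_{ij} = \ln \mathrm{GSD}_{ij}$:

$$m_{ij} \sim N(\mu_j,\ \sigma^2_{\mathrm{study},j}), \qquad
  y_{ij} \mid m_{ij} \sim N(m_{ij},\ \sigma^2_{\mathrm{ind},j}/n_{ij}),$$
$$\frac{(n_{ij}-1)\, s_{ij}^2}{\sigma^2_{\mathrm{ind},j}} \sim
  \chi^2_{\,n_{ij}-1} \quad (n_{ij} \ge 2).$$

The three named variance components are the substrate-level
interindividual SD $\sigma_{\mathrm{ind},j}$, the interstudy SD
$\sigma_{\mathrm{study},j}$, and — when several substrates of an isoform
are pooled — the intersubstrate hyper-level
$\ln \sigma_{\mathrm{ind},j} \sim N(M, S^2)$. This is the minimal model
that produces those components from summary data: the study mean and
log-GSD are sufficient statistics for a lognormal sample, and both enter
through their exact sampling distributions. The dispersion term is
implemented as the equivalent Gamma density of the observed $s_{ij}^2$
(shape $(n-1)/2$, rate $(n-1)/2\sigma^2_{\mathrm{ind},j}$), i.e. the
chi-square statement written as a proper density of the data; the test
suite checks the implementation against an independently coded
chi-square-plus-Jacobian oracle at $10^{-10}$.

Degenerate inputs are handled explicitly: studies with $n_{ij}=1$ (or a
reported GSD of exactly 1) contribute only their mean term, whose
marginal variance is then $\sigma^2_{\mathrm{study},j} +
\sigma^2_{\mathrm{ind},j}$; they inform the substrate mean but not the
dispersion.

### Priors

Defaults (all overridable through `prior_config()`):

* $\mu_j \sim N(0, 10^2)$ on the log scale — effectively flat over any
  plausible dose-normalised GM;
* $\sigma_{\mathrm{ind},j},\ \sigma_{\mathrm{study},j} \sim
  \mathrm{HalfNormal}(1)$ — weakly informative, covering GSDs of roughly
  1–5;
* $M \sim N(-1, 1^2)$, $S \sim \mathrm{HalfNormal}(0.5)$ — centred on
  $\sigma_{\mathrm{ind}} \approx 0.37$ (CV $\approx$ 0.38), wide enough
  to reach both tight (CV 0.1) and extreme (CV > 1) substrates.

Compounds whose kinetic variability has been meta-analysed before (in
this field, zidovudine and oxazepam) can carry informative normal priors
on $\ln \sigma_{\mathrm{ind},j}$ via `informative_overrides`; an override
replaces the hyper-level term for that substrate. The historical prior
values are not shipped because the cited source does not print them; the
mechanism is the contribution here.

## Sampling and numerical choices

The sampler is a componentwise adaptive random-walk
Metropolis-within-Gibbs:

* Study effects $m_{ij}$ are integrated out analytically
  (normal–normal), so the sampled space is only $(\mu_j,
  \ln\sigma_{\mathrm{ind},j}, \ln\sigma_{\mathrm{study},j}, M, \ln S)$ —
  8 coordinates for a two-substrate fit regardless of study count. The
  marginalisation is exact, not an approximation.
* SDs are sampled in log space (with the Jacobian) to avoid boundary
  rejections; $\tau_j = 1/\sigma^2_{\mathrm{ind},j}$ is derived from
  draws, never a sampled coordinate.
* The hyper-mean $M$ has a conjugate normal full conditional and is
  Gibbs-updated exactly each iteration, which removes the dominant
  autocorrelation in the hyper level.
* Proposal scales adapt toward 44% acceptance in batches of 25 during
  warmup and are frozen afterwards, keeping the retained chain Markov.
* Per-chain seeds are derived deterministically from the master seed, so
  identical configurations give bit-identical draws (and byte-identical
  CSV exports, which the pipeline manifest checksums rely on).

Defaults are 3 chains × 1000 warmup + 2500 kept draws, which on the
reference problems gives split-$\hat R$ < 1.05 and ESS above 400 for all
parameters; failures flag the result and warn rather than erroring.
Split-$\hat R$ and ESS (Geyer initial-monotone truncation of the
split-chain autocorrelation sum) are implemented in the package and
validated on constructed chains: iid normals, a deliberately shifted
chain, an AR(0.95) process, and constant (degenerate) chains.

Posterior summaries use *order-statistic* (type-1) quantiles. This is
deliberate: medians then commute exactly with the monotone maps
$\sigma \mapsto \mathrm{CV} \mapsto \mathrm{UF}$, so the reported UF
median is exactly the UF of the reported CV median, a consistency
property the test suite asserts at $10^{-9}$. With thousands of draws the
difference from interpolated quantiles is far below Monte-Carlo noise.

## From draws to uncertainty factors

Per draw, $\mathrm{CV} = \sqrt{\exp(\sigma^2_{\mathrm{ind}})-1}$ and
$\mathrm{UF}_p = \exp(z_p\,\sigma_{\mathrm{ind}})$ — the ratio of the
$p$-th percentile of the lognormal population distribution to its median.
A dimensionally consistent reading of the published CV formula requires
$\sigma^2 = 1/\tau$; with that reading the analytic CV→UF map reproduces
(after half-up rounding to one decimal) the published UF pairs for every
per-substrate AUC/clearance table row checked, which is the package's
analytic acceptance layer.

**Overall rows.** How the isoform-level "overall" row is computed from a
multi-substrate fit is genuinely open; this package uses the standard
meta-analytic *predictive* choice: per posterior draw, a new substrate's
$\sigma_{\mathrm{ind}}$ is drawn from the hyper level as $\exp(M + Sz)$,
$z \sim N(0,1)$ (seeded from the fit's master seed), and the overall
log-GM is the mean of the substrate log-means; study and subject counts
are summed. Overall intervals are therefore wider than any single
substrate's — they include intersubstrate variability. With a single
substrate the substrate row *is* the overall row, matching the reporting
convention for single-compound isoforms. Report-time rounding is half-up
(CV to integer percent, UFs to one decimal) and is never applied
internally.

## The synthetic generator: what it does and does not emulate

`synthetic_scenario()` emulates the statistical structure of a collated
PK literature database: lognormal individuals, study-level random
effects, several substrates per isoform, study sizes in the published
6–80 range, total-mg dosing with body weights around 70.8 kg and 20%
missing at random, and mixed reporting (55% AM/SD, 15% each AM/SE, AM/CV,
GM/GSD — literature databases of this kind are dominated by AM/SD
reporting). Presets mirror published isoform tables in study counts,
study sizes and CV magnitude.

It deliberately does **not** emulate: publication bias, rounding of
published summaries, covariate structure (age, sex, genotype, health
status effects), correlated parameters within a study, or
heavy-tailed/multimodal deviations from lognormality (e.g. polymorphic
subpopulations). Passing recovery tests therefore shows the chain of
standardisation + model + summarisation is self-consistent under its own
assumptions — not that real literature data satisfy those assumptions.

Validation problem sizes were chosen to make the checks sharp but cheap:
the reference recovery scenario is 2 substrates × 12 studies × 20
subjects (true CV 0.5, $\sigma_{\mathrm{study}}$ = 0.2) across 20 seeds
with 2 × 1600-iteration chains; the likelihood-concentration check uses
one 10,000-subject study, where the posterior median of
$\sigma_{\mathrm{ind}}$ must sit within 5% of the observed log-GSD.

## Known limitations

* The exact hierarchical form and prior values of earlier published
  models are not reproducible from their descriptions; this package's
  model is a declared reconstruction, validated against its own reference
  density and recovery tests rather than claimed identical to any prior
  implementation.
* The database schema is likewise a reconstruction of the quantities the
  method requires; real extractions will need mapping onto it.
* No covariate modelling: the target population is non-phenotyped healthy
  adults, and genotype effects are summarised only descriptively
  (`genotype_frequencies()`, `auc_ratio_to_wildtype()`).
* Records missing body weight are normalised with a continent default;
  if the default is biased for a geography, that bias propagates to the
  GM (not to the CV or UFs, which depend only on log-scale dispersion).
* A single-study substrate cannot separate $\sigma_{\mathrm{study}}$ from
  the prior; its interval for $\sigma_{\mathrm{study}}$ is essentially
  the prior and should be read as such.
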