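# pkvar

Hierarchical Bayesian meta-analysis of human pharmacokinetic variability
and derivation of pathway-related uncertainty factors.

## The problem

Chemical risk assessment covers human toxicokinetic variability with a
default factor of 3.16 (10^0.5). For compounds cleared predominantly by a
single enzyme pathway — for example UDP-glucuronosyltransferase (UGT)
isoforms and their probe substrates — that default can be replaced by a
pathway-related factor derived from observed pharmacokinetic (PK)
variability in humans. The raw material is published study-level summary
statistics of Cmax, AUC and clearance, which are heterogeneous in three
ways: dosing (total mg vs mg/kg vs mg/m²), reporting (arithmetic mean with
SD, SE or CV, or geometric mean with GSD), and structure (many studies per
substrate, several substrates per isoform).

`pkvar` implements the full chain for analysts doing this kind of
meta-analysis:

1. **Standardisation.** PK values are treated as lognormal. Every reported
   summary is converted to geometric summaries by moment matching,

   GM = X / √(1 + CV²),  GSD = exp(√(ln(1 + CV²))),  CV = SD / X,

   and doses are normalised per kg body weight (per m² body surface area
   for BSA-dosed compounds such as SN38), with continent-level default
   body weights filling gaps.

2. **Variance decomposition.** A three-level hierarchical Bayesian model
   separates interindividual, interstudy and intersubstrate variability.
   With μ_j the substrate log-mean, study effects and study summaries enter
   through their exact sampling distributions:

   m_ij ~ N(μ_j, σ²_study,j),  lnGM_ij ~ N(m_ij, σ²_ind,j / n_ij),
   (n_ij − 1) lnGSD²_ij / σ²_ind,j ~ χ²(n_ij − 1),

   with an isoform hyper-level ln σ_ind,j ~ N(M, S²) when several
   substrates are pooled. The posterior is sampled by an adaptive
   Metropolis-within-Gibbs sampler with split-R̂/ESS diagnostics.

3. **Uncertainty factors.** Per posterior draw, CV = √(exp(σ²_ind) − 1)
   and UF_p = exp(z_p·σ_ind), the ratio of the p-th percentile of the
   population variability distribution to its median (z₉₅ = 1.6449,
   z₉₇.₅ = 1.9600). Medians and 95% credible intervals are reported per
   substrate and for the isoform overall.

A seeded synthetic-data generator with known ground truth
(`synthetic_scenario()`, `simulate_study_summaries()`) makes every stage
testable without any external data, and `run_pipeline()` wires the stages
into one reproducible, manifest-checked analysis.

## Worked example

A small synthetic database shipped with the package mimics a
one-substrate isoform table (9 oral clearance studies, 98 subjects, true
interindividual CV 0.40):

```r
library(pkvar)

path <- system.file("extdata", "synthetic_ugt1a6_clearance.csv", package = "pkvar")
db   <- read_pk_database(path)
obs  <- normalize_database(select_analysis_set(db, "deferiprone_like",
                                               "oral", "clearance"))
fit  <- fit_pkvar(obs, mcmc = mcmc_config(seed = 1))
fit
#> Hierarchical PK variability model
#>   parameter: clearance, route: oral
#>   substrates: deferiprone_like
#>   studies: 9, subjects: 98
#>   draws: 2500 x 3 chains; converged: TRUE

build_report_table(summary(fit))
#>           compound nst  n cv_pct   gm uf95 uf95_ci uf975 uf975_ci
#> 1 deferiprone_like   9 98     42 1.68  1.9 1.8-2.2   2.2  2.0-2.5
#> 2          overall   9 98     42 1.68  1.9 1.8-2.2   2.2  2.0-2.5
```

Reading the row: across 9 studies the model estimates an interindividual
CV of 42% (the generator's truth is 40%) around a geometric mean clearance
of 1.68 mL/min/kg; 97.5% of healthy adults are estimated to fall within a
factor 2.2 (95% CI 2.0–2.5) of the median — below the default
toxicokinetic factor of 3.16. With a single substrate the overall row
equals the substrate row; with several substrates it comes from the
isoform-level predictive distribution.

The same analysis end to end, with artifacts and a checksummed manifest:

```r
run_pipeline(pipeline_config(preset = "ugt1a6_oral_clearance",
                             out_dir = "results/ugt1a6",
                             route = "oral", parameter = "clearance",
                             seed = 1))
```

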