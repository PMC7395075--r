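# Shared fixtures, built in code.

# a small mixed database covering both routes, all three parameters and
# every reporting flavour
example_records <- function() {
  data.frame(
    study_id = c("s1", "s2", "s3", "s4", "s5"),
    substrate_id = c("zidovudine", "zidovudine", "ethinylestradiol",
                     "SN38", "deferiprone"),
    isoform_ids = c("UGT2B7", "UGT2B7", "UGT1A1", "UGT1A1", "UGT1A6"),
    route = c("oral", "iv", "oral", "iv", "oral"),
    parameter = c("auc", "clearance", "auc", "auc", "cmax"),
    n_subjects = c(12L, 8L, 20L, 15L, 10L),
    dose_value = c(100, 2, 0.03, 350, 25),
    dose_basis = c("total_mg", "mg_per_kg", "total_mg", "mg_per_m2",
                   "mg_per_kg"),
    body_weight_kg = c(70, NA, NA, NA, 65),
    bsa_m2 = c(NA, NA, NA, 1.85, NA),
    geography = c("Europe", "North America", "Europe", "Asia", "Asia"),
    health_status = c("healthy", "healthy", "healthy", "patient", "healthy"),
    regimen = c("single_dose", "single_dose", "repeated_21d", "single_dose",
                "single_dose"),
    central_kind = c("AM", "GM", "AM", "AM", "AM"),
    central_value = c(5000, 20, 1200, 900, 8000),
    dispersion_kind = c("SD", "GSD", "CV_fraction", "SE", "SD"),
    dispersion_value = c(2500, 1.4, 0.3, 60, 3200),
    value_units = c("ng*h/mL", "mL/min/kg", "ng*h/mL", "ng*h/mL", "ng/mL"),
    stringsAsFactors = FALSE
  )
}

example_db <- function() pk_database(example_records())

# quick MCMC settings for unit tests (acceptance tests set their own)
quick_mcmc <- function(seed = 1, ...) {
  mcmc_config(chains = 2, warmup_draws = 400, kept_draws = 600,
              seed = seed, min_ess = 50, ...)
}

# independent half-normal log-density used by the log-posterior oracle
oracle_halfnorm <- function(x, scale) {
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}
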