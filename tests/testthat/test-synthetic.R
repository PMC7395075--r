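test_that("individual simulation is seeded and respects the moments", {
  sc <- synthetic_scenario(seed = 5)
  v1 <- simulate_individuals(sc, 1, 1, 50)
  v2 <- simulate_individuals(sc, 1, 1, 50)
  expect_identical(v1, v2)
  expect_false(identical(v1, simulate_individuals(sc, 1, 2, 50)))

  # degenerate noise collapses to exp(mu)
  sc0 <- synthetic_scenario(substrates = data.frame(
    substrate_id = "a", mu = log(100), sigma_ind = 1e-12,
    sigma_study = 1e-12, stringsAsFactors = FALSE), seed = 1)
  v <- simulate_individuals(sc0, 1, 1, 20)
  expect_equal(v, rep(100, 20), tolerance = 1e-6)

  # lognormal moment identity: sigma_ind = 0.4 gives CV 0.417 at large n
  scm <- synthetic_scenario(substrates = data.frame(
    substrate_id = "a", mu = 0, sigma_ind = 0.4, sigma_study = 1e-12,
    stringsAsFactors = FALSE), seed = 2)
  v <- simulate_individuals(scm, 1, 1, 1e6)
  expect_equal(sd(v) / mean(v), sqrt(expm1(0.16)), tolerance = 0.01)
})

test_that("simulated databases are valid, seeded, and GM <= AM per study", {
  sc <- synthetic_scenario(seed = 31)
  sim <- simulate_study_summaries(sc)
  expect_s3_class(sim$database, "pk_database")
  expect_identical(nrecords(sim$database), 24L)
  expect_identical(nrow(validate_records(sim$database)), 0L)
  expect_identical(sim$truth$substrates, sc$substrates)
  expect_equal(sim$truth$true_cv, rep(0.5, 2), tolerance = 1e-12)

  # reruns are identical; different seeds differ
  sim2 <- simulate_study_summaries(sc)
  expect_identical(sim$database$records, sim2$database$records)
  sim3 <- simulate_study_summaries(synthetic_scenario(seed = 32))
  expect_false(identical(sim$database$records, sim3$database$records))

  # per-study geometric mean never exceeds the arithmetic mean
  for (j in 1:2) {
    for (i in 1:12) {
      v <- simulate_individuals(sc, j, i, 20)
      expect_lte(exp(mean(log(v))), mean(v))
    }
  }
})

test_that("one-study one-record scenarios and pure GM/GSD mixes work", {
  sc <- synthetic_scenario(
    substrates = data.frame(substrate_id = "a", mu = 1, sigma_ind = 0.4,
                            sigma_study = 0.2, stringsAsFactors = FALSE),
    studies_per_substrate = 1, subjects_per_study = c(5, 5), seed = 4)
  sim <- simulate_study_summaries(sc)
  expect_identical(nrecords(sim$database), 1L)

  scg <- synthetic_scenario(reporting_mix = c(AM_SD = 0, AM_SE = 0,
                                              AM_CV = 0, GM_GSD = 1),
                            seed = 4)
  simg <- simulate_study_summaries(scg)
  expect_true(all(simg$database$records$central_kind == "GM"))
  expect_true(all(simg$database$records$dispersion_kind == "GSD"))
})

test_that("presets mimic the published table structure", {
  sc <- make_isoform_preset("ugt2b7_oral_auc")
  expect_s3_class(sc, "synthetic_scenario")
  expect_identical(sum(sc$studies_per_substrate), 30L)
  expect_identical(nrow(sc$substrates), 2L)
  expect_equal(cv_from_sigma(sc$substrates$sigma_ind), c(0.29, 0.28),
               tolerance = 1e-12)
  expect_error(make_isoform_preset("nope"), "ugt2b7_oral_auc")
  for (nm in c("ugt1a6_oral_clearance", "ugt1a3_oral_cmax")) {
    expect_s3_class(make_isoform_preset(nm), "synthetic_scenario")
  }
})

test_that("one giant low-interstudy study recovers sigma_ind within 5%", {
  true_sigma <- sigma_from_cv(0.5)
  sc <- synthetic_scenario(
    substrates = data.frame(substrate_id = "a", mu = log(500),
                            sigma_ind = true_sigma, sigma_study = 1e-6,
                            stringsAsFactors = FALSE),
    studies_per_substrate = 1, subjects_per_study = c(5000, 5000),
    missing_bw = 0,
    reporting_mix = c(AM_SD = 0, AM_SE = 0, AM_CV = 0, GM_GSD = 1),
    seed = 77)
  obs <- normalize_database(simulate_study_summaries(sc)$database)
  fit <- suppressWarnings(fit_pkvar(obs, mcmc = quick_mcmc(5)))
  est <- coef(fit)[["sigma_ind[a]"]]
  expect_equal(est, true_sigma, tolerance = 0.05)
})
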