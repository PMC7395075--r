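test_that("dispersion statistics convert to SD as defined", {
  expect_equal(sd_from_dispersion("SE", 2, n = 25), 10)
  expect_equal(sd_from_dispersion("CV_fraction", 0.3, mean = 50), 15)
  expect_equal(sd_from_dispersion("SD", 7), 7)
  expect_error(sd_from_dispersion("SE", 2, n = 1), "n >= 2")
  expect_error(sd_from_dispersion("GSD", 1.5), "geometric")
})

test_that("AM/SD converts to GM/GSD by lognormal moment matching", {
  expect_equal(am_sd_to_gm_gsd(100, 0), c(gm = 100, gsd = 1))
  # frozen values; cross-checked once against moments of 1e7 simulated
  # lognormal draws
  expect_equal(am_sd_to_gm_gsd(100, 50), c(gm = 89.4427, gsd = 1.6038),
               tolerance = 1e-4)
  expect_equal(am_sd_to_gm_gsd(10, 10), c(gm = 7.0711, gsd = 2.2993),
               tolerance = 1e-4)
  expect_error(am_sd_to_gm_gsd(0, 5), "> 0")
})

test_that("GM/GSD inverts back to AM/SD exactly", {
  expect_equal(gm_gsd_to_am_sd(100, 1), c(am = 100, sd = 0))
  expect_equal(gm_gsd_to_am_sd(89.4427, 1.6038), c(am = 100, sd = 50),
               tolerance = 1e-3)
  expect_error(gm_gsd_to_am_sd(10, 0.9), ">= 1")
})

test_that("the conversion pair are mutual inverses over CV in [0, 5]", {
  for (cv in c(0, 0.01, 0.05, 0.3, 1, 2.5, 5)) {
    am <- 42
    g <- am_sd_to_gm_gsd(am, cv * am)
    back <- gm_gsd_to_am_sd(g[["gm"]], g[["gsd"]])
    expect_equal(back[["am"]], am, tolerance = 1e-12)
    expect_equal(back[["sd"]], cv * am, tolerance = 1e-12)
    # GM <= AM with equality iff SD = 0; GSD nondecreasing in SD
    expect_lte(g[["gm"]], am)
    if (cv > 0) expect_lt(g[["gm"]], am)
  }
  gsds <- vapply(c(0, 10, 20, 40), function(s)
    am_sd_to_gm_gsd(100, s)[["gsd"]], numeric(1))
  expect_true(all(diff(gsds) > 0))
})

test_that("doses normalise per kg or per m2 with documented fallbacks", {
  cfg <- normalization_config()
  rec <- as.list(example_records()[1, ]) # total 100 mg, bw 70
  expect_equal(normalize_dose(rec, cfg), 100 / 70)

  rec$body_weight_kg <- NA
  rec$dose_value <- 141.6 # falls back to Europe default 70.8 kg
  expect_equal(normalize_dose(rec, cfg), 2)

  rec$geography <- "Atlantis"
  expect_error(normalize_dose(rec, cfg), "no default for geography")

  # BSA substrate: reported BSA wins, default 1.79 m2 otherwise
  sn <- as.list(example_records()[4, ])
  sn$dose_basis <- "total_mg"; sn$dose_value <- 626.5
  expect_equal(normalize_dose(sn, cfg), 626.5 / 1.85)
  sn$bsa_m2 <- NA
  expect_equal(normalize_dose(sn, cfg), 626.5 / 1.79, tolerance = 1e-12)
})

test_that("records standardise to (ln GM, ln GSD) in canonical units", {
  cfg <- normalization_config()
  # GM/GSD record at 1 mg/kg is the identity path
  rec <- as.list(example_records()[2, ])
  rec$parameter <- "auc"; rec$value_units <- "ng*h/mL"
  rec$dose_value <- 1; rec$dose_basis <- "mg_per_kg"
  out <- normalize_record(rec, cfg)
  expect_equal(out$ln_gm, log(20))
  expect_equal(out$ln_gsd, log(1.4))

  # AM/SD AUC at 2 mg/kg: composition of the verified pieces
  rec <- as.list(example_records()[1, ])
  rec$central_value <- 100; rec$dispersion_value <- 50
  rec$dose_value <- 2; rec$dose_basis <- "mg_per_kg"
  out <- normalize_record(rec, cfg)
  expect_equal(out$ln_gm, log(89.44272 / 2), tolerance = 1e-6)
  expect_equal(out$ln_gsd, log(1.6038073), tolerance = 1e-6)

  # clearance units convert L/h/kg -> mL/min/kg (x 1000/60)
  cl <- as.list(example_records()[2, ])
  cl$central_value <- 2; cl$value_units <- "L/h/kg"
  out <- normalize_record(cl, cfg)
  expect_equal(exp(out$ln_gm), 2 * 1000 / 60, tolerance = 1e-12)
})

test_that("normalisation is invariant to how an equivalent dose is coded", {
  cfg <- normalization_config()
  base <- as.list(example_records()[1, ]) # AM/SD oral auc
  a <- base
  a$dose_basis <- "mg_per_kg"; a$dose_value <- 2
  b <- base
  b$dose_basis <- "total_mg"; b$dose_value <- 140; b$body_weight_kg <- 70
  expect_equal(normalize_record(a, cfg)$ln_gm, normalize_record(b, cfg)$ln_gm)

  # and to the concentration unit the study chose
  c1 <- base; c1$central_value <- 5000; c1$dispersion_value <- 2500
  c2 <- base; c2$central_value <- 5; c2$dispersion_value <- 2.5
  c2$value_units <- "ug*h/mL"
  expect_equal(normalize_record(c1, cfg)$ln_gm, normalize_record(c2, cfg)$ln_gm,
               tolerance = 1e-12)
})

test_that("normalize_database maps every record and keeps order", {
  db <- example_db()
  obs <- normalize_database(db)
  expect_identical(nrow(obs), nrecords(db))
  expect_identical(obs$source_study_id, db$records$study_id)
  expect_true(all(is.finite(obs$ln_gm)))
  expect_true(all(obs$ln_gsd >= 0))
  expect_identical(nrow(normalize_database(pk_database())), 0L)
})
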