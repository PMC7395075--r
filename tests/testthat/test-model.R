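two_study_obs <- function() {
  data.frame(substrate_id = "zidovudine", route = "oral", parameter = "auc",
             n_subjects = c(12L, 8L), ln_gm = c(6.1, 5.8),
             ln_gsd = c(0.35, 0.42),
             source_study_id = c("a", "b"), stringsAsFactors = FALSE)
}

test_that("model specs index substrates and reject mixed slices", {
  obs <- two_study_obs()
  spec <- build_model_spec(obs)
  expect_identical(spec$substrates, "zidovudine")
  expect_false(spec$pool)

  obs2 <- rbind(obs, transform(obs, substrate_id = "codeine"))
  spec2 <- build_model_spec(obs2)
  expect_identical(length(spec2$substrates), 2L)
  expect_true(spec2$pool)

  expect_error(build_model_spec(obs[0, ]), "non-empty")
  bad <- obs; bad$route[2] <- "iv"
  expect_error(build_model_spec(bad), "route")
  one <- obs; one$n_subjects[1] <- 1L
  expect_false(build_model_spec(one)$use_gsd[1])
})

test_that("log_posterior matches an independently coded term-by-term oracle", {
  obs <- two_study_obs()
  pr <- prior_config()
  spec <- build_model_spec(obs, pr)
  params <- list(mu = 6.0, sigma_ind = 0.4, sigma_study = 0.15,
                 m = c(6.05, 5.9))

  # oracle: each density term coded separately, chi-square form with the
  # explicit change-of-variables Jacobian for the dispersion statistic
  oracle <- dnorm(params$mu, pr$mu_mean, pr$mu_sd, log = TRUE) +
    oracle_halfnorm(params$sigma_ind, pr$sigma_ind_scale) +
    oracle_halfnorm(params$sigma_study, pr$sigma_study_scale) +
    sum(dnorm(params$m, params$mu, params$sigma_study, log = TRUE)) +
    sum(dnorm(obs$ln_gm, params$m, params$sigma_ind / sqrt(obs$n_subjects),
              log = TRUE)) +
    sum({
      q <- (obs$n_subjects - 1) * obs$ln_gsd^2 / params$sigma_ind^2
      dchisq(q, obs$n_subjects - 1, log = TRUE) +
        log((obs$n_subjects - 1) / params$sigma_ind^2)
    })
  expect_equal(log_posterior(spec, params), oracle, tolerance = 1e-10)

  # with zero observations the density reduces to the prior sum
  prior_only <- build_model_spec(obs[1, ], pr)
  p0 <- list(mu = 1, sigma_ind = 0.5, sigma_study = 0.5, m = 1.2)
  lp_full <- log_posterior(prior_only, p0)
  data_terms <- dnorm(1.2, 1, 0.5, log = TRUE) +
    dnorm(obs$ln_gm[1], 1.2, 0.5 / sqrt(12), log = TRUE) +
    dgamma(obs$ln_gsd[1]^2, 11 / 2, rate = 11 / (2 * 0.25), log = TRUE)
  prior_sum <- dnorm(1, pr$mu_mean, pr$mu_sd, log = TRUE) +
    2 * oracle_halfnorm(0.5, 1)
  expect_equal(lp_full - data_terms, prior_sum, tolerance = 1e-10)
})

test_that("log_posterior is additive in duplicated data and rejects sigma <= 0", {
  obs <- two_study_obs()
  pr <- prior_config()
  params <- list(mu = 6.0, sigma_ind = 0.4, sigma_study = 0.15,
                 m = c(6.05, 5.9))
  lp1 <- log_posterior(build_model_spec(obs, pr), params)
  params2 <- params; params2$m <- rep(params$m, 2)
  lp2 <- log_posterior(build_model_spec(rbind(obs, obs), pr), params2)
  # doubling the dataset doubles the data part (priors counted once)
  prior_sum <- dnorm(6, pr$mu_mean, pr$mu_sd, log = TRUE) +
    oracle_halfnorm(0.4, 1) + oracle_halfnorm(0.15, 1)
  expect_equal(lp2 - prior_sum, 2 * (lp1 - prior_sum), tolerance = 1e-10)

  bad <- params; bad$sigma_ind <- -0.1
  expect_identical(log_posterior(build_model_spec(obs, pr), bad), -Inf)
  bad <- params; bad$sigma_study <- 0
  expect_identical(log_posterior(build_model_spec(obs, pr), bad), -Inf)
})

test_that("informative overrides and the hyper level enter the density", {
  obs <- two_study_obs()
  pr <- prior_config(informative_overrides = list(zidovudine = c(-1.1, 0.2)))
  spec <- build_model_spec(obs, pr)
  params <- list(mu = 6.0, sigma_ind = 0.4, sigma_study = 0.15,
                 m = c(6.05, 5.9))
  delta <- log_posterior(spec, params) -
    log_posterior(build_model_spec(obs, prior_config()), params)
  expect_equal(delta,
               dlnorm(0.4, -1.1, 0.2, log = TRUE) - oracle_halfnorm(0.4, 1),
               tolerance = 1e-10)

  obs2 <- rbind(obs, transform(obs, substrate_id = "codeine"))
  spec2 <- build_model_spec(obs2, prior_config())
  p2 <- list(mu = c(6, 6), sigma_ind = c(0.4, 0.4),
             sigma_study = c(0.15, 0.15), m = rep(c(6.05, 5.9), 2),
             M = -1, S = 0.3)
  expect_error(log_posterior(spec2, p2[setdiff(names(p2), "M")]),
               "hyperparameters")
  expect_true(is.finite(log_posterior(spec2, p2)))
})

test_that("integrating out study effects matches the closed-form marginal", {
  # the sampler works on the marginal density; verify by quadrature that
  # integrating the full density over each m_ij reproduces the
  # normal-normal marginal lnGM_ij ~ N(mu, sigma_study^2 + sigma_ind^2/n)
  obs <- two_study_obs()
  pr <- prior_config()
  spec <- build_model_spec(obs, pr)
  fixed <- list(mu = 6.0, sigma_ind = 0.4, sigma_study = 0.15)
  joint_in_m <- function(m1, m2) {
    vapply(seq_along(m1), function(k) {
      exp(log_posterior(spec, c(fixed, list(m = c(m1[k], m2[k])))))
    }, numeric(1))
  }
  # m terms factorise across studies, so two 1-D integrals suffice
  int1 <- integrate(function(m1) joint_in_m(m1, rep(5.9, length(m1))),
                    5, 7, rel.tol = 1e-10)$value
  int2 <- integrate(function(m2) joint_in_m(rep(6.1, length(m2)), m2),
                    5, 7, rel.tol = 1e-10)$value
  dens_at <- function(m1, m2) joint_in_m(m1, m2)[1]
  full_int <- int1 * int2 / dens_at(6.1, 5.9)

  marginal <- dnorm(fixed$mu, pr$mu_mean, pr$mu_sd, log = TRUE) +
    oracle_halfnorm(fixed$sigma_ind, 1) +
    oracle_halfnorm(fixed$sigma_study, 1) +
    sum(dnorm(obs$ln_gm, fixed$mu,
              sqrt(fixed$sigma_study^2 + fixed$sigma_ind^2 / obs$n_subjects),
              log = TRUE)) +
    sum(dgamma(obs$ln_gsd^2, (obs$n_subjects - 1) / 2,
               rate = (obs$n_subjects - 1) / (2 * fixed$sigma_ind^2),
               log = TRUE))
  expect_equal(log(full_int), marginal, tolerance = 1e-8)
})

test_that("the sampler is deterministic for a fixed seed and config", {
  obs <- two_study_obs()
  spec <- build_model_spec(obs)
  cfg <- quick_mcmc(seed = 7)
  d1 <- suppressWarnings(run_mcmc(spec, cfg))
  d2 <- suppressWarnings(run_mcmc(spec, cfg))
  expect_identical(d1$draws, d2$draws)
  d3 <- suppressWarnings(run_mcmc(spec, quick_mcmc(seed = 8)))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("adding an identical substrate leaves a marginal posterior alone", {
  # exchangeability sanity check: duplicating substrate data as a new
  # substrate must not move the original's posterior beyond MC error
  sim <- simulate_study_summaries(synthetic_scenario(seed = 11))
  obs <- normalize_database(sim$database)
  one <- obs[obs$substrate_id == "SUBST1", ]
  twin <- transform(one, substrate_id = "SUBST1b")
  f1 <- suppressWarnings(fit_pkvar(rbind(one, twin), mcmc = quick_mcmc(2)))
  f2 <- suppressWarnings(fit_pkvar(rbind(one, twin,
    transform(one, substrate_id = "SUBST1c")), mcmc = quick_mcmc(3)))
  cv1 <- summary(f1)[1, "cv_median"]
  cv2 <- summary(f2)[1, "cv_median"]
  expect_equal(cv1, cv2, tolerance = 0.08)
})
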