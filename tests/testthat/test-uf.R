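test_that("sigma <-> CV conversions are exact and mutually inverse", {
  expect_equal(cv_from_sigma(0), 0)
  expect_equal(cv_from_sigma(sqrt(log(1.25))), 0.5, tolerance = 1e-12)
  expect_equal(cv_from_sigma(0.83255), 1.0, tolerance = 1e-4)
  expect_equal(sigma_from_cv(0), 0)
  expect_equal(sigma_from_cv(0.5), 0.472381, tolerance = 1e-6)
  for (x in c(0.1, 0.5, 1, 2)) {
    expect_equal(cv_from_sigma(sigma_from_cv(x)), x, tolerance = 1e-12)
  }
  expect_error(cv_from_sigma(-0.1), ">= 0")
})

test_that("uncertainty factors follow the percentile-to-median ratio", {
  expect_equal(uf_from_cv(0, 97.5), 1)
  expect_equal(uf_from_cv(0.5, 97.5), 2.524, tolerance = 1e-3)
  expect_error(uf_from_cv(0.4, 50), "\\(50, 100\\)")
  expect_error(uf_from_cv(0.4, 100), "\\(50, 100\\)")

  # strictly increasing in both arguments; 97.5th above 95th
  cvs <- seq(0.05, 2, length.out = 30)
  u95 <- uf_from_cv(cvs, 95)
  u975 <- uf_from_cv(cvs, 97.5)
  expect_true(all(diff(u95) > 0))
  expect_true(all(u975 > u95))
  expect_true(all(uf_from_cv(0.4, c(90)) < uf_from_cv(0.4, 95)))
})

test_that("degenerate constant draws give point summaries", {
  sig <- sqrt(log(1.25))
  arr <- array(0, c(100, 2, 3),
               dimnames = list(NULL, c("chain1", "chain2"),
                               c("mu[x]", "sigma_ind[x]", "sigma_study[x]")))
  arr[, , 2] <- sig
  arr[, , 3] <- 0.1
  draws <- structure(list(draws = arr, substrates = "x", pool = FALSE,
                          parameter = "auc", route = "oral",
                          config = mcmc_config(chains = 2, seed = 1)),
                     class = "pkvar_draws")
  s <- summarize_variability(draws, "x", counts = c(3L, 30L))
  expect_equal(s$gm_median, 1)
  expect_equal(s$cv_median, 0.5, tolerance = 1e-12)
  expect_equal(s$uf975_median, 2.524, tolerance = 1e-3)
  expect_equal(s$cv_lo95, s$cv_hi95)
  # single-substrate fits report the substrate as the overall
  ov <- summarize_variability(draws, "overall", counts = c(3L, 30L))
  expect_equal(ov$cv_median, s$cv_median)
})

test_that("medians commute with the monotone sigma -> CV -> UF maps", {
  set.seed(9)
  sig <- abs(rnorm(501, 0.4, 0.1))
  arr <- array(sig, c(501, 1, 1))
  med <- function(x) quantile(x, 0.5, type = 1, names = FALSE)
  expect_equal(med(uf_from_cv(cv_from_sigma(sig), 97.5)),
               uf_from_cv(cv_from_sigma(med(sig)), 97.5), tolerance = 1e-12)
})

test_that("report tables order rows and apply the printing rules", {
  sig <- c(0.39, 0.47)
  rows <- lapply(seq_along(sig), function(i) {
    arr <- array(0, c(100, 2, 3),
                 dimnames = list(NULL, c("chain1", "chain2"),
                                 paste0(c("mu[", "sigma_ind[", "sigma_study["),
                                        "x]")))
    arr[, , 2] <- sig[i]
    draws <- structure(list(draws = arr, substrates = "x", pool = FALSE,
                            parameter = "auc", route = "oral",
                            config = mcmc_config(chains = 2, seed = 1)),
                       class = "pkvar_draws")
    s <- summarize_variability(draws, "x", counts = c(5L, 50L))
    s$scope <- c("zz_compound", "overall")[i]
    s
  })
  tab <- build_report_table(do.call(rbind, rows))
  expect_identical(tab$compound, c("zz_compound", "overall"))
  expect_identical(tab$cv_pct, round_half_up(100 * cv_from_sigma(sig)))
  expect_match(tab$uf95_ci[1], "^[0-9.]+-[0-9.]+$")

  # stated rounding rules: CV% to integer, UF half-up to one decimal
  expect_equal(round_half_up(0.405 * 100), 41)
  expect_equal(round_half_up(2.07, 1), 2.1)
  expect_equal(round_half_up(2.25, 1), 2.3)
})
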