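# Hierarchical Bayesian variance decomposition of PK summary data.
#
# Three nested levels of variation:
#   interindividual  sigma_ind[j]   SD of log PK values within a study
#   interstudy       sigma_study[j] SD of study-level log means around the
#                                   substrate mean mu[j]
#   intersubstrate   (M, S)         hyper-distribution of log sigma_ind[j]
#                                   across an isoform's probe substrates
#
# Each study contributes its sufficient statistics under lognormality:
#   lnGM_ij  ~ Normal(m_ij, sigma_ind[j]^2 / n_ij),  m_ij ~ Normal(mu_j, sigma_study[j]^2)
#   (n_ij - 1) lnGSD_ij^2 / sigma_ind[j]^2 ~ ChiSq(n_ij - 1)   [n_ij >= 2]
# The dispersion term is implemented as the equivalent Gamma density of the
# observed lnGSD^2 so the likelihood is a proper density of the data.
# The sampler works on the exact study-effect-marginalised posterior
# (lnGM_ij ~ Normal(mu_j, sigma_study^2 + sigma_ind^2/n_ij)); the full
# conditional parameterisation is kept in log_posterior() as the reference
# density.

#' Prior configuration for the hierarchical model
#'
#' Defaults are weakly informative on the log scale: substrate log-means
#' `mu_j ~ Normal(mu_mean, mu_sd^2)`; interindividual and interstudy SDs
#' half-normal; when pooling across substrates,
#' `log sigma_ind_j ~ Normal(M, S^2)` with `M ~ Normal(-1, 1)` and
#' `S ~ HalfNormal(0.5)` (plausible GSDs roughly 1--5). Substrates with
#' previously meta-analysed variability (e.g. zidovudine, oxazepam) can be
#' given informative normal priors on `log sigma_ind` via
#' `informative_overrides`.
#'
#' @param mu_mean,mu_sd Normal prior on each substrate log-mean.
#' @param sigma_ind_scale Half-normal scale for `sigma_ind` when not pooled
#'   and not overridden.
#' @param sigma_study_scale Half-normal scale for `sigma_study`.
#' @param hyper_M_mean,hyper_M_sd Normal prior on the hyper-mean `M` of
#'   `log sigma_ind`.
#' @param hyper_S_scale Half-normal scale for the hyper-SD `S`.
#' @param informative_overrides Named list mapping substrate ids to
#'   `c(mean, sd)` of a normal prior on `log sigma_ind` for that substrate.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(mu_mean = 0, mu_sd = 10,
                         sigma_ind_scale = 1, sigma_study_scale = 1,
                         hyper_M_mean = -1, hyper_M_sd = 1,
                         hyper_S_scale = 0.5,
                         informative_overrides = list()) {
  stopifnot(mu_sd > 0, sigma_ind_scale > 0, sigma_study_scale > 0,
            hyper_M_sd > 0, hyper_S_scale > 0, is.list(informative_overrides))
  for (o in informative_overrides) {
    stopifnot(length(o) == 2L, is.numeric(o), o[2] > 0)
  }
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_ind_scale = sigma_ind_scale,
                 sigma_study_scale = sigma_study_scale,
                 hyper_M_mean = hyper_M_mean, hyper_M_sd = hyper_M_sd,
                 hyper_S_scale = hyper_S_scale,
                 informative_overrides = informative_overrides),
            class = "prior_config")
}

#' MCMC configuration
#'
#' @param chains Number of chains (>= 2, so split-R-hat is defined).
#' @param warmup_draws Adaptation iterations discarded per chain.
#' @param kept_draws Retained iterations per chain.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param rhat_threshold Convergence threshold on split R-hat.
#' @param min_ess Minimum effective sample size per parameter.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, warmup_draws = 1000, kept_draws = 2500,
                        seed = 1, rhat_threshold = 1.05, min_ess = 400) {
  stopifnot(chains >= 2, warmup_draws >= 1, kept_draws >= 1,
            rhat_threshold > 1, min_ess >= 1)
  structure(list(chains = as.integer(chains),
                 warmup_draws = as.integer(warmup_draws),
                 kept_draws = as.integer(kept_draws),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 min_ess = as.integer(min_ess)),
            class = "mcmc_config")
}

#' Build a hierarchical model specification
#'
#' Groups normalised observations by substrate, indexes them, and flags
#' degenerate studies (`n_subjects = 1`, or a reported GSD of exactly 1)
#' whose dispersion likelihood term is omitted. All observations must share
#' one PK parameter and one route: variance components are estimated per
#' parameter x route, never pooled across them.
#'
#' @param observations Data frame from [normalize_database()] (columns
#'   `substrate_id`, `n_subjects`, `ln_gm`, `ln_gsd`, and optionally
#'   `parameter`, `route`, `source_study_id`).
#' @param priors A [prior_config()].
#' @return An object of class `pkvar_model_spec`.
#' @export
build_model_spec <- function(observations, priors = prior_config()) {
  if (!is.data.frame(observations) || nrow(observations) == 0L) {
    stop("observations must be a non-empty data frame")
  }
  req <- c("substrate_id", "n_subjects", "ln_gm", "ln_gsd")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("observations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("parameter", "route")) {
    if (col %in% names(observations) &&
        length(unique(observations[[col]])) > 1L) {
      stop("observations mix more than one ", col,
           "; fit each parameter x route separately")
    }
  }
  if (!all(is.finite(observations$ln_gm)) ||
      !all(is.finite(observations$ln_gsd)) ||
      any(observations$ln_gsd < 0)) {
    stop("non-finite ln_gm/ln_gsd or negative ln_gsd in observations")
  }
  if (any(observations$n_subjects < 1L)) stop("n_subjects must be >= 1")
  substrates <- sort(unique(observations$substrate_id))
  j <- match(observations$substrate_id, substrates)
  use_gsd <- observations$n_subjects >= 2L & observations$ln_gsd > 0
  structure(list(
    observations = observations,
    substrates = substrates,
    j = j,
    use_gsd = use_gsd,
    pool = length(substrates) >= 2L,
    parameter = if ("parameter" %in% names(observations))
      observations$parameter[1L] else NA_character_,
    route = if ("route" %in% names(observations))
      observations$route[1L] else NA_character_,
    priors = priors
  ), class = "pkvar_model_spec")
}

.log_halfnormal <- function(x, scale) {
  ifelse(x > 0, stats::dnorm(x, 0, scale, log = TRUE) + log(2), -Inf)
}

.sigma_ind_log_prior <- function(sigma_ind, spec, M = NULL, S = NULL) {
  pr <- spec$priors
  lp <- numeric(length(sigma_ind))
  for (jj in seq_along(sigma_ind)) {
    ov <- pr$informative_overrides[[spec$substrates[jj]]]
    if (!is.null(ov)) {
      lp[jj] <- stats::dlnorm(sigma_ind[jj], ov[1], ov[2], log = TRUE)
    } else if (spec$pool) {
      lp[jj] <- stats::dlnorm(sigma_ind[jj], M, S, log = TRUE)
    } else {
      lp[jj] <- .log_halfnormal(sigma_ind[jj], pr$sigma_ind_scale)
    }
  }
  lp
}

.gsd_loglik <- function(ln_gsd, n, sigma_ind) {
  # density of the observed lnGSD^2; equivalent to the chi-square sampling
  # law of (n-1) lnGSD^2 / sigma^2 after change of variables
  stats::dgamma(ln_gsd^2, shape = (n - 1) / 2,
                rate = (n - 1) / (2 * sigma_ind^2), log = TRUE)
}

#' Log posterior density of the full parameterisation
#'
#' Reference density with study effects explicit. `params` is a list with
#' `mu`, `sigma_ind`, `sigma_study` (one value per substrate, in the order
#' of `spec$substrates`), `m` (one study effect per observation row), and,
#' when pooling, hyperparameters `M` and `S`. Nonpositive SDs yield `-Inf`
#' (rejection), not an error.
#'
#' @param spec A [build_model_spec()] result.
#' @param params Named list of parameter values (natural scale).
#' @return Scalar log posterior density (unnormalised).
#' @export
log_posterior <- function(spec, params) {
  stopifnot(inherits(spec, "pkvar_model_spec"))
  J <- length(spec$substrates)
  obs <- spec$observations
  mu <- params$mu; si <- params$sigma_ind; ss <- params$sigma_study
  if (length(mu) != J || length(si) != J || length(ss) != J ||
      length(params$m) != nrow(obs)) {
    stop("parameter assignment does not match the model specification")
  }
  if (spec$pool && (is.null(params$M) || is.null(params$S))) {
    stop("pooled model requires hyperparameters M and S")
  }
  if (any(si <= 0) || any(ss <= 0) || (spec$pool && params$S <= 0)) {
    return(-Inf)
  }
  pr <- spec$priors
  lp <- sum(stats::dnorm(mu, pr$mu_mean, pr$mu_sd, log = TRUE)) +
    sum(.sigma_ind_log_prior(si, spec, params$M, params$S)) +
    sum(.log_halfnormal(ss, pr$sigma_study_scale))
  if (spec$pool) {
    lp <- lp + stats::dnorm(params$M, pr$hyper_M_mean, pr$hyper_M_sd,
                            log = TRUE) +
      .log_halfnormal(params$S, pr$hyper_S_scale)
  }
  jdx <- spec$j
  lp <- lp + sum(stats::dnorm(params$m, mu[jdx], ss[jdx], log = TRUE))
  lp <- lp + sum(stats::dnorm(obs$ln_gm, params$m,
                              si[jdx] / sqrt(obs$n_subjects), log = TRUE))
  g <- spec$use_gsd
  if (any(g)) {
    lp <- lp + sum(.gsd_loglik(obs$ln_gsd[g], obs$n_subjects[g], si[jdx[g]]))
  }
  lp
}

# Marginal log posterior used by the sampler: study effects integrated out
# exactly (normal-normal), so lnGM_ij ~ N(mu_j, sigma_study^2 + sigma_ind^2/n).
.log_posterior_marginal <- function(spec, mu, sigma_ind, sigma_study,
                                    M = NULL, S = NULL) {
  if (any(sigma_ind <= 0) || any(sigma_study <= 0) ||
      (spec$pool && S <= 0)) {
    return(-Inf)
  }
  pr <- spec$priors
  obs <- spec$observations
  jdx <- spec$j
  lp <- sum(stats::dnorm(mu, pr$mu_mean, pr$mu_sd, log = TRUE)) +
    sum(.sigma_ind_log_prior(sigma_ind, spec, M, S)) +
    sum(.log_halfnormal(sigma_study, pr$sigma_study_scale))
  if (spec$pool) {
    lp <- lp + stats::dnorm(M, pr$hyper_M_mean, pr$hyper_M_sd, log = TRUE) +
      .log_halfnormal(S, pr$hyper_S_scale)
  }
  tot_sd <- sqrt(sigma_study[jdx]^2 + sigma_ind[jdx]^2 / obs$n_subjects)
  lp <- lp + sum(stats::dnorm(obs$ln_gm, mu[jdx], tot_sd, log = TRUE))
  g <- spec$use_gsd
  if (any(g)) {
    lp <- lp + sum(.gsd_loglik(obs$ln_gsd[g], obs$n_subjects[g],
                               sigma_ind[jdx[g]]))
  }
  lp
}

.theta_names <- function(spec) {
  s <- spec$substrates
  nm <- c(paste0("mu[", s, "]"), paste0("log_sigma_ind[", s, "]"),
          paste0("log_sigma_study[", s, "]"))
  if (spec$pool) nm <- c(nm, "M", "log_S")
  nm
}

.theta_target <- function(spec, theta) {
  J <- length(spec$substrates)
  mu <- theta[seq_len(J)]
  lsi <- theta[J + seq_len(J)]
  lss <- theta[2L * J + seq_len(J)]
  M <- if (spec$pool) theta[3L * J + 1L] else NULL
  lS <- if (spec$pool) theta[3L * J + 2L] else NULL
  # Jacobian of the log-SD reparameterisation: + log sigma per component
  .log_posterior_marginal(spec, mu, exp(lsi), exp(lss), M,
                          if (is.null(lS)) NULL else exp(lS)) +
    sum(lsi) + sum(lss) + (if (spec$pool) lS else 0)
}

.theta_init <- function(spec, jitter_sd = 0.3) {
  J <- length(spec$substrates)
  obs <- spec$observations
  mu0 <- vapply(seq_len(J), function(jj) {
    w <- obs$n_subjects[spec$j == jj]
    sum(obs$ln_gm[spec$j == jj] * w) / sum(w)
  }, numeric(1))
  si0 <- vapply(seq_len(J), function(jj) {
    v <- obs$ln_gsd[spec$j == jj & spec$use_gsd]
    if (length(v) == 0L) 0.3 else sqrt(mean(v^2))
  }, numeric(1))
  ss0 <- vapply(seq_len(J), function(jj) {
    v <- obs$ln_gm[spec$j == jj]
    if (length(v) < 2L) 0.2 else max(stats::sd(v), 0.05)
  }, numeric(1))
  theta <- c(mu0, log(si0), log(ss0))
  if (spec$pool) theta <- c(theta, mean(log(si0)), log(0.3))
  theta + stats::rnorm(length(theta), 0, jitter_sd)
}

# exact Gibbs update of the hyper-mean M: conjugate normal conditional
# given the log sigma_ind of the substrates tied to the hyper level
.gibbs_M <- function(spec, theta) {
  J <- length(spec$substrates)
  pr <- spec$priors
  hyper_j <- which(!(spec$substrates %in% names(pr$informative_overrides)))
  lS <- theta[3L * J + 2L]
  S2 <- exp(2 * lS)
  prec <- 1 / pr$hyper_M_sd^2 + length(hyper_j) / S2
  lsi <- theta[J + hyper_j]
  mean_c <- (pr$hyper_M_mean / pr$hyper_M_sd^2 + sum(lsi) / S2) / prec
  stats::rnorm(1L, mean_c, sqrt(1 / prec))
}

.run_one_chain <- function(spec, cfg, chain_id) {
  set.seed((cfg$seed + 104729L * chain_id) %% .Machine$integer.max)
  theta <- .theta_init(spec)
  np <- length(theta)
  lp <- .theta_target(spec, theta)
  # overdispersed inits can land in a zero-density region; pull back
  tries <- 0L
  while (!is.finite(lp) && tries < 50L) {
    theta <- .theta_init(spec, jitter_sd = 0.05)
    lp <- .theta_target(spec, theta)
    tries <- tries + 1L
  }
  if (!is.finite(lp)) stop("could not initialise chain ", chain_id)
  step <- rep(0.5, np)
  n_iter <- cfg$warmup_draws + cfg$kept_draws
  kept <- matrix(NA_real_, cfg$kept_draws, np)
  acc <- numeric(np)
  batch <- 25L
  n_batches <- 0L
  M_idx <- if (spec$pool) 3L * length(spec$substrates) + 1L else 0L
  for (it in seq_len(n_iter)) {
    if (spec$pool) {
      theta[M_idx] <- .gibbs_M(spec, theta)
      lp <- .theta_target(spec, theta)
    }
    for (k in seq_len(np)) {
      prop <- theta
      prop[k] <- prop[k] + stats::rnorm(1L) * step[k]
      lp_prop <- .theta_target(spec, prop)
      if (is.finite(lp_prop) &&
          (lp_prop >= lp || log(stats::runif(1L)) < lp_prop - lp)) {
        theta <- prop
        lp <- lp_prop
        acc[k] <- acc[k] + 1
      }
    }
    if (it <= cfg$warmup_draws && it %% batch == 0L) {
      n_batches <- n_batches + 1L
      rate <- acc / batch
      step <- step * exp(pmax(pmin(rate - 0.44, 0.5), -0.5) /
                           sqrt(n_batches))
      step <- pmin(pmax(step, 1e-5), 20)
      acc[] <- 0
    }
    if (it > cfg$warmup_draws) kept[it - cfg$warmup_draws, ] <- theta
  }
  kept
}

#' Run the MCMC sampler
#'
#' Componentwise adaptive random-walk Metropolis on the study-effect
#' marginalised posterior, sampling location parameters directly and SDs in
#' log space (proposal scales are adapted toward 44% acceptance during
#' warmup and frozen afterwards). Identical `cfg` (including seed) gives
#' bit-identical draws. If split R-hat or effective sample size fail the
#' configured thresholds a warning is raised and the result is flagged, but
#' draws are still returned.
#'
#' @param spec A [build_model_spec()] result.
#' @param cfg An [mcmc_config()].
#' @return An object of class `pkvar_draws`: a `kept_draws x chains x
#'   parameters` array of natural-scale draws (`mu[.]`, `sigma_ind[.]`,
#'   `sigma_study[.]`, and `M`, `S` when pooling) with convergence
#'   diagnostics attached.
#' @export
run_mcmc <- function(spec, cfg = mcmc_config()) {
  stopifnot(inherits(spec, "pkvar_model_spec"), inherits(cfg, "mcmc_config"))
  J <- length(spec$substrates)
  th_names <- .theta_names(spec)
  chains <- lapply(seq_len(cfg$chains), function(cid) {
    .run_one_chain(spec, cfg, cid)
  })
  s <- spec$substrates
  par_names <- c(paste0("mu[", s, "]"), paste0("sigma_ind[", s, "]"),
                 paste0("sigma_study[", s, "]"))
  if (spec$pool) par_names <- c(par_names, "M", "S")
  np <- length(par_names)
  arr <- array(NA_real_, c(cfg$kept_draws, cfg$chains, np),
               dimnames = list(NULL, paste0("chain", seq_len(cfg$chains)),
                               par_names))
  log_cols <- grepl("^log_", th_names)
  for (c_i in seq_len(cfg$chains)) {
    m <- chains[[c_i]]
    m[, log_cols] <- exp(m[, log_cols])
    arr[, c_i, ] <- m
  }
  draws <- structure(list(draws = arr, substrates = s, pool = spec$pool,
                          parameter = spec$parameter, route = spec$route,
                          config = cfg),
                     class = "pkvar_draws")
  diag <- convergence_diagnostics(draws, cfg)
  draws$diagnostics <- diag
  draws$converged <- diag$pass
  if (!diag$pass) {
    warning("MCMC did not meet convergence thresholds (see diagnostics)",
            call. = FALSE)
  }
  draws
}

#' @export
print.pkvar_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws: %d iterations x %d chains x %d parameters\n",
              d[1], d[2], d[3]))
  cat("converged:", isTRUE(x$converged), "\n")
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param x A `pkvar_draws` object.
#' @param ... Unused.
#' @return Matrix with `iterations * chains` rows, one column per parameter.
#' @export
as.matrix.pkvar_draws <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(aperm(x$draws, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(out) <- dimnames(x$draws)[[3]]
  out
}

.split_chains <- function(mat) {
  # mat: iterations x chains -> iterations/2 x (2*chains)
  n <- nrow(mat)
  h <- n %/% 2L
  cbind(mat[seq_len(h), , drop = FALSE],
        mat[(n - h + 1L):n, , drop = FALSE])
}

.rhat_one <- function(mat) {
  sp <- .split_chains(mat)
  n <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess_one <- function(mat) {
  sp <- .split_chains(mat)
  n <- nrow(sp)
  m <- ncol(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(colMeans(sp))
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(0)
  lag_max <- n - 2L
  acov <- vapply(seq_len(m), function(i) {
    stats::acf(sp[, i], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(lag_max + 1L))
  rho <- 1 - (W - rowMeans(acov)[-1L]) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  n_pairs <- length(rho) %/% 2L
  psum <- rho[2 * seq_len(n_pairs) - 1L] + rho[2 * seq_len(n_pairs)]
  tau <- 1
  running_min <- Inf
  for (p in seq_len(n_pairs)) {
    if (psum[p] < 0) break
    running_min <- min(running_min, psum[p])
    tau <- tau + 2 * running_min
  }
  max(m * n / tau, 0)
}

#' Convergence diagnostics
#'
#' Split R-hat and effective sample size per parameter, compared against
#' the thresholds in `cfg`. Degenerate (constant) chains give undefined
#' R-hat and zero ESS and are flagged as failures.
#'
#' @param draws A `pkvar_draws` object.
#' @param cfg The [mcmc_config()] providing `rhat_threshold` and `min_ess`.
#' @return List with `summary` (data frame: parameter, rhat, ess, ok) and
#'   `pass` (logical).
#' @export
convergence_diagnostics <- function(draws, cfg = draws$config) {
  stopifnot(inherits(draws, "pkvar_draws"))
  if (dim(draws$draws)[2] < 2L) stop("diagnostics require >= 2 chains")
  pars <- dimnames(draws$draws)[[3]]
  rhat <- vapply(pars, function(p) .rhat_one(draws$draws[, , p]), numeric(1))
  ess <- vapply(pars, function(p) .ess_one(draws$draws[, , p]), numeric(1))
  ok <- is.finite(rhat) & rhat < cfg$rhat_threshold & ess >= cfg$min_ess
  list(summary = data.frame(parameter = pars, rhat = rhat, ess = ess,
                            ok = ok, row.names = NULL,
                            stringsAsFactors = FALSE),
       pass = all(ok),
       rhat_threshold = cfg$rhat_threshold, min_ess = cfg$min_ess)
}

#' Export posterior draws as long-format CSV
#'
#' Writes columns `chain`, `draw`, `parameter`, `value` with fixed 15-digit
#' formatting, so identical draws always produce byte-identical files.
#'
#' @param draws A `pkvar_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_draws <- function(draws, path) {
  stopifnot(inherits(draws, "pkvar_draws"))
  d <- dim(draws$draws)
  pars <- dimnames(draws$draws)[[3]]
  long <- data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    draw = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
    parameter = rep(pars, each = d[1] * d[2]),
    value = sprintf("%.15g", as.vector(draws$draws)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
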