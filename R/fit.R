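# User-facing fitting interface: fit_pkvar() wraps build_model_spec() +
# run_mcmc() and returns a classed model object carrying the data, draws,
# diagnostics and bookkeeping counts that the summary/report layer needs.

#' Fit the hierarchical variability model to normalised PK observations
#'
#' This is the main entry point of the package. It takes dose-normalised
#' lognormal study summaries (from [normalize_database()]), builds the
#' three-level hierarchical model (interindividual / interstudy /
#' intersubstrate), samples the posterior by MCMC, and returns a fitted
#' model object. Use [summary.pkvar_fit()] to obtain geometric means, CVs
#' and uncertainty factors with credible intervals, and
#' [build_report_table()] to format them.
#'
#' @param observations Data frame of normalised observations (columns
#'   `substrate_id`, `n_subjects`, `ln_gm`, `ln_gsd`, and optionally
#'   `parameter`, `route`, `source_study_id`).
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @return An object of class `pkvar_fit` with elements `spec`, `draws`
#'   (class `pkvar_draws`), `diagnostics`, `counts` (per-substrate study and
#'   subject counts) and `call`.
#' @examples
#' sim <- simulate_study_summaries(synthetic_scenario(seed = 42))
#' obs <- normalize_database(sim$database)
#' fit <- fit_pkvar(obs, mcmc = mcmc_config(chains = 2, warmup_draws = 200,
#'                                          kept_draws = 300, seed = 1))
#' summary(fit)
#' @export
fit_pkvar <- function(observations, priors = prior_config(),
                      mcmc = mcmc_config()) {
  spec <- build_model_spec(observations, priors)
  draws <- run_mcmc(spec, mcmc)
  counts <- do.call(rbind, lapply(seq_along(spec$substrates), function(jj) {
    sel <- spec$j == jj
    data.frame(substrate_id = spec$substrates[jj],
               nst = sum(sel),
               n_total = sum(spec$observations$n_subjects[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(spec = spec, draws = draws,
                 diagnostics = draws$diagnostics,
                 converged = draws$converged,
                 counts = counts, call = match.call()),
            class = "pkvar_fit")
}

#' @export
print.pkvar_fit <- function(x, ...) {
  cat("Hierarchical PK variability model\n")
  cat(sprintf("  parameter: %s, route: %s\n", x$spec$parameter, x$spec$route))
  cat(sprintf("  substrates: %s\n", paste(x$spec$substrates, collapse = ", ")))
  cat(sprintf("  studies: %d, subjects: %d\n",
              sum(x$counts$nst), sum(x$counts$n_total)))
  d <- dim(x$draws$draws)
  cat(sprintf("  draws: %d x %d chains; converged: %s\n",
              d[1], d[2], isTRUE(x$converged)))
  invisible(x)
}

#' Summarise a fitted variability model
#'
#' One row per substrate plus an `"overall"` row (isoform-level predictive
#' distribution when several substrates were pooled), each giving posterior
#' median and 95% credible interval for the dose-normalised GM, the
#' interindividual CV and the uncertainty factors.
#'
#' @param object A `pkvar_fit`.
#' @param percentiles Upper percentiles for the UFs (default 95 and 97.5).
#' @param include_overall Append the overall row?
#' @param ... Unused.
#' @return Data frame of variability-summary rows.
#' @export
summary.pkvar_fit <- function(object, percentiles = c(95, 97.5),
                              include_overall = TRUE, ...) {
  rows <- lapply(seq_len(nrow(object$counts)), function(i) {
    summarize_variability(object$draws, object$counts$substrate_id[i],
                          counts = c(object$counts$nst[i],
                                     object$counts$n_total[i]),
                          percentiles = percentiles)
  })
  if (include_overall) {
    rows <- c(rows, list(summarize_variability(
      object$draws, "overall",
      counts = c(sum(object$counts$nst), sum(object$counts$n_total)),
      percentiles = percentiles)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior medians of the model parameters
#'
#' @param object A `pkvar_fit`.
#' @param ... Unused.
#' @return Named numeric vector of per-parameter posterior medians.
#' @export
coef.pkvar_fit <- function(object, ...) {
  m <- as.matrix(object$draws)
  apply(m, 2, function(x) stats::quantile(x, 0.5, type = 1, names = FALSE))
}

#' Standardised study-level residuals
#'
#' Residuals of the observed study log-GMs against the posterior-median
#' substrate means, scaled by the marginal study-level SD
#' `sqrt(sigma_study^2 + sigma_ind^2 / n)`. Values far outside (-2, 2)
#' point at studies the model does not accommodate.
#'
#' @param object A `pkvar_fit`.
#' @param ... Unused.
#' @return Numeric vector, one residual per observation.
#' @export
residuals.pkvar_fit <- function(object, ...) {
  cf <- coef(object)
  spec <- object$spec
  obs <- spec$observations
  s <- spec$substrates[spec$j]
  mu <- cf[paste0("mu[", s, "]")]
  si <- cf[paste0("sigma_ind[", s, "]")]
  ss <- cf[paste0("sigma_study[", s, "]")]
  as.numeric((obs$ln_gm - mu) / sqrt(ss^2 + si^2 / obs$n_subjects))
}

#' Forest-style plot of a fitted variability model
#'
#' Posterior medians and 95% credible intervals of the interindividual CV
#' (left panel) and the 97.5th-percentile uncertainty factor (right panel),
#' one line per substrate plus the overall row. The dashed reference line
#' marks the default toxicokinetic factor 3.16.
#'
#' @param x A `pkvar_fit`.
#' @param ... Unused.
#' @export
plot.pkvar_fit <- function(x, ...) {
  sm <- summary(x)
  k <- nrow(sm)
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 7, 2, 1))
  on.exit(graphics::par(old))
  panel <- function(med, lo, hi, xlab, ref = NULL) {
    graphics::plot(med, seq_len(k), xlim = range(c(lo, hi, ref)),
                   ylim = c(0.5, k + 0.5), pch = 19, yaxt = "n",
                   xlab = xlab, ylab = "")
    graphics::segments(lo, seq_len(k), hi, seq_len(k))
    graphics::axis(2, at = seq_len(k), labels = sm$scope, las = 1)
    if (!is.null(ref)) graphics::abline(v = ref, lty = 2)
  }
  panel(sm$cv_median, sm$cv_lo95, sm$cv_hi95, "interindividual CV")
  panel(sm$uf975_median, sm$uf975_lo95, sm$uf975_hi95,
        "UF (97.5th percentile)", ref = 3.16)
  invisible(sm)
}

#' Simulate study summaries from the posterior
#'
#' Posterior-predictive draws of new study-level summaries: for each
#' simulation a posterior draw is selected, a study effect is drawn around
#' the substrate mean, and the study's observed log-GM and log-GSD are
#' drawn from their sampling distributions at the given study size.
#'
#' @param object A `pkvar_fit`.
#' @param nsim Simulated studies per substrate.
#' @param seed Optional seed.
#' @param n_subjects Subjects per simulated study.
#' @param ... Unused.
#' @return Data frame with columns `substrate_id`, `sim`, `n_subjects`,
#'   `ln_gm`, `ln_gsd`.
#' @export
simulate.pkvar_fit <- function(object, nsim = 1, seed = NULL,
                               n_subjects = 20, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(object$draws)
  out <- lapply(object$spec$substrates, function(s) {
    idx <- sample.int(nrow(m), nsim, replace = TRUE)
    mu <- m[idx, paste0("mu[", s, "]")]
    si <- m[idx, paste0("sigma_ind[", s, "]")]
    ss <- m[idx, paste0("sigma_study[", s, "]")]
    me <- stats::rnorm(nsim, mu, ss)
    ln_gm <- stats::rnorm(nsim, me, si / sqrt(n_subjects))
    ln_gsd <- sqrt(stats::rgamma(nsim, shape = (n_subjects - 1) / 2,
                                 rate = (n_subjects - 1) / (2 * si^2)))
    data.frame(substrate_id = s, sim = seq_len(nsim),
               n_subjects = n_subjects, ln_gm = ln_gm, ln_gsd = ln_gsd,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
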