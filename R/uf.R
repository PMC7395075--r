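# CV and uncertainty-factor derivation from posterior draws.
#
# For lognormal PK values with log-scale interindividual SD sigma:
#   CV   = sqrt(exp(sigma^2) - 1)
#   UF_p = p-th percentile / median = exp(z_p * sigma)
# The UF is the ratio by which the upper tail of the healthy-adult
# variability distribution exceeds its median; it is compared against the
# default toxicokinetic factor 3.16 (10^0.5).

#' Coefficient of variation from the lognormal log-scale SD
#'
#' @param sigma Nonnegative log-scale SD (`sigma = ln GSD`); vectorised.
#' @return `sqrt(exp(sigma^2) - 1)`.
#' @export
cv_from_sigma <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("sigma must be finite and >= 0")
  }
  sqrt(expm1(sigma^2))
}

#' Lognormal log-scale SD from a coefficient of variation
#'
#' Exact inverse of [cv_from_sigma()].
#'
#' @param cv Nonnegative CV (fraction); vectorised.
#' @return `sqrt(log(1 + cv^2))`.
#' @export
sigma_from_cv <- function(cv) {
  if (any(!is.finite(cv)) || any(cv < 0)) stop("cv must be finite and >= 0")
  sqrt(log1p(cv^2))
}

#' Uncertainty factor from a coefficient of variation
#'
#' Ratio of the chosen upper percentile of the lognormal variability
#' distribution to its median: `UF = exp(z_p * sqrt(log(1 + cv^2)))`.
#'
#' @param cv Nonnegative CV (fraction); vectorised.
#' @param percentile Percentile in (50, 100); 95 and 97.5 are the
#'   conventional choices (`z_95 = 1.6449`, `z_97.5 = 1.9600`).
#' @return UF `>= 1`.
#' @export
uf_from_cv <- function(cv, percentile = 97.5) {
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 50 || percentile >= 100) {
    stop("percentile must lie in (50, 100)")
  }
  exp(stats::qnorm(percentile / 100) * sigma_from_cv(cv))
}

#' Round half away from zero
#'
#' Report-table rounding rule (2.25 -> 2.3 at one decimal), as opposed to
#' base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# order-statistic quantiles keep monotone-transform equivariance exact:
# median(f(x)) == f(median(x)) for increasing f
.q3 <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975), type = 1,
                                   names = FALSE)

.uf_col <- function(p) paste0("uf", sub("\\.", "", format(p)))

#' Summarise posterior variability for one substrate or the isoform overall
#'
#' Per posterior draw computes the dose-normalised geometric mean
#' `GM = exp(mu)`, the interindividual `CV = cv_from_sigma(sigma_ind)` and
#' the uncertainty factors `UF_p = uf_from_cv(CV, p)`, then reports the
#' posterior median and 95% credible interval of each (order-statistic
#' quantiles, so medians commute with the monotone CV->UF transform).
#'
#' For `scope = "overall"` the isoform-level predictive distribution is
#' used: each draw's `sigma_ind` is a fresh substrate drawn from the
#' hyper-level, `exp(M + S z)` with `z ~ N(0,1)` (seeded deterministically
#' from the fit's master seed), and the overall log-GM is the mean of the
#' substrate log-means. With a single substrate the substrate itself is the
#' overall, following the reporting convention for single-compound isoforms.
#'
#' @param draws A `pkvar_draws` object.
#' @param scope A substrate id, or `"overall"`.
#' @param counts Integer vector `c(nst, n_total)`: number of studies and
#'   total subjects behind the summary (bookkeeping only).
#' @param percentiles Upper percentiles for the UFs.
#' @return One-row data frame (a variability-summary row): scope, route,
#'   parameter, nst, n_total, then median/lo95/hi95 triples for gm, cv and
#'   each UF.
#' @export
summarize_variability <- function(draws, scope, counts = c(NA, NA),
                                  percentiles = c(95, 97.5)) {
  stopifnot(inherits(draws, "pkvar_draws"))
  m <- as.matrix(draws)
  if (nrow(m) == 0L) stop("empty draws")
  s <- draws$substrates
  if (identical(scope, "overall")) {
    if (length(s) == 1L) {
      mu <- m[, paste0("mu[", s, "]")]
      sigma <- m[, paste0("sigma_ind[", s, "]")]
    } else {
      if (!draws$pool) stop("overall summary requires a pooled fit")
      mu <- rowMeans(m[, paste0("mu[", s, "]"), drop = FALSE])
      set.seed((draws$config$seed + 999331L) %% .Machine$integer.max)
      sigma <- exp(m[, "M"] + m[, "S"] * stats::rnorm(nrow(m)))
    }
  } else {
    if (!(scope %in% s)) stop("unknown substrate: ", scope)
    mu <- m[, paste0("mu[", scope, "]")]
    sigma <- m[, paste0("sigma_ind[", scope, "]")]
  }
  gm <- exp(mu)
  cv <- cv_from_sigma(sigma)
  qs <- list(gm = .q3(gm), cv = .q3(cv))
  out <- data.frame(scope = scope, route = draws$route,
                    parameter = draws$parameter,
                    nst = as.integer(counts[1]), n_total = as.integer(counts[2]),
                    stringsAsFactors = FALSE)
  for (nm in names(qs)) {
    out[[paste0(nm, "_median")]] <- qs[[nm]][2]
    out[[paste0(nm, "_lo95")]] <- qs[[nm]][1]
    out[[paste0(nm, "_hi95")]] <- qs[[nm]][3]
  }
  for (p in percentiles) {
    q <- .q3(uf_from_cv(cv, p))
    col <- .uf_col(p)
    out[[paste0(col, "_median")]] <- q[2]
    out[[paste0(col, "_lo95")]] <- q[1]
    out[[paste0(col, "_hi95")]] <- q[3]
  }
  out
}

#' Format variability summaries as a report table
#'
#' Lays the summaries out in the conventional column order (nst, n, CV as
#' integer percent, GM, UF and 95% CI per percentile), substrates first and
#' the overall row last. Rounding — CV to integer percent, UFs and CI
#' bounds half-up to one decimal — is applied here only; upstream values
#' stay unrounded.
#'
#' @param summaries Data frame of rows from [summarize_variability()],
#'   sharing one parameter and route.
#' @param gm_digits Significant digits for the geometric mean column.
#' @return Data frame of formatted character/numeric report columns.
#' @export
build_report_table <- function(summaries, gm_digits = 3) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  if (length(unique(paste(summaries$parameter, summaries$route))) > 1L) {
    stop("summaries must share one parameter x route grouping")
  }
  ord <- order(summaries$scope == "overall", summaries$scope)
  summaries <- summaries[ord, , drop = FALSE]
  uf_cols <- unique(sub("_(median|lo95|hi95)$", "",
                        grep("^uf", names(summaries), value = TRUE)))
  out <- data.frame(
    compound = summaries$scope,
    nst = summaries$nst,
    n = summaries$n_total,
    cv_pct = round_half_up(100 * summaries$cv_median),
    gm = signif(summaries$gm_median, gm_digits),
    stringsAsFactors = FALSE
  )
  fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)
  for (col in uf_cols) {
    out[[col]] <- fmt1(summaries[[paste0(col, "_median")]])
    out[[paste0(col, "_ci")]] <- paste0(
      fmt1(summaries[[paste0(col, "_lo95")]]), "-",
      fmt1(summaries[[paste0(col, "_hi95")]]))
  }
  rownames(out) <- NULL
  out
}

#' Write a report table as aligned plain text
#'
#' @param table Output of [build_report_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_text <- function(table, path) {
  txt <- utils::capture.output(print(table, row.names = FALSE))
  writeLines(txt, path)
  invisible(path)
}
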