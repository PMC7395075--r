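# Genotype-level presentation summaries: SNP genotype frequencies and
# AUC ratios of variant genotypes relative to wild type. Pure arithmetic on
# collated literature counts; no statistical testing is performed here.

#' Genotype frequencies from wt/wt, wt/var, var/var counts
#'
#' @param counts Numeric vector of three nonnegative genotype counts in the
#'   order wild-type homozygote, heterozygote, variant homozygote (names,
#'   if present, are preserved).
#' @return Fractions summing to 1.
#' @export
genotype_frequencies <- function(counts) {
  if (length(counts) != 3L || !is.numeric(counts)) {
    stop("counts must be three numbers: wt/wt, wt/var, var/var")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  total <- sum(counts)
  if (total == 0) stop("all genotype counts are zero")
  out <- counts / total
  if (is.null(names(out))) names(out) <- c("wt_wt", "wt_var", "var_var")
  out
}

#' AUC of each genotype group as a percentage of wild type
#'
#' @param auc_values Named numeric vector of genotype-group AUCs (same
#'   units); must contain a `"wt_wt"` entry with a positive value.
#' @return Named vector of percentages; `wt_wt` maps to 100.
#' @export
auc_ratio_to_wildtype <- function(auc_values) {
  if (is.null(names(auc_values)) || !("wt_wt" %in% names(auc_values))) {
    stop("auc_values must contain a 'wt_wt' entry")
  }
  wt <- auc_values[["wt_wt"]]
  if (!is.finite(wt) || wt <= 0) stop("wild-type AUC must be > 0")
  if (any(auc_values <= 0)) stop("AUC values must be > 0")
  100 * auc_values / wt
}

#' Genotype frequency table for several populations
#'
#' Convenience wrapper over [genotype_frequencies()] for a collated counts
#' table (CSV-friendly layout).
#'
#' @param df Data frame with columns `population`, `snp_id`, `wt_wt`,
#'   `wt_var`, `var_var`.
#' @return The input with three frequency columns `f_wt_wt`, `f_wt_var`,
#'   `f_var_var` appended.
#' @export
genotype_frequency_table <- function(df) {
  req <- c("population", "snp_id", "wt_wt", "wt_var", "var_var")
  if (!all(req %in% names(df))) {
    stop("need columns: ", paste(req, collapse = ", "))
  }
  f <- t(apply(df[, c("wt_wt", "wt_var", "var_var")], 1,
               function(x) genotype_frequencies(as.numeric(x))))
  df$f_wt_wt <- f[, 1]
  df$f_wt_var <- f[, 2]
  df$f_var_var <- f[, 3]
  df
}
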