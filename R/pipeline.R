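# End-to-end pipeline: read/simulate -> validate -> select -> normalise ->
# fit -> summarise -> report, with every artifact written to one output
# directory and listed (with checksums) in a JSON manifest. Input files are
# never modified.

#' Pipeline configuration
#'
#' Exactly one of `input` (path to a PK summary CSV) or `preset` (a
#' [make_isoform_preset()] name) must be given.
#'
#' @param input Path to a PK database CSV, or `NULL`.
#' @param preset Synthetic preset name, or `NULL`.
#' @param out_dir Output directory (created if absent).
#' @param route,parameter Analysis slice to model.
#' @param substrates Substrates to include (`NULL` = all present in the
#'   slice).
#' @param include_patients,include_repeated Inclusion flags passed to
#'   [select_analysis_set()].
#' @param norm_config A [normalization_config()].
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param percentiles UF percentiles, each in (50, 100).
#' @param seed Master seed (also seeds the preset generator and the MCMC
#'   unless `mcmc` overrides it explicitly).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, preset = NULL, out_dir,
                            route = "oral", parameter = "auc",
                            substrates = NULL,
                            include_patients = FALSE,
                            include_repeated = FALSE,
                            norm_config = normalization_config(),
                            priors = prior_config(),
                            mcmc = NULL,
                            percentiles = c(95, 97.5),
                            seed = 1) {
  if (is.null(input) == is.null(preset)) {
    stop("give exactly one of 'input' or 'preset'")
  }
  stopifnot(all(percentiles > 50), all(percentiles < 100))
  if (is.null(mcmc)) mcmc <- mcmc_config(seed = seed)
  structure(list(input = input, preset = preset, out_dir = out_dir,
                 route = route, parameter = parameter,
                 substrates = substrates,
                 include_patients = include_patients,
                 include_repeated = include_repeated,
                 norm_config = norm_config, priors = priors, mcmc = mcmc,
                 percentiles = percentiles, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full variability analysis pipeline
#'
#' Executes read/simulate, validate, select, normalise, fit, summarise and
#' report in order, writing these artifacts under `cfg$out_dir`:
#' `normalized_observations.csv`, `posterior_draws.csv`,
#' `diagnostics.json`, `report_table.csv`, `report_table.txt`,
#' `forest_data.csv` and `manifest.json` (paths, MD5 checksums, seeds,
#' record counts and the convergence flag). Reruns with an identical
#' configuration produce byte-identical artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (list; `$converged` carries the
#'   diagnostic outcome).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$preset)) {
    sim <- .stage("simulate", {
      scenario <- make_isoform_preset(cfg$preset, seed = cfg$seed)
      simulate_study_summaries(scenario)
    })
    db <- sim$database
  } else {
    db <- .stage("read", read_pk_database(cfg$input))
    sim <- NULL
  }
  .stage("validate", {
    v <- validate_records(db, bsa_substrates = cfg$norm_config$bsa_substrates)
    if (nrow(v) > 0L) {
      stop(sprintf("%d record(s) violate invariants (first: record %d, %s)",
                   nrow(v), v$record[1], v$rule[1]))
    }
  })
  selected <- .stage("select", {
    subs <- cfg$substrates
    if (is.null(subs)) {
      keep <- db$records$route == cfg$route &
        db$records$parameter == cfg$parameter
      subs <- sort(unique(db$records$substrate_id[keep]))
    }
    parts <- lapply(subs, function(s) {
      select_analysis_set(db, s, cfg$route, cfg$parameter,
                          include_patients = cfg$include_patients,
                          include_repeated = cfg$include_repeated)$records
    })
    out <- pk_database(do.call(rbind, c(parts, list(db$records[0, ]))))
    if (nrecords(out) == 0L) stop("no records after filtering")
    out
  })
  obs <- .stage("normalize", normalize_database(selected, cfg$norm_config))
  fit <- .stage("fit", fit_pkvar(obs, priors = cfg$priors, mcmc = cfg$mcmc))
  summaries <- .stage("summarize",
                      summary(fit, percentiles = cfg$percentiles))
  report <- .stage("report", build_report_table(summaries))

  path <- function(f) file.path(cfg$out_dir, f)
  utils::write.csv(obs, path("normalized_observations.csv"),
                   row.names = FALSE)
  export_draws(fit$draws, path("posterior_draws.csv"))
  diag <- fit$diagnostics
  jsonlite::write_json(
    list(pass = diag$pass, rhat_threshold = diag$rhat_threshold,
         min_ess = diag$min_ess, parameters = diag$summary),
    path("diagnostics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report, path("report_table.csv"), row.names = FALSE)
  write_report_text(report, path("report_table.txt"))
  export_forest_data(summaries, path("forest_data.csv"))

  artifacts <- c("normalized_observations.csv", "posterior_draws.csv",
                 "diagnostics.json", "report_table.csv", "report_table.txt",
                 "forest_data.csv")
  manifest <- list(
    seed = cfg$seed,
    input = if (is.null(cfg$input)) paste0("preset:", cfg$preset)
      else cfg$input,
    route = cfg$route, parameter = cfg$parameter,
    n_records_model = nrow(obs),
    substrates = fit$spec$substrates,
    converged = isTRUE(fit$converged),
    artifacts = lapply(artifacts, function(f) {
      list(file = f, md5 = unname(tools::md5sum(path(f))))
    })
  )
  if (!is.null(sim)) {
    jsonlite::write_json(sim$truth, path("truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest$artifacts <- c(manifest$artifacts,
                            list(list(file = "truth.json",
                                      md5 = unname(tools::md5sum(
                                        path("truth.json"))))))
  }
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Export variability summaries in forest-plot layout
#'
#' One row per scope x route x parameter, columns holding the posterior
#' median and 95% bounds for GM, CV and each UF, sorted by scope for a
#' stable order. Written with full precision so a read round-trips to at
#' least six significant digits.
#'
#' @param summaries Data frame of [summarize_variability()] rows.
#' @param path Optional CSV path; when given the frame is also written.
#' @return The (sorted) data frame, invisibly when writing.
#' @export
export_forest_data <- function(summaries, path = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  out <- summaries[order(summaries$scope, summaries$route,
                         summaries$parameter), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(format(out, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
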