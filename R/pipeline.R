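#' Assemble a run configuration
#'
#' One object drives [run_full_analysis()]: either a synthetic-series
#' request or input file paths, plus field, search and contour settings.
#' All defaults echo the classical settings (2 A grid, 4 A margin,
#' attenuation 0.3, 30 kcal/mol cutoff, 100 bootstrap runs, 1.0 log-unit
#' outlier threshold, 80/20 contour levels). Can also be read from a YAML
#' file with [read_run_config()]; the effective configuration is
#' serialized into the output directory for provenance.
#'
#' @param output_dir Where the report bundle is written.
#' @param input Optional list: `sdf` (path), `activity_tag`,
#'   `activities_csv` (sidecar path with id/activity-or-value/role),
#'   `alignment` (list: `template_id`, `n_common` for a shared-prefix
#'   map).
#' @param synthetic Optional `synthetic_spec` (used when `input` is NULL).
#' @param spacing,margin Lattice settings.
#' @param attenuation,energy_cutoff Field settings.
#' @param comsia_kinds CoMSIA kinds searched.
#' @param include_comfa Add the CoMFA pair candidate.
#' @param bootstrap_runs,max_components,tie_tol Search settings.
#' @param outlier_threshold Log-unit residual threshold.
#' @param favored_pct,disfavored_pct Contour levels.
#' @param seed Seed for every stochastic stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(output_dir,
                       input = NULL, synthetic = NULL,
                       spacing = 2.0, margin = 4.0,
                       attenuation = 0.3, energy_cutoff = 30,
                       comsia_kinds = COMSIA_KINDS, include_comfa = TRUE,
                       bootstrap_runs = 100L, max_components = NULL,
                       tie_tol = 0.005, outlier_threshold = 1.0,
                       favored_pct = 80, disfavored_pct = 20,
                       seed = 1L) {
  if (is.null(input) && is.null(synthetic))
    stop("config needs either an input block or a synthetic spec")
  structure(list(output_dir = output_dir, input = input,
                 synthetic = synthetic, spacing = spacing, margin = margin,
                 attenuation = attenuation, energy_cutoff = energy_cutoff,
                 comsia_kinds = comsia_kinds,
                 include_comfa = isTRUE(include_comfa),
                 bootstrap_runs = as.integer(bootstrap_runs),
                 max_components = max_components, tie_tol = tie_tol,
                 outlier_threshold = outlier_threshold,
                 favored_pct = favored_pct, disfavored_pct = disfavored_pct,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `synthetic` block
#' is passed to [synthetic_spec()].
#'
#' @param path YAML file.
#' @param seed Optional seed override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic))
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  if (!is.null(seed)) raw$seed <- seed
  do.call(run_config, raw)
}

.load_input <- function(cfg) {
  inp <- cfg$input
  acts <- if (!is.null(inp$activities_csv))
    utils::read.csv(inp$activities_csv, stringsAsFactors = FALSE) else NULL
  mols <- read_molecules(inp$sdf, format = "sdf",
                         activity_tag = if (is.null(inp$activity_tag))
                           "pKi" else inp$activity_tag,
                         activities = acts)
  if (!is.null(inp$alignment)) {
    spec <- common_prefix_spec(mols, inp$alignment$template_id,
                               inp$alignment$n_common)
    mols <- align_to_template(mols, spec)$molecules
  }
  roles <- vapply(mols, function(m) m$role, character(1))
  list(train = mols[roles == "train"], test = mols[roles == "test"])
}

#' Run the full 3D-QSAR analysis
#'
#' End to end: load or generate the series, align (when an alignment block
#' is configured), build the lattice and field blocks, search every field
#' combination, compute the top model's full statistics block, flag
#' residual outliers, and extract StDev*Coeff contour grids (one DX file
#' per field of the top model). Everything is written under the
#' configured output directory: `search_report.csv` / `.json` (all
#' candidates), `top_model.json` (the classical summary-statistics rows),
#' `outliers.csv`, `predictions.csv`, `contour_<kind>.dx` (+ JSON
#' sidecars), and `config_used.yaml`. Deterministic for a fixed seed.
#'
#' @param config A `run_config` or the path to a YAML file.
#' @return Invisible list: `search`, `outliers`, `grids`, `series`, plus
#'   the file paths written.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  series <- if (!is.null(config$input)) .load_input(config)
            else generate_series(config$synthetic)
  fc <- field_config(attenuation = config$attenuation,
                     energy_cutoff = config$energy_cutoff)
  sc <- search_config(max_components = config$max_components,
                      tie_tol = config$tie_tol,
                      bootstrap_runs = config$bootstrap_runs,
                      seed = config$seed,
                      include_comfa = config$include_comfa)
  lattice <- build_lattice(c(series$train, series$test),
                           spacing = config$spacing, margin = config$margin)
  search <- run_search(series$train, series$test, lattice = lattice,
                       fconfig = fc, sconfig = sc,
                       comsia_kinds = config$comsia_kinds)
  top <- top_candidate(search)
  outliers <- flag_outliers(search, series$train,
                            threshold = config$outlier_threshold)
  grids <- list()
  for (k in top$kinds) {
    g <- stdev_coeff_grid(top$model, top$dset, search$lattice, k)
    g <- levels_by_contribution(g, config$favored_pct, config$disfavored_pct)
    export_grid(g, file.path(outdir, paste0("contour_", k, ".dx")),
                format = "dx")
    grids[[k]] <- g
  }
  utils::write.csv(search$report, file.path(outdir, "search_report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(search$report,
                       file.path(outdir, "search_report.json"),
                       dataframe = "rows", digits = 10, na = "null")
  jsonlite::write_json(stats_table(search),
                       file.path(outdir, "top_model.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")
  utils::write.csv(outliers, file.path(outdir, "outliers.csv"),
                   row.names = FALSE)
  preds <- data.frame(
    id = c(search$train_ids,
           vapply(series$test, function(m) m$id, character(1))),
    role = c(rep("train", length(series$train)),
             rep("test", length(series$test))),
    actual = c(vapply(series$train, function(m) m$activity, numeric(1)),
               vapply(series$test, function(m) m$activity, numeric(1))),
    predicted = c(top$model$fitted,
                  if (is.null(top$test_pred)) numeric(0) else top$test_pred))
  utils::write.csv(preds, file.path(outdir, "predictions.csv"),
                   row.names = FALSE)
  cfg_out <- config
  cfg_out$synthetic <- if (!is.null(config$synthetic))
    unclass(config$synthetic) else NULL
  yaml::write_yaml(unclass(cfg_out), file.path(outdir, "config_used.yaml"))
  invisible(list(search = search, outliers = outliers, grids = grids,
                 series = series, output_dir = outdir))
}

#' Summary-statistics block for the top model
#'
#' The classical one-column summary: q2, r2_ncv, SEE, F, r2_pred, SEP,
#' component count, bootstrap means, and the per-field contribution
#' shares.
#'
#' @param search A `qsar_search`.
#' @param candidate Candidate to summarize (default top).
#' @return Named list.
#' @export
stats_table <- function(search, candidate = top_candidate(search)) {
  s <- candidate$stats
  list(fields = paste(candidate$kinds, collapse = "+"),
       q2 = s$q2, r2_ncv = s$r2_ncv, see = s$see, fstat = s$fstat,
       r2_pred = s$r2_pred, sep = s$sep, n_components = s$n_components,
       r2_boot = s$r2_boot, sd_boot = s$sd_boot, see_boot = s$see_boot,
       field_contributions = as.list(s$contributions))
}

#' Predict new molecules with a finished analysis
#'
#' Aligns nothing (molecules are assumed on the model frame already unless
#' an alignment spec is given), computes the top candidate's fields on the
#' stored lattice, and predicts activities. When actual activities are
#' present on every molecule the external-validation statistics
#' (predictive r2, SD, PRESS) are reported too. A molecule that cannot be
#' processed yields a per-molecule failure record instead of aborting the
#' batch.
#'
#' @param search A `qsar_search` (e.g. `result$search` from
#'   [run_full_analysis()]).
#' @param molecules List of `qsar_molecule`.
#' @param alignment Optional `alignment_spec` applied first (the template
#'   must be among `molecules`).
#' @return List: `predictions` (data.frame id, predicted, actual,
#'   failure), `r2_pred`, `sd`, `press` (NA unless actuals present).
#' @export
run_predict <- function(search, molecules, alignment = NULL) {
  if (!is.null(alignment))
    molecules <- align_to_template(molecules, alignment)$molecules
  n <- length(molecules)
  pred <- rep(NA_real_, n); fail <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- tryCatch(predict_activities(search, molecules[i]),
                  error = function(e) conditionMessage(e))
    if (is.numeric(p)) pred[i] <- p else fail[i] <- p
  }
  actual <- vapply(molecules, function(m) m$activity, numeric(1))
  out <- data.frame(id = vapply(molecules, function(m) m$id, character(1)),
                    predicted = pred, actual = actual, failure = fail,
                    stringsAsFactors = FALSE)
  r2 <- list(r2_pred = NA_real_, sd = NA_real_, press = NA_real_)
  r2_error <- NA_character_
  if (!anyNA(actual) && !anyNA(pred))
    r2 <- tryCatch(predictive_r2(pred, actual, search$y_train_mean),
                   error = function(e) {
                     r2_error <<- conditionMessage(e)
                     r2
                   })
  list(predictions = out, r2_pred = r2$r2_pred, sd = r2$sd,
       press = r2$press, r2_error = r2_error)
}
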