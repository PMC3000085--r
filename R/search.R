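#' Enumerate all non-empty field-kind subsets
#'
#' For the five CoMSIA properties this yields the classical 31 candidate
#' descriptor combinations. Deterministic order: by subset size, then
#' lexicographically within a size.
#'
#' @param kinds Character vector of available field kinds.
#' @return List of character vectors (the subsets).
#' @export
enumerate_field_sets <- function(kinds) {
  if (!length(kinds)) stop("no field kinds supplied")
  kinds <- sort(unique(kinds))
  out <- list()
  for (sz in seq_along(kinds)) {
    combos <- utils::combn(kinds, sz, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, character(1), collapse = " "))]
    out <- c(out, combos)
  }
  out
}

#' Search configuration
#'
#' @param max_components Largest PLS component count scanned (default
#'   `min(10, floor(n/3))`, applied at run time).
#' @param tie_tol q2 tie tolerance for component selection.
#' @param parsimony_window Demote a candidate whose q2 beats a
#'   substantially smaller model's by less than this (default 0.02).
#' @param parsimony_gap "Substantially smaller" = at least this many fewer
#'   components (default 2).
#' @param bootstrap_runs Bootstrap runs per candidate (default 100; 0
#'   disables bootstrap during the search).
#' @param seed Seed for the bootstrap resampling.
#' @param include_comfa Also evaluate the CoMFA steric+electrostatic pair
#'   as one extra candidate.
#' @param autoscale Per-column autoscaling inside PLS.
#' @return Object of class `search_config`.
#' @export
search_config <- function(max_components = NULL, tie_tol = 0.005,
                          parsimony_window = 0.02, parsimony_gap = 2L,
                          bootstrap_runs = 100L, seed = 1L,
                          include_comfa = TRUE, autoscale = FALSE) {
  structure(list(max_components = max_components, tie_tol = tie_tol,
                 parsimony_window = parsimony_window,
                 parsimony_gap = as.integer(parsimony_gap),
                 bootstrap_runs = as.integer(bootstrap_runs),
                 seed = as.integer(seed),
                 include_comfa = isTRUE(include_comfa),
                 autoscale = isTRUE(autoscale)),
            class = "search_config")
}

# evaluate one candidate field set; blocks_* are full named block lists
.eval_candidate <- function(kinds, blocks_train, blocks_test, y_train, y_test,
                            cfg) {
  dset <- assemble_descriptors(blocks_train[kinds])
  sel <- select_components(dset$X, y_train, cfg$max_components,
                           tie_tol = cfg$tie_tol, autoscale = cfg$autoscale)
  nc <- sel$n_components
  # the component scan already ran the LOO at every count
  ss <- sum((y_train - mean(y_train))^2)
  loo <- list(q2 = sel$q2[nc], sep = sel$sep[nc],
              press = (1 - sel$q2[nc]) * ss)
  loo_pred <- sel$loo_pred[, nc]
  model <- fit_pls(dset$X, y_train, nc, autoscale = cfg$autoscale)
  fs <- final_stats(model, dset$X, y_train)
  contrib <- field_contributions(model, dset$index)
  boot <- if (cfg$bootstrap_runs >= 2)
    bootstrap_validate(dset$X, y_train, nc, runs = cfg$bootstrap_runs,
                       seed = cfg$seed, autoscale = cfg$autoscale)
  else list(r2_boot = NA_real_, sd_boot = NA_real_, see_boot = NA_real_)
  pred <- NULL; rp <- list(r2_pred = NA_real_, sd = NA_real_, press = NA_real_)
  if (!is.null(blocks_test) && length(y_test)) {
    Xt <- project_descriptors(dset, blocks_test)
    pred <- predict(model, Xt)
    rp <- tryCatch(predictive_r2(pred, y_test, mean(y_train)),
                   error = function(e) rp)
  }
  list(kinds = kinds, dset = dset, model = model, test_pred = pred,
       loo_pred = loo_pred,
       stats = list(q2 = loo$q2, sep = loo$sep, press = loo$press,
                    r2_ncv = fs$r2_ncv, see = fs$see, fstat = fs$fstat,
                    n_components = nc,
                    r2_boot = boot$r2_boot, sd_boot = boot$sd_boot,
                    see_boot = boot$see_boot,
                    r2_pred = rp$r2_pred, sd = rp$sd, press_test = rp$press,
                    contributions = contrib),
       status = "ok")
}

#' Exhaustive field-combination model search
#'
#' Evaluates every non-empty subset of the available CoMSIA field kinds
#' (31 subsets for the five classical properties), plus optionally the
#' CoMFA steric+electrostatic pair as one extra candidate. For each
#' candidate: descriptors are assembled (CoMFA-STD scaling), the component
#' count is chosen by LOO q2, and the full validation battery is computed
#' (q2, SEP, r2_ncv, SEE, F, bootstrap, predictive r2 on the test set,
#' field contributions). Candidates are ranked by q2 descending; a
#' candidate that beats a model with at least `parsimony_gap` fewer
#' components by less than `parsimony_window` in q2 is demoted below all
#' non-demoted candidates (the classical preference for comparable
#' predictions at fewer components). A candidate whose descriptor assembly
#' or fit fails is recorded with status `"failed"` and the search
#' continues.
#'
#' @param train,test Lists of `qsar_molecule` with activities (test may be
#'   empty).
#' @param lattice Optional `grid_lattice`; built from train+test with the
#'   defaults when NULL.
#' @param fconfig A `field_config`.
#' @param sconfig A `search_config`.
#' @param comsia_kinds CoMSIA kinds to search over (default all five).
#' @return Object of class `qsar_search`: `report` (one row per candidate),
#'   `candidates` (full objects incl. fitted models), `lattice`, configs.
#' @export
run_search <- function(train, test = list(), lattice = NULL,
                       fconfig = field_config(), sconfig = search_config(),
                       comsia_kinds = COMSIA_KINDS) {
  if (length(train) < 6) stop("need at least 6 training molecules")
  y_train <- vapply(train, function(m) m$activity, numeric(1))
  if (anyNA(y_train)) stop("every training molecule needs an activity")
  y_test <- vapply(test, function(m) m$activity, numeric(1))
  if (is.null(lattice)) lattice <- build_lattice(c(train, test))
  all_kinds <- unique(c(comsia_kinds,
                        if (sconfig$include_comfa)
                          c("comfa_steric", "comfa_electrostatic")))
  fc <- fconfig; fc$field_kinds <- all_kinds
  blocks_train <- compute_field_blocks(train, lattice, fc)
  blocks_test <- if (length(test)) compute_field_blocks(test, lattice, fc)
                 else NULL
  sets <- enumerate_field_sets(comsia_kinds)
  if (sconfig$include_comfa)
    sets <- c(sets, list(c("comfa_steric", "comfa_electrostatic")))
  cands <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    cands[[i]] <- tryCatch(
      .eval_candidate(sets[[i]], blocks_train, blocks_test, y_train, y_test,
                      sconfig),
      error = function(e) list(kinds = sets[[i]], stats = NULL,
                               status = paste("failed:",
                                              conditionMessage(e))))
  }
  report <- .search_report(cands)
  ord <- .rank_candidates(report, sconfig)
  report <- report[ord, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  cands <- cands[ord]
  structure(list(report = report, candidates = cands, lattice = lattice,
                 field_config = fconfig, search_config = sconfig,
                 train_ids = vapply(train, function(m) m$id, character(1)),
                 y_train = y_train, y_train_mean = mean(y_train)),
            class = "qsar_search")
}

.search_report <- function(cands) {
  rows <- lapply(cands, function(cd) {
    nm <- paste(cd$kinds, collapse = "+")
    if (is.null(cd$stats)) {
      data.frame(fields = nm, n_components = NA_integer_, q2 = NA_real_,
                 sep = NA_real_, r2_ncv = NA_real_, see = NA_real_,
                 fstat = NA_real_, r2_pred = NA_real_, r2_boot = NA_real_,
                 sd_boot = NA_real_, see_boot = NA_real_,
                 status = cd$status, stringsAsFactors = FALSE)
    } else {
      s <- cd$stats
      data.frame(fields = nm, n_components = s$n_components, q2 = s$q2,
                 sep = s$sep, r2_ncv = s$r2_ncv, see = s$see,
                 fstat = s$fstat, r2_pred = s$r2_pred, r2_boot = s$r2_boot,
                 sd_boot = s$sd_boot, see_boot = s$see_boot,
                 status = cd$status, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# rank: ok candidates by q2 desc (demoted ones after all non-demoted),
# failures last. Candidates whose q2 ties the best within tie_tol are
# ordered by simplicity first (fewer field kinds, then fewer components,
# then enumeration order): at that resolution the models are statistically
# indistinguishable and the simpler description wins.
.rank_candidates <- function(report, cfg) {
  ok <- which(report$status == "ok")
  demoted <- rep(FALSE, nrow(report))
  for (i in ok) {
    smaller <- ok[report$n_components[ok] <= report$n_components[i] -
                    cfg$parsimony_gap]
    if (length(smaller) &&
        any(report$q2[smaller] >= report$q2[i] - cfg$parsimony_window))
      demoted[i] <- TRUE
  }
  key_group <- ifelse(report$status != "ok", 2L, ifelse(demoted, 1L, 0L))
  q2 <- ifelse(is.na(report$q2), -Inf, report$q2)
  nkinds <- lengths(strsplit(report$fields, "+", fixed = TRUE))
  lead <- which(key_group == 0L)
  tied <- rep(FALSE, nrow(report))
  if (length(lead)) {
    best <- max(q2[lead])
    # "comparable predictions" at the search level: the parsimony window
    tied[lead] <- q2[lead] >= best - cfg$parsimony_window
  }
  order(key_group,
        !tied,
        ifelse(tied, nkinds, 0L),
        ifelse(tied, report$n_components, 0L),
        -q2,
        seq_len(nrow(report)))
}

#' Top candidate of a search
#' @param search A `qsar_search`.
#' @return The first ranked candidate (list with model, descriptor set, stats).
#' @export
top_candidate <- function(search) {
  stopifnot(inherits(search, "qsar_search"))
  search$candidates[[1]]
}

#' Predict activities for molecules with a search candidate
#'
#' Computes the candidate's field blocks for the given molecules on the
#' search lattice, projects them onto the candidate's descriptor columns
#' and scales, and applies the PLS model.
#'
#' @param search A `qsar_search`.
#' @param molecules List of aligned `qsar_molecule`.
#' @param candidate A candidate from the search (default the top one).
#' @return Numeric predictions (p-units), named by molecule id.
#' @export
predict_activities <- function(search, molecules,
                               candidate = top_candidate(search)) {
  fc <- search$field_config
  fc$field_kinds <- candidate$kinds
  blocks <- compute_field_blocks(molecules, search$lattice, fc)
  Xn <- project_descriptors(candidate$dset, blocks)
  stats::setNames(predict(candidate$model, Xn),
                  vapply(molecules, function(m) m$id, character(1)))
}

#' Flag residual outliers
#'
#' Residual = actual - predicted activity; molecules whose absolute
#' residual exceeds the threshold (default 1.0 logarithmic unit, the
#' classical rule) are flagged. For molecules that are part of the
#' candidate's own training set the cross-validated (leave-one-out)
#' prediction is used: a fitted high-dimensional PLS model shrinks the
#' training residual of even a grossly mislabeled compound towards zero,
#' so only the held-out residual can reveal it. Other molecules are
#' predicted directly. Reported sorted by absolute residual, descending.
#' Flagged compounds are left for the analyst to exclude; nothing is
#' removed automatically.
#'
#' @param search A `qsar_search`.
#' @param molecules Molecules with known activities.
#' @param threshold Log-unit threshold (default 1.0).
#' @param candidate Search candidate used for prediction (default top).
#' @param cv Use LOO predictions for training molecules (default TRUE).
#' @return data.frame `id`, `actual`, `predicted`, `residual`, `flagged`.
#' @export
flag_outliers <- function(search, molecules, threshold = 1.0,
                          candidate = top_candidate(search), cv = TRUE) {
  y <- vapply(molecules, function(m) m$activity, numeric(1))
  if (anyNA(y)) stop("every molecule needs an activity to compute residuals")
  pred <- predict_activities(search, molecules, candidate)
  if (cv && !is.null(candidate$loo_pred)) {
    ids <- names(pred)
    hit <- match(ids, search$train_ids)
    use <- !is.na(hit)
    pred[use] <- candidate$loo_pred[hit[use]]
  }
  res <- y - pred
  out <- data.frame(id = names(pred), actual = y, predicted = unname(pred),
                    residual = unname(res),
                    flagged = abs(res) > threshold,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$residual)), , drop = FALSE]
}
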