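#' Fit a PLS1 regression (NIPALS)
#'
#' Classical single-response partial least squares: descriptors are
#' mean-centered (optionally autoscaled), latent components are extracted
#' sequentially by the NIPALS recursion, and the regression vector is
#' returned on the original descriptor scale. Deterministic for fixed
#' input. Extraction stops early, below the requested number of
#' components, only if the residual descriptor matrix is numerically
#' exhausted (perfect fit); the model records the number actually used.
#'
#' @param X Descriptor matrix (n x p), no missing values.
#' @param y Activity vector, length n, non-constant.
#' @param n_components Number of latent components (1 <= Nc <= min(n-1, p)).
#' @param autoscale Divide each column by its SD before fitting (default
#'   FALSE; block scaling is normally applied upstream).
#' @return Object of class `pls_model`: `coef` (original scale),
#'   `intercept`, `n_components`, centering/scaling record, fitted values,
#'   per-column training SDs (`xsd`, for StDev*Coeff maps and field
#'   contributions).
#' @export
fit_pls <- function(X, y, n_components, autoscale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("y is constant; nothing to model")
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components out of bounds: need 1 <= Nc <= min(n-1, p) = ",
         min(n - 1, p))
  path <- .pls_path(X, y, n_components, autoscale)
  ncomp <- path$ncomp
  b <- path$B[, ncomp]
  structure(list(
    coef = b,
    intercept = path$ymean - sum(path$xmean * b),
    n_components = ncomp,
    requested_components = n_components,
    autoscale = autoscale,
    xmean = path$xmean, xscale = path$xscale, ymean = path$ymean,
    xsd = path$xsd,
    fitted = drop(X %*% b) + (path$ymean - sum(path$xmean * b)),
    n = n, p = p
  ), class = "pls_model")
}

# vectorized column standard deviations (denominator n - 1)
.col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(NA_real_, ncol(X)))
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

# NIPALS PLS1 returning the cumulative coefficient vector (original X scale)
# after each component: B is p x ncomp. Centering/scaling computed here so
# cross-validation folds re-estimate it.
.pls_path <- function(X, y, ncomp, autoscale = FALSE) {
  n <- nrow(X); p <- ncol(X)
  xmean <- colMeans(X)
  xsd <- .col_sds(X)
  xscale <- if (autoscale) ifelse(xsd > 0, xsd, 1) else rep(1, p)
  Xc <- sweep(sweep(X, 2, xmean), 2, xscale, FUN = "/")
  ymean <- mean(y)
  yc <- y - ymean
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); qv <- numeric(ncomp)
  a <- 0
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pvec <- drop(crossprod(Xc, t)) / tt
    qh <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pvec)
    yc <- yc - qh * t
    a <- h
    W[, h] <- w; P[, h] <- pvec; qv[h] <- qh
  }
  if (a == 0) stop("no usable PLS component (X'y vanishes)")
  B <- matrix(0, p, a)
  for (h in seq_len(a)) {
    Ph <- P[, seq_len(h), drop = FALSE]
    Wh <- W[, seq_len(h), drop = FALSE]
    Bc <- Wh %*% solve(crossprod(Ph, Wh), qv[seq_len(h)])
    B[, h] <- drop(Bc) / xscale
  }
  list(B = B, ncomp = a, xmean = xmean, xscale = xscale, ymean = ymean,
       xsd = xsd)
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$coef) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d training molecules, %d descriptors\n",
              x$n_components, x$n, x$p))
  invisible(x)
}

# LOO predictions for components 1..ncomp: one NIPALS path per fold
# (components are nested, so a single fit yields every component count).
# Returns an n x ncomp matrix of held-out predictions.
.loo_predictions <- function(X, y, ncomp, autoscale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  preds <- matrix(NA_real_, n, ncomp)
  for (i in seq_len(n)) {
    path <- .pls_path(X[-i, , drop = FALSE], y[-i], ncomp, autoscale)
    for (h in seq_len(ncomp)) {
      hh <- min(h, path$ncomp)
      b <- path$B[, hh]
      preds[i, h] <- sum(X[i, ] * b) + (path$ymean - sum(path$xmean * b))
    }
  }
  preds
}

#' Leave-one-out cross-validation
#'
#' Refits the PLS model n times, each time leaving one molecule out
#' (centering and any scaling re-estimated inside the fold), and predicts
#' the held-out activity. `q2 = 1 - PRESS / sum((y - mean(y))^2)` with the
#' full-training-set mean in the denominator (the classical convention),
#' and `SEP = sqrt(PRESS / (n - Nc - 1))`.
#'
#' @param X Descriptor matrix.
#' @param y Activities.
#' @param n_components Number of PLS components (must be <= n - 2 so every
#'   fold can fit it).
#' @param autoscale Passed to the fold fits.
#' @return List with `q2`, `sep`, `press`.
#' @export
loo_validation <- function(X, y, n_components, autoscale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 molecules for LOO")
  if (n_components >= n - 1)
    stop("n_components must be <= n - 2 for LOO refits")
  preds <- .loo_predictions(X, y, n_components, autoscale)[, n_components]
  press <- sum((y - preds)^2)
  ss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / ss,
       sep = sqrt(press / (n - n_components - 1)),
       press = press)
}

#' Choose the number of PLS components by LOO q2
#'
#' Scans 1..`max_components`, computes the LOO q2 at each count, and
#' returns the count with the highest q2; counts whose q2 comes within
#' `tie_tol` of the best are treated as ties and the smallest such count
#' wins (parsimony: equal internal prediction at lower SEP).
#'
#' @param X Descriptor matrix.
#' @param y Activities.
#' @param max_components Largest count to scan; default `min(10,
#'   floor(n/3))`, never above `n - 2` or `ncol(X)`.
#' @param tie_tol q2 window regarded as a tie (default 0.005).
#' @param autoscale Passed through.
#' @return List with `n_components`, the scanned `q2` / `sep` vectors, and
#'   `loo_pred` (n x max_components matrix of held-out predictions).
#' @export
select_components <- function(X, y, max_components = NULL, tie_tol = 0.005,
                              autoscale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  cap <- min(n - 2L, ncol(X))
  if (is.null(max_components)) max_components <- min(10L, floor(n / 3))
  max_components <- min(max_components, cap)
  if (max_components < 1) stop("cannot scan any component count (n too small)")
  preds <- .loo_predictions(X, y, max_components, autoscale)
  ss <- sum((y - mean(y))^2)
  press <- colSums((y - preds)^2)
  q2 <- 1 - press / ss
  sep <- sqrt(press / (n - seq_len(max_components) - 1))
  best <- max(q2)
  nc <- which(q2 >= best - tie_tol)[1]
  list(n_components = as.integer(nc), q2 = q2, sep = sep, loo_pred = preds)
}

#' Non-cross-validated fit statistics
#'
#' `r2_ncv = 1 - RSS / sum((y - mean(y))^2)`,
#' `SEE = sqrt(RSS / (n - Nc - 1))`, and the PLS F statistic
#' `F = (r2 / Nc) / ((1 - r2) / (n - Nc - 1))`. A numerically perfect fit
#' returns `F = Inf`.
#'
#' @param model A fitted `pls_model`.
#' @param X,y The training data the model was fitted on.
#' @return List with `r2_ncv`, `see`, `fstat`.
#' @export
final_stats <- function(model, X, y) {
  n <- length(y); nc <- model$n_components
  if (n <= nc + 1) stop("need n > Nc + 1 for SEE and F")
  pred <- predict(model, X)
  rss <- sum((y - pred)^2)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  list(r2_ncv = r2,
       see = sqrt(rss / (n - nc - 1)),
       fstat = fstat_from_r2(r2, n, nc))
}

#' F statistic from r2, n and component count
#'
#' @param r2 Non-cross-validated r2.
#' @param n Number of training molecules.
#' @param nc Number of PLS components.
#' @return `(r2/nc) / ((1-r2)/(n-nc-1))`; `Inf` when `r2 == 1`.
#' @export
fstat_from_r2 <- function(r2, n, nc) {
  if (r2 >= 1) return(Inf)
  (r2 / nc) / ((1 - r2) / (n - nc - 1))
}

#' Predictive r2 on an external test set
#'
#' `r2_pred = (SD - PRESS) / SD`, where SD is the sum of squared deviations
#' of the test activities from the training-set mean activity and PRESS the
#' sum of squared prediction errors on the test set.
#'
#' @param predictions Predicted test activities.
#' @param y_test Actual test activities.
#' @param y_train_mean Mean activity of the training set.
#' @return List with `r2_pred`, `sd`, `press`.
#' @export
predictive_r2 <- function(predictions, y_test, y_train_mean) {
  if (length(y_test) < 1) stop("need at least one test molecule")
  if (length(predictions) != length(y_test))
    stop("predictions and y_test differ in length")
  sd_ <- sum((y_test - y_train_mean)^2)
  if (sd_ == 0)
    stop("SD is zero: every test activity equals the training mean")
  press <- sum((y_test - predictions)^2)
  list(r2_pred = (sd_ - press) / sd_, sd = sd_, press = press)
}

#' Bootstrap validation of a PLS model
#'
#' Resamples the training rows with replacement `runs` times, refits with
#' the parent model's component count, and records r2 and SEE on each
#' resample; reports the mean r2, its standard deviation, and the mean
#' SEE. A resample with constant activities is redrawn (at most 100 extra
#' draws per run). Fully reproducible for a fixed seed.
#'
#' @param X,y Training data.
#' @param n_components Component count (fixed across resamples).
#' @param runs Number of bootstrap runs (default 100, the classical
#'   battery).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param autoscale Passed through.
#' @return List with `r2_boot`, `sd_boot`, `see_boot`, `runs`.
#' @export
bootstrap_validate <- function(X, y, n_components, runs = 100, seed = 1,
                               autoscale = FALSE) {
  if (runs < 2) stop("need at least 2 bootstrap runs")
  X <- as.matrix(X)
  n <- nrow(X)
  withr::with_seed(seed, {
    r2s <- numeric(runs); sees <- numeric(runs)
    for (b in seq_len(runs)) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0
      while (stats::sd(y[idx]) == 0) {
        tries <- tries + 1
        if (tries > 100) stop("bootstrap resamples keep drawing constant y")
        idx <- sample.int(n, n, replace = TRUE)
      }
      m <- fit_pls(X[idx, , drop = FALSE], y[idx], n_components, autoscale)
      st <- final_stats(m, X[idx, , drop = FALSE], y[idx])
      r2s[b] <- st$r2_ncv; sees[b] <- st$see
    }
    list(r2_boot = mean(r2s), sd_boot = stats::sd(r2s),
         see_boot = mean(sees), runs = runs)
  })
}

#' Per-field-kind contribution shares
#'
#' The classical field-contribution decomposition: each descriptor column
#' contributes `|coefficient| * (column SD over the training molecules)`;
#' shares are summed per field kind and normalized to 1.
#'
#' @param model A fitted `pls_model`.
#' @param index Column index data.frame (`kind`, `column`), e.g.
#'   `dset$index` from [assemble_descriptors()].
#' @return Named numeric vector of shares summing to 1.
#' @export
field_contributions <- function(model, index) {
  if (!nrow(index)) stop("empty column index")
  if (nrow(index) != length(model$coef))
    stop("index does not cover the model's columns")
  contrib <- abs(model$coef) * model$xsd
  shares <- tapply(contrib, index$kind, sum)
  shares <- stats::setNames(as.numeric(shares), names(shares))
  total <- sum(shares)
  if (total == 0) return(shares * 0)
  shares / total
}
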