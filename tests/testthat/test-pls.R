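test_that("single-column PLS equals simple least squares", {
  fx <- rand_Xy(12, 1, seed = 5, noise = 0.3)
  m <- fit_pls(fx$X, fx$y, 1)
  ols <- lm(fx$y ~ fx$X[, 1])
  expect_equal(unname(predict(m, fx$X)), unname(fitted(ols)),
               tolerance = 1e-10)
})

test_that("full-rank PLS reproduces multiple least squares", {
  withr::with_seed(9, {
    X <- matrix(rnorm(18), 6, 3)
    y <- rnorm(6)
  })
  m <- fit_pls(X, y, 3)
  ols <- lm(y ~ X)
  expect_equal(unname(predict(m, X)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_pls(X, rep(1, 10), 1), "constant")
  expect_error(fit_pls(X, rnorm(10), 0), "out of bounds")
  expect_error(fit_pls(X, rnorm(10), 5), "out of bounds")
  expect_error(loo_validation(X, rnorm(10), 9), "n - 2")
})

test_that("prediction at the mean descriptor row is the mean activity", {
  fx <- rand_Xy(10, 6, seed = 21, noise = 0.5)
  for (nc in c(1, 3)) {
    m <- fit_pls(fx$X, fx$y, nc)
    expect_equal(unname(predict(m, matrix(colMeans(fx$X), 1))),
                 mean(fx$y), tolerance = 1e-10)
  }
})

test_that("LOO equals the explicit n-refit loop", {
  for (seed in c(1, 2, 3)) {
    fx <- rand_Xy(12, 30, seed = seed, noise = 0.4)
    for (nc in c(1, 3)) {
      got <- loo_validation(fx$X, fx$y, nc)
      want <- loo_brute_force(fx$X, fx$y, nc)
      expect_equal(got$q2, want$q2, tolerance = 1e-10)
      expect_equal(got$sep, want$sep, tolerance = 1e-10)
      expect_equal(got$press, want$press, tolerance = 1e-10)
    }
  }
})

test_that("LOO q2 hits the perfect-signal and pure-noise limits", {
  # noiseless y in the column space of a full-rank X: LOO refits at full
  # rank coincide with exact least squares in every fold
  fx <- rand_Xy(14, 6, seed = 8, noise = 0)
  expect_gte(loo_validation(fx$X, fx$y, 6)$q2, 0.999)
  # noise X independent of y: no internal predictivity
  withr::with_seed(31, {
    X <- matrix(rnorm(14 * 40), 14, 40)
    y <- rnorm(14)
  })
  expect_lte(loo_validation(X, y, 2)$q2, 0.2)
})

test_that("component selection recovers planted latent dimensionality", {
  withr::with_seed(17, {
    T2 <- matrix(rnorm(40), 20, 2)
    P <- matrix(rnorm(2 * 25), 2, 25)
    X <- T2 %*% P
    y <- drop(T2 %*% c(2, -1.5))
  })
  sel <- select_components(X, y, max_components = 5)
  expect_equal(sel$n_components, 2L)
  # counts whose q2 ties within the tolerance resolve to the smaller one
  sel_loose <- select_components(X, y, max_components = 5, tie_tol = 2)
  expect_equal(sel_loose$n_components, 1L)
  # strictly decreasing q2 from the first component -> one component
  fx <- rand_Xy(15, 1, seed = 4, noise = 0.2)
  sel1 <- select_components(cbind(fx$X, fx$X * 2), fx$y, max_components = 4)
  expect_equal(sel1$n_components, 1L)
})

test_that("q2 is invariant to column rescaling when autoscaling", {
  fx <- rand_Xy(12, 8, seed = 13, noise = 0.3)
  X2 <- fx$X
  X2[, 3] <- X2[, 3] * 250
  X2[, 5] <- X2[, 5] * 1e-4
  a <- loo_validation(fx$X, fx$y, 2, autoscale = TRUE)
  b <- loo_validation(X2, fx$y, 2, autoscale = TRUE)
  expect_equal(a$q2, b$q2, tolerance = 1e-10)
})

test_that("non-cross-validated statistics follow the classical formulas", {
  expect_equal(fstat_from_r2(0.5, 22, 1), 20, tolerance = 1e-12)
  expect_identical(fstat_from_r2(1, 24, 3), Inf)
  fx <- rand_Xy(15, 6, seed = 19, noise = 0.4)
  m <- fit_pls(fx$X, fx$y, 2)
  st <- final_stats(m, fx$X, fx$y)
  rss <- sum((fx$y - predict(m, fx$X))^2)
  expect_equal(st$r2_ncv, 1 - rss / sum((fx$y - mean(fx$y))^2))
  expect_equal(st$see, sqrt(rss / (15 - 2 - 1)))
  expect_lte(st$r2_ncv, 1)
  expect_lte(loo_validation(fx$X, fx$y, 2)$q2, 1)
})

test_that("predictive r2 implements (SD - PRESS) / SD", {
  y <- c(1, 2, 3)
  expect_equal(predictive_r2(y, y, 1.5)$r2_pred, 1)
  expect_equal(predictive_r2(rep(1.5, 3), y, 1.5)$r2_pred, 0)
  # direct arithmetic: SD = 10, PRESS = 2 -> 0.8
  got <- predictive_r2(c(0, 4), c(1, 3), y_train_mean = 0)
  expect_equal(got$sd, 10)
  expect_equal(got$press, 2)
  expect_equal(got$r2_pred, 0.8)
  expect_error(predictive_r2(c(1, 2), c(2, 2), 2), "SD is zero")
})

test_that("bootstrap validation is seed-reproducible with sane limits", {
  # two latent factors drive X and y exactly: a 2-component refit of any
  # resample is a perfect fit
  withr::with_seed(23, {
    T2 <- matrix(rnorm(28), 14, 2)
    X <- T2 %*% matrix(rnorm(16), 2, 8)
    y <- drop(T2 %*% c(1.5, -1))
  })
  fx <- list(X = X, y = y)
  b1 <- bootstrap_validate(fx$X, fx$y, 2, runs = 25, seed = 11)
  b2 <- bootstrap_validate(fx$X, fx$y, 2, runs = 25, seed = 11)
  expect_identical(b1, b2)
  # noiseless linear signal: near-perfect resample fits
  expect_gte(b1$r2_boot, 0.99)
  expect_lte(b1$sd_boot, 0.01)
  expect_error(bootstrap_validate(fx$X, fx$y, 2, runs = 1), "at least 2")
  # default runs follow the classical battery
  expect_equal(formals(bootstrap_validate)$runs, 100)
})

test_that("field contributions normalize |coef| x SD shares per kind", {
  fx <- rand_Xy(10, 6, seed = 29, noise = 0.2)
  m <- fit_pls(fx$X, fx$y, 2)
  idx1 <- data.frame(kind = rep("only", 6), column = 1:6)
  expect_equal(unname(field_contributions(m, idx1)), 1)
  idx2 <- data.frame(kind = rep(c("a", "b"), each = 3), column = 1:6)
  fc <- field_contributions(m, idx2)
  expect_equal(sum(fc), 1, tolerance = 1e-12)
  expect_error(field_contributions(m, idx2[0, ]), "empty")
  # duplicated blocks split the contribution evenly by symmetry
  Xd <- cbind(fx$X, fx$X)
  md <- fit_pls(Xd, fx$y, 2)
  idxd <- data.frame(kind = rep(c("a", "b"), each = 6), column = 1:12)
  fcd <- field_contributions(md, idxd)
  expect_equal(unname(fcd), c(0.5, 0.5), tolerance = 1e-6)
})
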