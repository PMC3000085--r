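# shared fixtures and independent oracles

# a bare molecule from an explicit coordinate matrix with hand-set weights
make_mol <- function(id, xyz, charge = 0, radius = 1.5, hydrophobicity = 0,
                     hbd = FALSE, hba = FALSE, epsilon = 0.107,
                     activity = NA_real_, role = "train") {
  n <- nrow(xyz)
  qsar_molecule(id, data.frame(
    element = rep("C", n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n), radius = rep_len(radius, n),
    epsilon = rep_len(epsilon, n),
    hydrophobicity = rep_len(hydrophobicity, n),
    hbd = rep_len(hbd, n), hba = rep_len(hba, n)),
    activity = activity, role = role)
}

# a lattice placed by hand (bypassing build_lattice) for point-level tests
make_lattice <- function(origin, spacing, dims) {
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims)),
            class = "grid_lattice")
}

# rotation matrices
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

apply_rigid <- function(mol, R, t) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, FUN = "+")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

# image of an axis-aligned lattice under a 90-degree z rotation + translation,
# plus the index permutation mapping old point order to new point order
rotate_lattice_z90 <- function(lat, t = c(0, 0, 0)) {
  nx <- lat$dims[1]; ny <- lat$dims[2]; nz <- lat$dims[3]; s <- lat$spacing
  o <- lat$origin
  new_origin <- c(-(o[2] + s * (ny - 1)), o[1], o[3]) + t
  new_lat <- make_lattice(new_origin, s, c(ny, nx, nz))
  # old point (i,j,k) -> new grid index (ny-1-j, i, k); both x-fastest
  old <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  perm <- (ny - 1 - old$j) + ny * old$i + (nx * ny) * old$k + 1
  list(lattice = new_lat, perm = perm)
}

# random PLS fixture with a planted linear signal
rand_Xy <- function(n, p, seed, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- numeric(p); beta[seq_len(min(3, p))] <- c(1.5, -1, 0.5)[seq_len(min(3, p))]
    y <- drop(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y)
  })
}

# brute-force LOO oracle: n explicit refits through the public API
loo_brute_force <- function(X, y, nc) {
  n <- nrow(X)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_pls(X[-i, , drop = FALSE], y[-i], nc)
    preds[i] <- predict(m, X[i, , drop = FALSE])
  }
  press <- sum((y - preds)^2)
  list(q2 = 1 - press / sum((y - mean(y))^2),
       sep = sqrt(press / (n - nc - 1)), press = press)
}

# noiseless fixture series shared between tests (generated once per run)
.fixture_env <- new.env()
noiseless_fixtures <- function() {
  if (is.null(.fixture_env$fx))
    .fixture_env$fx <- benchmark_fixtures(noise_sd = 0)
  .fixture_env$fx
}

# search on a series without bootstrap (the expensive part is not needed
# for recovery checks)
quick_search <- function(series, ...) {
  run_search(series$train, series$test, lattice = series$lattice,
             sconfig = search_config(bootstrap_runs = 0), ...)
}

planted_cosine <- function(series, search) {
  planted_recovery_stats(series, search)$cosine
}

# drop flagged outliers and re-run the search (the classical
# report-then-exclude flow)
exclude_and_research <- function(series, search) {
  fl <- flag_outliers(search, series$train)
  keep <- !vapply(series$train, function(m) m$id %in% fl$id[fl$flagged],
                  logical(1))
  run_search(series$train[keep], series$test, lattice = series$lattice,
             sconfig = search_config(bootstrap_runs = 0))
}
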