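test_that("lattice encloses atoms with the requested margin", {
  mol <- make_mol("a", matrix(0, 1, 3))
  lat <- build_lattice(list(mol), spacing = 2, margin = 4)
  expect_equal(lat$origin, c(-4, -4, -4), ignore_attr = TRUE)
  expect_equal(lat$dims, c(5L, 5L, 5L))
  # translating every atom translates the origin, dims unchanged
  mol2 <- make_mol("b", matrix(c(10, 0, 0), 1, 3))
  lat2 <- build_lattice(list(mol2), spacing = 2, margin = 4)
  expect_equal(lat2$origin - lat$origin, c(10, 0, 0), ignore_attr = TRUE)
  expect_equal(lat2$dims, lat$dims)
  expect_error(build_lattice(list(mol), spacing = 0), "positive")
  expect_error(build_lattice(list(mol), margin = -1), "non-negative")
})

test_that("default lattice spacing is the classical 2 A", {
  expect_equal(formals(build_lattice)$spacing, 2.0)
  expect_equal(formals(field_config)$attenuation, 0.3)
  expect_equal(formals(field_config)$energy_cutoff, 30)
})

test_that("CoMFA fields follow the 6-12 and Coulomb forms with clamping", {
  probe <- comfa_probe()
  mol <- make_mol("a", matrix(0, 1, 3), charge = 0, radius = 1.6,
                  epsilon = 0.2)
  # single probe point at the pair equilibrium separation
  d_eq <- probe$vdw_radius + 1.6
  lat1 <- make_lattice(c(d_eq, 0, 0), 2, c(1, 1, 1))
  f <- comfa_fields(mol, lat1, probe)
  # independent scalar evaluation of the Lennard-Jones well
  eps_pair <- sqrt(probe$well_depth * 0.2)
  expect_equal(drop(f$comfa_steric$values), -eps_pair, tolerance = 1e-12)
  # zero charges -> electrostatic identically zero
  expect_equal(drop(f$comfa_electrostatic$values), 0)
  # a grid point inside the atom clamps to +cutoff exactly
  lat0 <- make_lattice(c(0.1, 0, 0), 2, c(1, 1, 1))
  f0 <- comfa_fields(mol, lat0, probe)
  expect_identical(drop(f0$comfa_steric$values), 30)
  # charged atom at tiny separation clamps electrostatics symmetrically
  molq <- make_mol("q", matrix(0, 1, 3), charge = -0.4)
  fq <- comfa_fields(molq, lat0, probe)
  expect_identical(drop(fq$comfa_electrostatic$values), -30)
  # Coulomb with distance-dependent dielectric: 332.06 q1 q2 / r^2
  latr <- make_lattice(c(4, 0, 0), 2, c(1, 1, 1))
  fr <- comfa_fields(molq, latr, probe)
  expect_equal(drop(fr$comfa_electrostatic$values),
               332.06 * 1.0 * (-0.4) / 16, tolerance = 1e-12)
})

test_that("no CoMFA value escapes the cutoff on a dense random grid", {
  withr::with_seed(42, {
    xyz <- matrix(rnorm(30, sd = 2), 10, 3)
    mol <- make_mol("r", xyz, charge = runif(10, -0.5, 0.5),
                    radius = runif(10, 1.2, 1.9))
  })
  lat <- build_lattice(list(mol), spacing = 1.0, margin = 2)
  f <- comfa_fields(mol, lat, comfa_probe())
  for (b in f) {
    expect_true(all(is.finite(b$values)))
    expect_true(all(abs(b$values) <= 30))
  }
})

test_that("CoMSIA similarity indices match the Gaussian closed form", {
  cfg <- field_config()
  probe <- comsia_probe()
  # unit weights: charge 1 atom, probe charge 1
  mol <- make_mol("a", matrix(0, 1, 3), charge = 1)
  lat0 <- make_lattice(c(0, 0, 0), 2, c(1, 1, 1))
  f0 <- comsia_fields(mol, lat0, probe, cfg, kinds = "comsia_E")
  expect_equal(drop(f0$comsia_E$values), -1, tolerance = 1e-12)
  lat2 <- make_lattice(c(2, 0, 0), 2, c(1, 1, 1))
  f2 <- comsia_fields(mol, lat2, probe, cfg, kinds = "comsia_E")
  expect_equal(drop(f2$comsia_E$values), -exp(-1.2), tolerance = 1e-12)
  # steric weight is radius^3 (times probe radius^3 = 1)
  molS <- make_mol("s", matrix(0, 1, 3), radius = 1.5)
  fS <- comsia_fields(molS, lat2, probe, cfg, kinds = "comsia_S")
  expect_equal(drop(fS$comsia_S$values), -1.5^3 * exp(-1.2),
               tolerance = 1e-12)
})

test_that("CoMSIA fields are additive over atoms and finite everywhere", {
  lat <- make_lattice(c(-2, -2, -2), 2, c(3, 3, 3))
  a1 <- make_mol("a1", matrix(c(0.3, 0, 0), 1, 3), charge = 0.8,
                 hydrophobicity = 0.5, hbd = TRUE, hba = TRUE)
  a2 <- make_mol("a2", matrix(c(-1, 0.5, 1), 1, 3), charge = -0.4,
                 hydrophobicity = -0.7, hbd = FALSE, hba = TRUE)
  both <- make_mol("b", rbind(coords(a1), coords(a2)),
                   charge = c(0.8, -0.4), hydrophobicity = c(0.5, -0.7),
                   hbd = c(TRUE, FALSE), hba = c(TRUE, TRUE))
  for (k in COMSIA_KINDS) {
    f1 <- comsia_fields(a1, lat, kinds = k)[[k]]$values
    f2 <- comsia_fields(a2, lat, kinds = k)[[k]]$values
    fb <- comsia_fields(both, lat, kinds = k)[[k]]$values
    expect_equal(fb, f1 + f2, tolerance = 1e-12)
    expect_true(all(is.finite(fb)))
  }
})

test_that("single-atom CoMSIA magnitude decays strictly with distance", {
  mol <- make_mol("a", matrix(0, 1, 3), charge = 1)
  r <- seq(0, 8, by = 0.5)
  vals <- vapply(r, function(d) {
    lat <- make_lattice(c(d, 0, 0), 1, c(1, 1, 1))
    drop(comsia_fields(mol, lat, kinds = "comsia_E")$comsia_E$values)
  }, numeric(1))
  expect_true(all(diff(abs(vals)) < 0))
})

test_that("doubling the attenuation factor never increases |A|", {
  # same-sign atomic weights: each Gaussian term shrinks with larger
  # attenuation, so the summed magnitude cannot grow
  withr::with_seed(7, {
    mol <- make_mol("a", matrix(rnorm(12), 4, 3), charge = runif(4, 0.1, 1))
  })
  lat <- build_lattice(list(mol), spacing = 2, margin = 4)
  a1 <- comsia_fields(mol, lat, config = field_config(attenuation = 0.3),
                      kinds = "comsia_E")$comsia_E$values
  a2 <- comsia_fields(mol, lat, config = field_config(attenuation = 0.6),
                      kinds = "comsia_E")$comsia_E$values
  expect_true(all(abs(a2) <= abs(a1) + 1e-12))
})

test_that("fields are invariant under a common rigid motion of molecules and lattice", {
  withr::with_seed(11, {
    mol <- make_mol("a", matrix(rnorm(9), 3, 3), charge = c(0.4, -0.2, 0.1),
                    radius = c(1.4, 1.7, 1.6))
  })
  lat <- build_lattice(list(mol), spacing = 2, margin = 4)
  shift <- c(3.2, -1.5, 0.7)
  rl <- rotate_lattice_z90(lat, shift)
  molr <- apply_rigid(mol, rot_z(pi / 2), shift)
  for (k in c("comsia_S", "comsia_E")) {
    f <- comsia_fields(mol, lat, kinds = k)[[k]]$values
    fr <- comsia_fields(molr, rl$lattice, kinds = k)[[k]]$values
    expect_equal(drop(fr)[rl$perm], drop(f), tolerance = 1e-8)
  }
  fc <- comfa_fields(mol, lat)
  fcr <- comfa_fields(molr, rl$lattice)
  for (k in names(fc))
    expect_equal(drop(fcr[[k]]$values)[rl$perm], drop(fc[[k]]$values),
                 tolerance = 1e-8)
})

test_that("descriptor assembly filters, scales and indexes blocks", {
  withr::with_seed(3, {
    V1 <- matrix(rnorm(40), 4, 10)
  })
  b_const <- list(k1 = structure(list(kind = "k1",
                                      values = matrix(1, 4, 5)),
                                 class = "field_block"))
  expect_error(assemble_descriptors(b_const, min_sigma = 0.5),
               "no descriptor columns")
  # two blocks, one scaled by 1000: block-standard scaling equalizes them
  blocks <- list(
    a = structure(list(kind = "a", values = V1), class = "field_block"),
    b = structure(list(kind = "b", values = V1 * 1000),
                  class = "field_block"))
  ds <- assemble_descriptors(blocks, scaling = "comfa_std", min_sigma = 0)
  Xa <- ds$X[, ds$index$kind == "a"]
  Xb <- ds$X[, ds$index$kind == "b"]
  expect_equal(sd(as.vector(Xa)), sd(as.vector(Xb)), tolerance = 1e-12)
  # no scaling, no filter: raw concatenation
  ds2 <- assemble_descriptors(blocks, scaling = "none", min_sigma = 0)
  expect_equal(ds2$X, cbind(V1, V1 * 1000), ignore_attr = TRUE)
  # the index maps every column back to its lattice point
  expect_equal(ds2$index$point, rep(1:10, 2))
  # projection reproduces the training matrix
  expect_equal(project_descriptors(ds, blocks), ds$X, ignore_attr = TRUE)
})
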