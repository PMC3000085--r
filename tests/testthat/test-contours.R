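# a small fitted model + descriptor set for contour tests
contour_fixture <- function(seed = 15) {
  ser <- generate_series(synthetic_spec(n_train = 10, n_test = 0,
                                        seed = seed, noise_sd = 0.1))
  y <- vapply(ser$train, function(m) m$activity, numeric(1))
  # the CoMFA block's minimum-sigma filter leaves absent grid points,
  # which the contour machinery must carry as NA
  fc <- field_config(field_kinds = c("comfa_steric", "comsia_E"))
  blocks <- compute_field_blocks(ser$train, ser$lattice, fc)
  ds <- assemble_descriptors(blocks)
  m <- fit_pls(ds$X, y, 2)
  list(model = m, dset = ds, lattice = ser$lattice)
}

test_that("StDev*Coeff grids are column SD times coefficient", {
  fx <- contour_fixture()
  g <- stdev_coeff_grid(fx$model, fx$dset, fx$lattice, "comfa_steric")
  rows <- fx$dset$index$kind == "comfa_steric"
  cols <- fx$dset$index$column[rows]
  pts <- fx$dset$index$point[rows]
  expect_equal(g$values[pts],
               fx$model$xsd[cols] * fx$model$coef[cols])
  # a zero coefficient yields a zero grid value
  m0 <- fx$model
  m0$coef[cols[1]] <- 0
  g0 <- stdev_coeff_grid(m0, fx$dset, fx$lattice, "comfa_steric")
  expect_identical(g0$values[pts[1]], 0)
  # filtered-out columns appear as absent, not zero
  expect_true(anyNA(g$values))
  expect_error(stdev_coeff_grid(fx$model, fx$dset, fx$lattice, "comsia_H"),
               "not in the descriptor index")
})

test_that("grids from duplicated blocks are identical across the two kinds", {
  withr::with_seed(33, V <- matrix(rnorm(60), 6, 10))
  blocks <- list(
    a = structure(list(kind = "a", values = V), class = "field_block"),
    b = structure(list(kind = "b", values = V), class = "field_block"))
  ds <- assemble_descriptors(blocks, min_sigma = 0)
  y <- V[, 1] - 0.5 * V[, 4]
  m <- fit_pls(ds$X, y, 2)
  lat <- make_lattice(c(0, 0, 0), 2, c(10, 1, 1))
  ga <- stdev_coeff_grid(m, ds, lat, "a")
  gb <- stdev_coeff_grid(m, ds, lat, "b")
  expect_equal(ga$values, gb$values, tolerance = 1e-10)
})

test_that("contribution levels are percentiles with linear interpolation", {
  lat <- make_lattice(c(0, 0, 0), 1, c(100, 1, 1))
  g <- structure(list(lattice = lat, kind = "comsia_S",
                      values = as.numeric(1:100)), class = "contour_grid")
  g <- levels_by_contribution(g, 80, 20)
  expect_equal(g$favored_level, 80.2)
  expect_equal(g$disfavored_level, 20.8)
  # degenerate distribution: both levels collapse to the common value
  gu <- structure(list(lattice = lat, kind = "comsia_S",
                       values = rep(2.5, 100)), class = "contour_grid")
  gu <- levels_by_contribution(gu, 95, 5)
  expect_equal(gu$favored_level, 2.5)
  expect_equal(gu$disfavored_level, 2.5)
  expect_error(levels_by_contribution(g, 20, 80), "favored_pct")
  ga <- structure(list(lattice = lat, kind = "comsia_S",
                       values = rep(NA_real_, 100)), class = "contour_grid")
  expect_error(levels_by_contribution(ga, 80, 20), "no present values")
})

test_that("raising the favored percentage never lowers the favored level", {
  withr::with_seed(6, vals <- rnorm(200))
  lat <- make_lattice(c(0, 0, 0), 1, c(200, 1, 1))
  g <- structure(list(lattice = lat, kind = "comsia_E", values = vals),
                 class = "contour_grid")
  for (mode in c("value_percentile", "abs_mass")) {
    lv <- vapply(c(50, 70, 80, 90, 95, 99), function(p)
      levels_by_contribution(g, p, 10, mode = mode)$favored_level,
      numeric(1))
    expect_true(all(diff(lv) >= -1e-12))
  }
})

test_that("DX export round-trips values, origin and dims through a text parse", {
  fx <- contour_fixture()
  g <- stdev_coeff_grid(fx$model, fx$dset, fx$lattice, "comfa_steric")
  g <- levels_by_contribution(g, 80, 20)
  tf <- withr::local_tempfile(fileext = ".dx")
  export_grid(g, tf, format = "dx")
  lines <- readLines(tf)
  dims <- fx$lattice$dims
  expect_equal(lines[1], sprintf(
    "object 1 class gridpositions counts %d %d %d", dims[1], dims[2], dims[3]))
  origin <- as.numeric(strsplit(lines[2], " +")[[1]][2:4])
  expect_equal(origin, unname(fx$lattice$origin), tolerance = 1e-6)
  delta1 <- as.numeric(strsplit(lines[3], " +")[[1]][2:4])
  expect_equal(delta1, c(fx$lattice$spacing, 0, 0), tolerance = 1e-6)
  first_data <- grep("data follows$", lines) + 1
  last_data <- grep("^attribute", lines)[1] - 1
  nums <- as.numeric(unlist(strsplit(trimws(lines[first_data:last_data]),
                                     " +")))
  expect_length(nums, prod(dims))
  # undo the z-fastest ordering and compare at 6 significant figures
  arr <- aperm(array(nums, dim = rev(dims)), c(3, 2, 1))
  want <- ifelse(is.na(g$values), 0, g$values)
  expect_equal(as.vector(arr), want, tolerance = 1e-6)
  # the sidecar records kind, levels and absent points
  side <- jsonlite::read_json(paste0(tf, ".json"), simplifyVector = TRUE)
  expect_equal(side$kind, "comfa_steric")
  expect_equal(side$favored_level, g$favored_level, tolerance = 1e-12)
  expect_equal(sort(side$absent_points), which(is.na(g$values)))
})

test_that("cube export writes Bohr-scaled headers and all values", {
  fx <- contour_fixture()
  g <- stdev_coeff_grid(fx$model, fx$dset, fx$lattice, "comsia_E")
  tf <- withr::local_tempfile(fileext = ".cube")
  export_grid(g, tf, format = "cube")
  lines <- readLines(tf)
  b <- 1.8897259886
  hdr <- as.numeric(strsplit(trimws(lines[3]), " +")[[1]])
  expect_equal(hdr[2:4], unname(fx$lattice$origin) * b, tolerance = 1e-5)
  nx <- as.numeric(strsplit(trimws(lines[4]), " +")[[1]])
  expect_equal(nx[1], fx$lattice$dims[1])
  expect_equal(nx[2], fx$lattice$spacing * b, tolerance = 1e-5)
  nums <- as.numeric(unlist(strsplit(trimws(lines[8:length(lines)]), " +")))
  expect_length(nums, prod(fx$lattice$dims))
  arr <- aperm(array(nums, dim = rev(fx$lattice$dims)), c(3, 2, 1))
  want <- ifelse(is.na(g$values), 0, g$values)
  expect_equal(as.vector(arr), want, tolerance = 1e-4)
})
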