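#' StDev*Coeff contour grid for one field kind
#'
#' The classical QSAR map: for every descriptor column of the requested
#' kind that survived the minimum-sigma filter, the grid value at its
#' lattice point is (column standard deviation over the training
#' molecules) x (PLS coefficient). Points whose column was dropped by the
#' filter are recorded as NA (absent), not zero.
#'
#' @param model A fitted `pls_model`.
#' @param dset The `descriptor_set` the model was fitted on.
#' @param lattice The `grid_lattice` the descriptors were computed on.
#' @param kind Field kind to map.
#' @return Object of class `contour_grid`: `lattice`, `kind`, `values`
#'   (length = number of lattice points, NA where absent), and NULL
#'   `favored_level` / `disfavored_level` until set.
#' @export
stdev_coeff_grid <- function(model, dset, lattice, kind) {
  rows <- dset$index$kind == kind
  if (!any(rows)) stop("kind '", kind, "' is not in the descriptor index")
  cols <- dset$index$column[rows]
  pts <- dset$index$point[rows]
  values <- rep(NA_real_, prod(lattice$dims))
  values[pts] <- model$xsd[cols] * model$coef[cols]
  structure(list(lattice = lattice, kind = kind, values = values,
                 favored_level = NULL, disfavored_level = NULL),
            class = "contour_grid")
}

# |value|-mass weighted quantile: smallest level v such that the cumulative
# share of sum(|values|) carried by points with value <= v reaches p.
.abs_mass_quantile <- function(values, p) {
  ord <- order(values)
  v <- values[ord]; w <- abs(v)
  if (sum(w) == 0) return(stats::quantile(values, p, names = FALSE))
  cw <- cumsum(w) / sum(w)
  v[which(cw >= p)[1]]
}

#' Favored/disfavored isolevels at stated contribution percentages
#'
#' The "N% level contribution" of the classical contour displays is
#' implemented, by default, as the N-th percentile of the StDev*Coeff
#' value distribution over the surviving grid points (linear interpolation
#' between order statistics): points above the favored level mark regions
#' where increasing the field raises predicted activity, points below the
#' disfavored level the opposite. An alternative `"abs_mass"` rule places
#' the levels at quantiles of the |value|-mass distribution, for users who
#' read "contribution" as share of total absolute StDev*Coeff.
#'
#' @param grid A `contour_grid`.
#' @param favored_pct,disfavored_pct Percentages with
#'   `0 < disfavored_pct < favored_pct < 100`. Classical displays use
#'   95/5, 85/15 or 80/20.
#' @param mode `"value_percentile"` (default) or `"abs_mass"`.
#' @return The grid with `favored_level` and `disfavored_level` set.
#' @export
levels_by_contribution <- function(grid, favored_pct = 80,
                                   disfavored_pct = 20,
                                   mode = c("value_percentile", "abs_mass")) {
  mode <- match.arg(mode)
  if (!(disfavored_pct > 0 && favored_pct < 100 &&
        disfavored_pct < favored_pct))
    stop("need 0 < disfavored_pct < favored_pct < 100")
  v <- grid$values[!is.na(grid$values)]
  if (!length(v)) stop("contour grid has no present values")
  if (mode == "value_percentile") {
    grid$favored_level <- stats::quantile(v, favored_pct / 100,
                                          names = FALSE, type = 7)
    grid$disfavored_level <- stats::quantile(v, disfavored_pct / 100,
                                             names = FALSE, type = 7)
  } else {
    grid$favored_level <- .abs_mass_quantile(v, favored_pct / 100)
    grid$disfavored_level <- .abs_mass_quantile(v, disfavored_pct / 100)
  }
  grid$level_rule <- mode
  grid
}

#' Export a contour grid as an OpenDX or Gaussian cube volume
#'
#' Writes a standard volumetric text file carrying the lattice origin,
#' spacing and dims plus the grid values (absent points written as 0), and
#' a JSON sidecar (`<path>.json`) recording the field kind, the isolevels
#' (when set), the level rule, and the indices of absent points so the
#' zeros are distinguishable from true values. OpenDX files are in
#' Angstrom; Gaussian cube files follow that format's Bohr convention.
#'
#' @param grid A `contour_grid`.
#' @param path Output file path.
#' @param format `"dx"` or `"cube"`.
#' @return `path`, invisibly.
#' @export
export_grid <- function(grid, path, format = c("dx", "cube")) {
  format <- match.arg(format)
  lat <- grid$lattice
  nx <- lat$dims[1]; ny <- lat$dims[2]; nz <- lat$dims[3]
  vals <- ifelse(is.na(grid$values), 0, grid$values)
  # package order: x fastest; both formats want z fastest
  arr <- array(vals, dim = c(nx, ny, nz))
  vz <- as.vector(aperm(arr, c(3, 2, 1)))
  num <- function(x) formatC(x, format = "g", digits = 7)
  if (format == "dx") {
    lines <- c(
      sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
      sprintf("origin %s %s %s", num(lat$origin[1]), num(lat$origin[2]),
              num(lat$origin[3])),
      sprintf("delta %s 0 0", num(lat$spacing)),
      sprintf("delta 0 %s 0", num(lat$spacing)),
      sprintf("delta 0 0 %s", num(lat$spacing)),
      sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
      sprintf("object 3 class array type double rank 0 items %d data follows",
              length(vz)))
    body <- tapply(num(vz), (seq_along(vz) - 1) %/% 3, paste, collapse = " ")
    lines <- c(lines, unname(body),
               'attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3')
  } else {
    b <- 1.8897259886   # Angstrom -> Bohr
    lines <- c("qsar3d StDev*Coeff contour grid",
               sprintf("field kind: %s", grid$kind),
               sprintf("%5d %11.6f %11.6f %11.6f", 1L,
                       lat$origin[1] * b, lat$origin[2] * b, lat$origin[3] * b),
               sprintf("%5d %11.6f %11.6f %11.6f", nx, lat$spacing * b, 0, 0),
               sprintf("%5d %11.6f %11.6f %11.6f", ny, 0, lat$spacing * b, 0),
               sprintf("%5d %11.6f %11.6f %11.6f", nz, 0, 0, lat$spacing * b),
               sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 6L, 0,
                       lat$origin[1] * b, lat$origin[2] * b, lat$origin[3] * b))
    body <- tapply(sprintf("%13.5e", vz), (seq_along(vz) - 1) %/% 6,
                   paste, collapse = " ")
    lines <- c(lines, unname(body))
  }
  tryCatch(writeLines(lines, path),
           error = function(e) stop("failed to write ", path, ": ",
                                    conditionMessage(e)))
  sidecar <- list(kind = grid$kind,
                  favored_level = grid$favored_level,
                  disfavored_level = grid$disfavored_level,
                  level_rule = if (is.null(grid$level_rule))
                    "value_percentile" else grid$level_rule,
                  origin = unname(lat$origin), spacing = lat$spacing,
                  dims = unname(lat$dims),
                  absent_points = which(is.na(grid$values)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
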