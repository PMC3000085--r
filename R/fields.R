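#' The seven supported field kinds
#'
#' Two CoMFA interaction-energy fields (Lennard-Jones steric, Coulomb
#' electrostatic with a distance-dependent dielectric) and the five CoMSIA
#' similarity-index fields (steric S, electrostatic E, hydrophobic H,
#' hydrogen-bond donor D, hydrogen-bond acceptor A).
#' @export
FIELD_KINDS <- c("comfa_steric", "comfa_electrostatic",
                 "comsia_S", "comsia_E", "comsia_H", "comsia_D", "comsia_A")

#' The five CoMSIA field kinds
#' @export
COMSIA_KINDS <- c("comsia_S", "comsia_E", "comsia_H", "comsia_D", "comsia_A")

#' Probe atom specification
#'
#' The classical defaults: CoMFA uses an sp3 carbon probe of vdW radius
#' 1.52 A and charge +1; CoMSIA a probe of radius 1.0 A, charge +1 and
#' hydrophobicity +1 (donor and acceptor probe weights are 1).
#'
#' @param vdw_radius Probe vdW radius, Angstrom.
#' @param charge Probe charge, elementary units.
#' @param hydrophobicity Probe hydrophobicity weight (CoMSIA).
#' @param well_depth Probe Lennard-Jones well depth, kcal/mol (CoMFA steric).
#' @return Object of class `probe_spec`.
#' @export
probe_spec <- function(vdw_radius = 1.52, charge = 1.0,
                       hydrophobicity = 1.0, well_depth = 0.107) {
  if (vdw_radius <= 0) stop("probe radius must be positive")
  structure(list(vdw_radius = vdw_radius, charge = charge,
                 hydrophobicity = hydrophobicity, well_depth = well_depth),
            class = "probe_spec")
}

#' Default CoMFA probe (sp3 carbon, 1.52 A, +1 e)
#' @export
comfa_probe <- function() probe_spec(1.52, 1.0, 1.0, 0.107)

#' Default CoMSIA probe (1.0 A, +1 e, hydrophobicity +1)
#' @export
comsia_probe <- function() probe_spec(1.0, 1.0, 1.0, 0.107)

#' Field computation settings
#'
#' @param attenuation CoMSIA Gaussian attenuation factor alpha (default 0.3).
#' @param energy_cutoff CoMFA truncation, kcal/mol (default 30).
#' @param field_kinds Which fields to compute.
#' @param dielectric_mode `"distance"` for the distance-dependent dielectric
#'   eps(r) = r (energy ~ 1/r^2) or `"constant"` (energy ~ 1/r).
#' @return Object of class `field_config`.
#' @export
field_config <- function(attenuation = 0.3, energy_cutoff = 30,
                         field_kinds = FIELD_KINDS,
                         dielectric_mode = c("distance", "constant")) {
  if (attenuation <= 0) stop("attenuation must be positive")
  if (energy_cutoff <= 0) stop("energy cutoff must be positive")
  field_kinds <- match.arg(field_kinds, FIELD_KINDS, several.ok = TRUE)
  structure(list(attenuation = attenuation, energy_cutoff = energy_cutoff,
                 field_kinds = field_kinds,
                 dielectric_mode = match.arg(dielectric_mode)),
            class = "field_config")
}

#' Build the cubic probe lattice around an aligned series
#'
#' The minimal axis-aligned regular lattice with the given spacing whose
#' bounding box extends at least `margin` beyond the union of all atomic
#' positions. Deterministic for fixed input; translating every atom
#' translates the lattice origin by the same vector.
#'
#' @param molecules List of aligned `qsar_molecule`.
#' @param spacing Grid spacing, Angstrom (default 2.0, the classical value).
#' @param margin Extension beyond the atoms, Angstrom (default 4.0).
#' @return Object of class `grid_lattice` with `origin`, `spacing`, `dims`.
#' @export
build_lattice <- function(molecules, spacing = 2.0, margin = 4.0) {
  if (spacing <= 0) stop("spacing must be positive")
  if (margin < 0) stop("margin must be non-negative")
  if (length(molecules) < 1L) stop("need at least one molecule")
  xyz <- do.call(rbind, lapply(molecules, coords))
  if (nrow(xyz) < 1L) stop("need at least one atom")
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "grid_lattice")
}

#' Lattice point coordinates
#'
#' Enumerates the regular lattice as `origin + spacing * (i, j, k)` with the
#' x index varying fastest; this ordering is the package-wide convention
#' that descriptor columns and contour grids share.
#'
#' @param lattice A `grid_lattice`.
#' @return m x 3 matrix of coordinates (Angstrom).
#' @export
lattice_points <- function(lattice) {
  g <- expand.grid(x = seq_len(lattice$dims[1]) - 1L,
                   y = seq_len(lattice$dims[2]) - 1L,
                   z = seq_len(lattice$dims[3]) - 1L)
  sweep(as.matrix(g) * lattice$spacing, 2, lattice$origin, FUN = "+")
}

#' @export
print.grid_lattice <- function(x, ...) {
  cat(sprintf("<grid_lattice> %dx%dx%d, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

.field_block <- function(kind, values) {
  structure(list(kind = kind, values = values), class = "field_block")
}

# squared distances from each atom (rows of xyz) to each lattice point:
# atoms x points matrix
.dist2_matrix <- function(xyz, pts) {
  outer(rowSums(xyz^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(xyz)), rowSums(pts^2)) - 2 * xyz %*% t(pts)
}

#' CoMFA interaction fields for one molecule
#'
#' Steric: summed Lennard-Jones 6-12 probe-atom energies,
#' `eps_pair * ((R/r)^12 - 2 (R/r)^6)` with `R` the sum of probe and atom
#' vdW radii and `eps_pair` their geometric-mean well depth
#' (Lorentz-Berthelot). Electrostatic: summed Coulomb energies
#' `332.06 q_i q_probe / r^2` under the distance-dependent dielectric
#' eps(r) = r (or `/r` under a constant dielectric). Both are truncated
#' symmetrically at the configured cutoff (default +-30 kcal/mol), which
#' also tames the singularities at atom positions.
#'
#' @param mol A `qsar_molecule` whose atoms carry radii and charges.
#' @param lattice A `grid_lattice`.
#' @param probe A `probe_spec` (default [comfa_probe()]).
#' @param config A `field_config`.
#' @return List of two `field_block`s (`comfa_steric`,
#'   `comfa_electrostatic`), each a 1 x n-points value matrix in kcal/mol.
#' @export
comfa_fields <- function(mol, lattice, probe = comfa_probe(),
                         config = field_config()) {
  if (probe$vdw_radius <= 0) stop("probe radius must be positive")
  pts <- lattice_points(lattice)
  xyz <- coords(mol)
  d2 <- .dist2_matrix(xyz, pts)
  d2[d2 < 1e-12] <- 1e-12
  r <- sqrt(d2)
  Rpair <- probe$vdw_radius + mol$atoms$radius          # per atom
  eps_pair <- sqrt(probe$well_depth * mol$atoms$epsilon)
  sr6 <- (Rpair / r)^6                                  # recycles by column?
  # (Rpair/r): Rpair is length n_atoms, r is n_atoms x n_pts -> recycle OK
  steric <- colSums(eps_pair * (sr6^2 - 2 * sr6))
  elec_num <- 332.06 * probe$charge * mol$atoms$charge
  elec <- if (config$dielectric_mode == "distance")
    colSums(elec_num / d2) else colSums(elec_num / r)
  cl <- config$energy_cutoff
  clamp <- function(v) pmin(pmax(v, -cl), cl)
  list(comfa_steric = .field_block("comfa_steric",
                                   matrix(clamp(steric), nrow = 1)),
       comfa_electrostatic = .field_block("comfa_electrostatic",
                                          matrix(clamp(elec), nrow = 1)))
}

# per-atom weights omega_ik for a CoMSIA kind
.comsia_weights <- function(mol, kind) {
  switch(kind,
         comsia_S = mol$atoms$radius^3,
         comsia_E = mol$atoms$charge,
         comsia_H = mol$atoms$hydrophobicity,
         comsia_D = as.numeric(mol$atoms$hbd),
         comsia_A = as.numeric(mol$atoms$hba),
         stop("unknown CoMSIA kind: ", kind))
}

.comsia_probe_weight <- function(probe, kind) {
  switch(kind,
         comsia_S = probe$vdw_radius^3,
         comsia_E = probe$charge,
         comsia_H = probe$hydrophobicity,
         comsia_D = 1.0,
         comsia_A = 1.0)
}

#' CoMSIA similarity-index fields for one molecule
#'
#' At each lattice point q the similarity index for property k is
#' `A_k(q) = - sum_i w_probe,k w_ik exp(-alpha r_iq^2)` — a Gaussian
#' distance dependence with attenuation factor alpha (default 0.3), finite
#' everywhere including at atom positions, with the conventional leading
#' minus sign. Atomic property weights: steric = radius^3, electrostatic =
#' partial charge, hydrophobic = atomic hydrophobicity, donor/acceptor =
#' 0/1 flags.
#'
#' @param mol A `qsar_molecule`.
#' @param lattice A `grid_lattice`.
#' @param probe A `probe_spec` (default [comsia_probe()]).
#' @param config A `field_config` (supplies alpha).
#' @param kinds Which CoMSIA kinds to compute.
#' @return Named list of `field_block`s (1 x n-points, unitless).
#' @export
comsia_fields <- function(mol, lattice, probe = comsia_probe(),
                          config = field_config(), kinds = COMSIA_KINDS) {
  kinds <- match.arg(kinds, COMSIA_KINDS, several.ok = TRUE)
  pts <- lattice_points(lattice)
  d2 <- .dist2_matrix(coords(mol), pts)
  d2[d2 < 0] <- 0
  G <- exp(-config$attenuation * d2)                     # atoms x points
  out <- list()
  for (k in kinds) {
    w <- .comsia_weights(mol, k)
    if (any(is.na(w))) stop("atoms lack weights for kind ", k)
    A <- -.comsia_probe_weight(probe, k) * drop(crossprod(G, w))
    out[[k]] <- .field_block(k, matrix(A, nrow = 1))
  }
  out
}

#' Compute field blocks for a whole series
#'
#' Runs [comfa_fields()] and/or [comsia_fields()] for every molecule and
#' stacks the rows into molecules x points blocks, one per requested kind.
#'
#' @param molecules List of aligned `qsar_molecule`.
#' @param lattice A `grid_lattice`.
#' @param config A `field_config` (its `field_kinds` selects the blocks).
#' @param comfa_probe,comsia_probe Probe specs.
#' @return Named list of `field_block`s.
#' @export
compute_field_blocks <- function(molecules, lattice, config = field_config(),
                                 comfa_probe = qsar3d::comfa_probe(),
                                 comsia_probe = qsar3d::comsia_probe()) {
  kinds <- config$field_kinds
  comfa_kinds <- intersect(kinds, c("comfa_steric", "comfa_electrostatic"))
  comsia_kinds <- intersect(kinds, COMSIA_KINDS)
  npts <- prod(lattice$dims)
  blocks <- lapply(kinds, function(k)
    matrix(NA_real_, length(molecules), npts))
  names(blocks) <- kinds
  for (i in seq_along(molecules)) {
    if (length(comfa_kinds)) {
      cf <- comfa_fields(molecules[[i]], lattice, comfa_probe, config)
      for (k in comfa_kinds) blocks[[k]][i, ] <- cf[[k]]$values
    }
    if (length(comsia_kinds)) {
      cs <- comsia_fields(molecules[[i]], lattice, comsia_probe, config,
                          kinds = comsia_kinds)
      for (k in comsia_kinds) blocks[[k]][i, ] <- cs[[k]]$values
    }
  }
  lapply(kinds, function(k) .field_block(k, blocks[[k]])) |>
    stats::setNames(kinds)
}
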