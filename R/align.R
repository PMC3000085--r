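#' Alignment specification for a congeneric series
#'
#' Rigid substructure-based alignment needs, per molecule, a map from its
#' atoms to atoms of the chosen template (the most potent compound of the
#' series, in classical practice). Each map must contain at least three
#' non-collinear pairs or the rotation is under-determined.
#'
#' @param template_id Id of the template molecule.
#' @param atom_maps Named list (names = molecule ids); each element a
#'   two-column integer matrix `(molecule atom index, template atom index)`.
#' @return Object of class `alignment_spec`.
#' @export
alignment_spec <- function(template_id, atom_maps) {
  stopifnot(is.character(template_id), is.list(atom_maps))
  for (nm in names(atom_maps)) {
    m <- atom_maps[[nm]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 3L)
      stop("atom map for '", nm, "' must be a >=3-row, 2-column matrix")
  }
  structure(list(template_id = template_id, atom_maps = atom_maps),
            class = "alignment_spec")
}

#' Derive an alignment spec from a shared substructure
#'
#' Convenience for series whose first `n_common` atoms are the scaffold in
#' identical order (true of this package's synthetic series and common for
#' hand-curated congeneric sets): maps atoms 1..n_common of every molecule
#' onto the same atoms of the template.
#'
#' @param molecules List of `qsar_molecule`.
#' @param template_id Template molecule id.
#' @param n_common Number of leading scaffold atoms shared by all molecules.
#' @return An `alignment_spec`.
#' @export
common_prefix_spec <- function(molecules, template_id, n_common) {
  ids <- vapply(molecules, function(m) m$id, character(1))
  maps <- lapply(ids, function(id) cbind(seq_len(n_common), seq_len(n_common)))
  names(maps) <- ids
  alignment_spec(template_id, maps)
}

# Kabsch: least-squares rotation + translation taking P onto Q (n x 3 each).
# Returns list(R, t) with x_new = x %*% t(R) + t, and the fit rmsd.
.kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  sv <- svd(crossprod(Pc, Qc))          # H = Pc' Qc = U D V'
  if (sv$d[2] < 1e-8)
    stop("mapped atoms are collinear; rotation is under-determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - drop(R %*% pc)
  rmsd <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Rigidly align a series onto its template
#'
#' Least-squares (Kabsch) superposition of every molecule's mapped atoms
#' onto the corresponding template atoms: rotation plus translation only,
#' no internal flexibility. The template itself is left untouched. The
#' reported RMSD is over mapped atoms only.
#'
#' @param molecules List of `qsar_molecule`.
#' @param spec An [alignment_spec()] covering every molecule.
#' @return List with `molecules` (aligned) and `rmsd` (named numeric,
#'   Angstrom).
#' @export
align_to_template <- function(molecules, spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  ids <- vapply(molecules, function(m) m$id, character(1))
  ti <- match(spec$template_id, ids)
  if (is.na(ti)) stop("template '", spec$template_id, "' not in the series")
  tmpl_xyz <- coords(molecules[[ti]])
  rmsd <- numeric(length(molecules)); names(rmsd) <- ids
  out <- molecules
  for (i in seq_along(molecules)) {
    map <- spec$atom_maps[[ids[i]]]
    if (is.null(map)) stop("alignment spec lacks a map for '", ids[i], "'")
    if (nrow(map) < 3L) stop("fewer than 3 mapped pairs for '", ids[i], "'")
    xyz <- coords(molecules[[i]])
    fit <- .kabsch(xyz[map[, 1], , drop = FALSE],
                   tmpl_xyz[map[, 2], , drop = FALSE])
    new_xyz <- sweep(sweep(xyz, 2, colMeans(xyz[map[, 1], , drop = FALSE])) %*%
                       t(fit$R), 2, colMeans(tmpl_xyz[map[, 2], , drop = FALSE]),
                     FUN = "+")
    moved <- new_xyz[map[, 1], , drop = FALSE]
    rmsd[i] <- sqrt(mean(rowSums((moved - tmpl_xyz[map[, 2], , drop = FALSE])^2)))
    out[[i]] <- set_coords(molecules[[i]], new_xyz)
  }
  list(molecules = out, rmsd = rmsd)
}
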