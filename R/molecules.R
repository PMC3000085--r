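#' Default per-element atom parameter table
#'
#' Element-keyed physicochemical parameters used to annotate atoms when the
#' input file carries none: van der Waals radius (Angstrom, Bondi-style),
#' Lennard-Jones well depth (kcal/mol, Tripos-like magnitudes), an atomic
#' hydrophobicity contribution (unitless, crude Crippen-style element-level
#' values), a crude polarity-increment partial charge (elementary charge
#' units), and a hydrogen-bond acceptor flag. Every column is overridable:
#' pass a modified copy to [read_molecules()] or [annotate_atoms()], or
#' supply exact per-atom values through a MOL2 charge column, an SDF data
#' field, or a sidecar table. The bundled charges are deliberately simple
#' placeholders for workflows without a proper charge assignment upstream;
#' serious use should feed real charges (e.g. Gasteiger-type from any
#' external tool) through the override path.
#'
#' @return A data.frame with columns `element`, `radius`, `epsilon`,
#'   `hydrophobicity`, `charge`, `hba`.
#' @export
default_atom_params <- function() {
  data.frame(
    element        = c("H",  "C",  "N",  "O",  "F",  "P",  "S",  "Cl", "Br", "I"),
    radius         = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
    epsilon        = c(0.042, 0.107, 0.095, 0.116, 0.109, 0.314, 0.314, 0.240, 0.320, 0.424),
    hydrophobicity = c(0.12, 0.36, -0.60, -0.40, 0.22, -0.20, 0.25, 0.65, 0.85, 1.05),
    charge         = c(0.10, 0.00, -0.30, -0.35, -0.25, 0.00, -0.10, -0.15, -0.10, -0.05),
    hba            = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Construct an annotated molecule
#'
#' The package's central container: an id, an atom table with coordinates and
#' the five per-atom property weights the similarity fields need (steric via
#' the vdW radius, electrostatic via the partial charge, hydrophobic, and the
#' donor/acceptor flags), an optional activity on the -log10 scale (pKi or
#' pIC50), and a train/test role.
#'
#' @param id Molecule identifier (string).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge`, `radius`, `epsilon`, `hydrophobicity`, `hbd`,
#'   `hba`; missing property columns are filled from `params`.
#' @param activity Optional finite numeric activity (p-units).
#' @param role `"train"` or `"test"`.
#' @param params Parameter table in the shape of [default_atom_params()].
#' @return An object of class `qsar_molecule`.
#' @export
qsar_molecule <- function(id, atoms, activity = NA_real_, role = "train",
                          params = default_atom_params()) {
  stopifnot(is.character(id), length(id) == 1L, is.data.frame(atoms))
  if (nrow(atoms) < 1L) stop("molecule '", id, "' has no atoms")
  need <- c("element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("molecule '", id, "' has non-finite coordinates")
  atoms <- annotate_atoms(atoms, params = params)
  if (any(atoms$radius <= 0)) stop("vdW radii must be positive")
  if (!is.na(activity) && !is.finite(activity))
    stop("activity of molecule '", id, "' is not finite")
  role <- match.arg(role, c("train", "test"))
  structure(list(id = id, atoms = atoms, activity = as.numeric(activity),
                 role = role),
            class = "qsar_molecule")
}

#' Fill missing per-atom properties from a parameter table
#'
#' Columns already present in `atoms` are kept (NA entries are filled);
#' absent columns are looked up by element. Unknown elements fall back to
#' carbon-like values. Donor flags, when not supplied, stay FALSE: donor
#' perception needs connectivity (an N/O with attached H), which the readers
#' derive from bond blocks when available.
#'
#' @param atoms Atom data.frame (see [qsar_molecule()]).
#' @param params Parameter table, see [default_atom_params()].
#' @return The completed atom data.frame.
#' @export
annotate_atoms <- function(atoms, params = default_atom_params()) {
  idx <- match(atoms$element, params$element)
  fallback <- match("C", params$element)
  idx[is.na(idx)] <- fallback
  fill <- function(col, src) {
    if (is.null(atoms[[col]])) atoms[[col]] <<- src
    else {
      nas <- is.na(atoms[[col]])
      atoms[[col]][nas] <<- src[nas]
    }
  }
  fill("radius", params$radius[idx])
  fill("epsilon", params$epsilon[idx])
  fill("hydrophobicity", params$hydrophobicity[idx])
  fill("charge", params$charge[idx])
  fill("hba", params$hba[idx])
  fill("hbd", rep(FALSE, nrow(atoms)))
  atoms$hbd <- as.logical(atoms$hbd)
  atoms$hba <- as.logical(atoms$hba)
  atoms
}

#' @export
print.qsar_molecule <- function(x, ...) {
  cat(sprintf("<qsar_molecule> %s: %d atoms, activity %s, role %s\n",
              x$id, nrow(x$atoms),
              ifelse(is.na(x$activity), "NA", format(x$activity)), x$role))
  invisible(x)
}

#' Coordinates of a molecule as a matrix
#' @param mol A `qsar_molecule`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Convert a measured affinity to the -log10 activity scale
#'
#' Ki or IC50 values in micromolar become pKi = -log10(Ki) or
#' pIC50 = -log10(IC50), the dependent variable of the QSAR models.
#'
#' @param value Positive concentration in micromolar.
#' @param kind `"Ki"` or `"IC50"` (informational; both use -log10).
#' @return Numeric p-value (unitless).
#' @examples
#' convert_activity(1.0, "Ki")     # 0
#' convert_activity(0.018, "IC50") # 1.7447
#' @export
convert_activity <- function(value, kind = c("Ki", "IC50")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("activity values must be positive and finite to take -log10")
  -log10(value)
}

# A usable bond block has >= 3 columns and in-range finite atom indices
# (ChemmineR yields a degenerate 2-column block for zero-bond records).
.clean_bonds <- function(bb, natoms) {
  if (is.null(bb) || !is.matrix(bb) || ncol(bb) < 3L || nrow(bb) == 0L)
    return(NULL)
  b <- cbind(bb[, 1], bb[, 2])
  ok <- is.finite(b[, 1]) & is.finite(b[, 2]) &
    b[, 1] >= 1 & b[, 1] <= natoms & b[, 2] >= 1 & b[, 2] <= natoms
  if (!any(ok)) return(NULL)
  b[ok, , drop = FALSE]
}

# Perceive donor flags from a bond list: N/O bonded to at least one H.
.donor_flags <- function(elements, bonds) {
  hbd <- rep(FALSE, length(elements))
  if (is.null(bonds) || nrow(bonds) == 0L) return(hbd)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    if (elements[i] %in% c("N", "O") && elements[j] == "H") hbd[i] <- TRUE
    if (elements[j] %in% c("N", "O") && elements[i] == "H") hbd[j] <- TRUE
  }
  hbd
}

#' Read a congeneric series from SDF or MOL2
#'
#' SDF (V2000) files are parsed with ChemmineR; MOL2 with bio3d. Activities
#' are taken from the named SDF data field when present, or merged from a
#' sidecar table (columns `id`, `value`, `kind`, `role`, with `value` a
#' concentration in micromolar converted via [convert_activity()], or
#' columns `id`, `activity`, `role` with ready p-values). MOL2 partial
#' charges are used when the file carries them; all remaining per-atom
#' properties come from `params`. Donor flags are perceived from the bond
#' block (N/O bonded to H).
#'
#' @param path Input file.
#' @param format `"sdf"` or `"mol2"`.
#' @param activity_tag Name of the SDF data field holding the activity
#'   (already on the p scale), default `"pKi"`.
#' @param activities Optional sidecar data.frame as described above.
#' @param params Atom parameter table.
#' @return List of `qsar_molecule`.
#' @export
read_molecules <- function(path, format = c("sdf", "mol2"),
                           activity_tag = "pKi", activities = NULL,
                           params = default_atom_params()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  mols <- if (format == "sdf") {
    .read_sdf(path, activity_tag, params)
  } else {
    .read_mol2(path, params)
  }
  if (!is.null(activities)) mols <- .merge_activities(mols, activities)
  mols
}

.read_sdf <- function(path, activity_tag, params) {
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(list())
  # zero-bond molfiles are legitimate here; ChemmineR only warns about them
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e) stop("failed to parse SDF: ",
                                            conditionMessage(e)))
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || !is.matrix(ab) || nrow(ab) == 0L || ncol(ab) < 3L ||
        !all(grepl("_", rownames(ab), fixed = TRUE)))
      stop("unparsable or empty record at index ", k)
    elements <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = elements,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    bonds <- .clean_bonds(ChemmineR::bondblock(sdf), nrow(ab))
    atoms$hbd <- .donor_flags(elements, bonds)
    hdr <- ChemmineR::header(sdf)[["Molecule_Name"]]
    id <- if (!is.null(hdr) && nzchar(trimws(hdr))) trimws(hdr)
          else sprintf("mol_%03d", k)
    act <- NA_real_
    db <- ChemmineR::datablock(sdf)
    if (!is.null(db) && activity_tag %in% names(db)) {
      v <- suppressWarnings(as.numeric(db[[activity_tag]]))
      if (is.na(v)) stop("record ", k, " ('", id, "'): activity tag '",
                         activity_tag, "' is not numeric")
      act <- v
    }
    out[[k]] <- qsar_molecule(id, atoms, activity = act, params = params)
  }
  out
}

.read_mol2 <- function(path, params) {
  raw <- tryCatch(bio3d::read.mol2(path),
                  error = function(e) stop("failed to parse MOL2: ",
                                           conditionMessage(e)))
  if (inherits(raw, "mol2")) raw <- list(raw)
  lapply(seq_along(raw), function(k) {
    m <- raw[[k]]
    at <- m$atom
    if (is.null(at) || nrow(at) == 0L) stop("unparsable record at index ", k)
    elements <- sub("\\..*$", "", at$elety)
    atoms <- data.frame(element = elements, x = at$x, y = at$y, z = at$z,
                        stringsAsFactors = FALSE)
    if (!is.null(at$charge) && !all(is.na(at$charge)) &&
        any(at$charge != 0)) atoms$charge <- at$charge
    bonds <- if (!is.null(m$bond)) cbind(m$bond$origin, m$bond$target) else NULL
    atoms$hbd <- .donor_flags(elements, bonds)
    id <- if (!is.null(m$name) && nzchar(trimws(m$name))) trimws(m$name)
          else sprintf("mol_%03d", k)
    qsar_molecule(id, atoms, params = params)
  })
}

.merge_activities <- function(mols, activities) {
  stopifnot(is.data.frame(activities), "id" %in% names(activities))
  for (i in seq_along(mols)) {
    row <- match(mols[[i]]$id, activities$id)
    if (is.na(row)) next
    if ("activity" %in% names(activities)) {
      mols[[i]]$activity <- as.numeric(activities$activity[row])
    } else if (all(c("value", "kind") %in% names(activities))) {
      mols[[i]]$activity <- convert_activity(activities$value[row],
                                             activities$kind[row])
    }
    if ("role" %in% names(activities) && !is.na(activities$role[row]))
      mols[[i]]$role <- match.arg(activities$role[row], c("train", "test"))
  }
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' Ids go to the molfile title line; activities, when present, are written
#' as a data field named by `activity_tag` so a write/read round trip
#' preserves them. Coordinates are written at 4 decimals (the V2000 fixed
#' field width).
#'
#' @param mols List of `qsar_molecule`.
#' @param path Output file.
#' @param activity_tag SDF field name for the activity.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, activity_tag = "pKi") {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    n <- nrow(mol$atoms)
    lines <- c(mol$id, "  qsar3d", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L))
    for (i in seq_len(n)) {
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                mol$atoms$x[i], mol$atoms$y[i], mol$atoms$z[i],
                                mol$atoms$element[i]))
    }
    lines <- c(lines, "M  END")
    if (!is.na(mol$activity)) {
      lines <- c(lines, sprintf(">  <%s>", activity_tag),
                 format(mol$activity, digits = 12), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
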