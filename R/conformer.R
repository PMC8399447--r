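# Core data containers: atom tables, normal modes, conformers and ensembles.
#
# A conformer bundles one optimized geometry with its relative electronic
# energy, harmonic normal modes (frequency, Raman activity, per-atom
# displacements), per-atom natural electron densities, intramolecular
# hydrogen-bond records and a backbone index map.  Atom indices are 0-based
# everywhere; residues are numbered 1-based from the protonated amino
# (alpha-NH3+) terminus.

VALID_ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca"
)

#' Construct an atom table
#'
#' @param element character vector of chemical symbols.
#' @param x,y,z Cartesian coordinates in Angstroms.
#' @param density per-atom natural electron density (total natural population,
#'   in electrons); `NA` when no population analysis is available.
#' @return a `data.frame` with one row per atom; row `i` is atom index `i - 1`
#'   (0-based indexing).
#' @export
atom_table <- function(element, x, y, z, density = NA_real_) {
  n <- length(element)
  df <- data.frame(
    element = as.character(element),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    density = rep_len(as.numeric(density), n),
    stringsAsFactors = FALSE
  )
  validate_atom_table(df)
  df
}

validate_atom_table <- function(atoms) {
  if (!is.data.frame(atoms) ||
      !all(c("element", "x", "y", "z", "density") %in% names(atoms)))
    stop2("atoms: must be a data.frame with columns element, x, y, z, density")
  bad <- setdiff(unique(atoms$element), VALID_ELEMENTS)
  if (length(bad))
    stop2("atoms: invalid element symbol(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop2("atoms: non-finite coordinates")
  dens <- atoms$density[!is.na(atoms$density)]
  if (any(dens < 0))
    stop2("atoms: natural_electron_density must be >= 0")
  invisible(atoms)
}

# coordinates as an n x 3 matrix
coords <- function(conformer) {
  as.matrix(conformer$atoms[, c("x", "y", "z")])
}

#' Construct a normal-mode table
#'
#' @param frequency unscaled harmonic frequencies, cm-1.
#' @param raman_activity Raman scattering activities, A^4/amu.
#' @return `data.frame` with columns `index` (1-based mode number),
#'   `frequency`, `raman_activity`.
#' @export
mode_table <- function(frequency, raman_activity) {
  if (length(frequency) != length(raman_activity))
    stop2("modes: frequency and raman_activity lengths differ")
  if (length(frequency) && any(frequency <= 0))
    stop2("modes: retained frequencies must be > 0")
  if (length(frequency) && any(raman_activity < 0))
    stop2("modes: raman_activity must be >= 0")
  data.frame(
    index = seq_along(frequency),
    frequency = as.numeric(frequency),
    raman_activity = as.numeric(raman_activity)
  )
}

#' Construct a hydrogen-bond record table
#'
#' Donor, hydrogen and acceptor are 0-based atom indices; `delta_q` is the
#' magnitude of charge transferred through the bond, in electrons.
#'
#' @param donor,hydrogen,acceptor 0-based atom indices.
#' @param delta_q transferred-charge magnitudes, e- (`NA` when unset).
#' @return `data.frame` with one row per bond.
#' @export
hbond_table <- function(donor = integer(), hydrogen = integer(),
                        acceptor = integer(), delta_q = NA_real_) {
  n <- length(donor)
  data.frame(
    donor = as.integer(donor),
    hydrogen = as.integer(hydrogen),
    acceptor = as.integer(acceptor),
    delta_q = rep_len(as.numeric(delta_q), n)
  )
}

validate_hbond_table <- function(hb, n_atoms, atoms = NULL) {
  for (i in seq_len(nrow(hb))) {
    trip <- c(hb$donor[i], hb$hydrogen[i], hb$acceptor[i])
    if (anyDuplicated(trip))
      stop2("hbonds: donor/hydrogen/acceptor indices must be distinct (row ",
            i, ")")
    if (any(trip < 0L) || any(trip >= n_atoms))
      stop2("hbonds: atom index out of range (row ", i, ")")
    if (!is.null(atoms) && atoms$element[hb$hydrogen[i] + 1L] != "H")
      stop2("hbonds: hydrogen_atom is not an H atom (row ", i, ")")
  }
  if (any(hb$delta_q < 0, na.rm = TRUE))
    stop2("hbonds: delta_q must be >= 0")
  invisible(hb)
}

#' Construct a conformer
#'
#' @param id conformer label, e.g. `"EGEDEA-A"`.
#' @param sequence one-letter peptide sequence (alphabet A, D, E, G).
#' @param relative_energy relative electronic energy, kcal/mol (>= 0).
#' @param atoms an [atom_table()].
#' @param modes a [mode_table()] (may have zero rows).
#' @param displacements list of `n_atoms x 3` matrices, one per mode
#'   (dimensionless normalized Cartesian displacements).
#' @param hbonds an [hbond_table()].
#' @param backbone backbone index map: a list with `residues` (data.frame with
#'   columns `residue`, `N`, `CA`, `C`, `O`; 0-based atom indices, `O` is `NA`
#'   for the C-terminal residue whose carbonyls are the carboxylate) and
#'   terminal entries `nterm_N`, `cterm_C`, `cterm_O1`, `cterm_O2`.
#' @param protonated logical; `TRUE` when the isolated molecule has
#'   self-protonated (a carboxylate proton moved onto the terminal amine).
#' @return object of class `"conformer"`.
#' @export
conformer <- function(id, sequence, relative_energy, atoms,
                      modes = mode_table(numeric(), numeric()),
                      displacements = list(),
                      hbonds = hbond_table(),
                      backbone = NULL,
                      protonated = FALSE) {
  x <- structure(
    list(id = as.character(id), sequence = as.character(sequence),
         relative_energy = as.numeric(relative_energy),
         atoms = atoms, modes = modes, displacements = displacements,
         hbonds = hbonds, backbone = backbone,
         protonated = isTRUE(protonated)),
    class = "conformer"
  )
  validate_conformer(x)
  x
}

#' Validate a conformer's invariants
#'
#' Checks energies, atom/mode/displacement consistency, hydrogen-bond records
#' and the backbone map.  Called by all constructors and readers; errors name
#' the offending field.
#'
#' @param x a `"conformer"`.
#' @return `x`, invisibly.
#' @export
validate_conformer <- function(x) {
  if (!is_number(x$relative_energy) || x$relative_energy < 0)
    stop2("conformer ", x$id, ": relative_energy must be a finite number >= 0")
  validate_atom_table(x$atoms)
  n_atoms <- nrow(x$atoms)
  if (nrow(x$modes) != length(x$displacements))
    stop2("conformer ", x$id, ": displacements list length (",
          length(x$displacements), ") != number of modes (", nrow(x$modes), ")")
  for (k in seq_along(x$displacements)) {
    d <- x$displacements[[k]]
    if (!is.matrix(d) || nrow(d) != n_atoms || ncol(d) != 3L)
      stop2("conformer ", x$id, ": displacements[[", k,
            "]] must be an n_atoms x 3 matrix (atom count ", n_atoms, ")")
  }
  validate_hbond_table(x$hbonds, n_atoms, x$atoms)
  if (!is.null(x$backbone)) validate_backbone(x$backbone, x$sequence, n_atoms)
  invisible(x)
}

validate_backbone <- function(bb, sequence, n_atoms) {
  res <- bb$residues
  n_res <- nchar(sequence)
  if (!is.data.frame(res) || nrow(res) != n_res)
    stop2("backbone: residues table must have one row per residue (",
          n_res, ")")
  idx <- c(res$N, res$CA, res$C, res$O[!is.na(res$O)],
           bb$nterm_N, bb$cterm_C, bb$cterm_O1, bb$cterm_O2)
  if (any(idx < 0L) || any(idx >= n_atoms))
    stop2("backbone: atom index out of range")
  if (!is.na(res$O[n_res]))
    stop2("backbone: C-terminal residue O must be NA (carboxylate oxygens ",
          "are cterm_O1/cterm_O2)")
  invisible(bb)
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer>", x$id, " sequence:", x$sequence,
      " dE:", format(x$relative_energy), "kcal/mol\n")
  cat("  atoms:", nrow(x$atoms), " modes:", nrow(x$modes),
      " hbonds:", nrow(x$hbonds),
      if (x$protonated) " [protonated]" else "", "\n")
  invisible(x)
}

#' Construct a conformer ensemble
#'
#' Relative energies are re-referenced so the minimum is exactly 0 (an
#' idempotent shift).
#'
#' @param fragment fragment label, e.g. `"EGEDEA"`.
#' @param conformers list of [conformer()] objects with unique ids.
#' @param temperature equilibrium temperature, K (default 298, the standard
#'   room-temperature condition used throughout).
#' @return object of class `"ensemble"`.
#' @export
ensemble <- function(fragment, conformers, temperature = 298) {
  if (!length(conformers)) stop2("ensemble: needs >= 1 conformer")
  ids <- vapply(conformers, function(cf) cf$id, character(1))
  if (anyDuplicated(ids))
    stop2("ensemble: duplicate conformer id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is_number(temperature) || temperature <= 0)
    stop2("ensemble: temperature must be > 0")
  x <- structure(
    list(fragment = as.character(fragment), conformers = conformers,
         temperature = as.numeric(temperature)),
    class = "ensemble"
  )
  rereference_energies(x)
}

#' Re-reference ensemble energies to a zero minimum
#'
#' Subtracts the minimum relative energy from every conformer so exactly the
#' lowest structure sits at 0 kcal/mol.  Idempotent.
#'
#' @param x an `"ensemble"`.
#' @return the ensemble with shifted energies.
#' @export
rereference_energies <- function(x) {
  e <- relative_energies(x)
  shift <- min(e)
  x$conformers <- lapply(x$conformers, function(cf) {
    cf$relative_energy <- cf$relative_energy - shift
    cf
  })
  x
}

#' Extract the relative-energy vector of an ensemble
#'
#' @param x an `"ensemble"` or `"weighted_ensemble"`.
#' @return numeric vector, kcal/mol, in conformer order.
#' @export
relative_energies <- function(x) {
  if (inherits(x, "weighted_ensemble")) x <- x$ensemble
  vapply(x$conformers, function(cf) cf$relative_energy, numeric(1))
}

#' Extract the conformer ids of an ensemble
#'
#' @param x an `"ensemble"` or `"weighted_ensemble"`.
#' @return character vector in conformer order.
#' @export
conformer_ids <- function(x) {
  if (inherits(x, "weighted_ensemble")) x <- x$ensemble
  vapply(x$conformers, function(cf) cf$id, character(1))
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble>", x$fragment, ":", length(x$conformers),
      "conformer(s) at", x$temperature, "K\n")
  cat("  dE (kcal/mol):",
      paste(format(relative_energies(x), digits = 4), collapse = ", "), "\n")
  invisible(x)
}
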