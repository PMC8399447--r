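# Reading and writing conformer ensembles.
#
# Interchange format: one JSON file per ensemble, schema tag "bzr-1".
# Coordinates are Angstroms, energies kcal/mol, frequencies unscaled cm-1,
# atom indices 0-based.  A minimal XYZ+CSV route covers bare coordinates, and
# a single quantum-chemistry text-log dialect (the one emitted by
# write_mock_log()) covers frequency/Raman-activity/natural-population
# blocks.

BZR_SCHEMA <- "bzr-1"

conformer_to_list <- function(cf) {
  out <- list(
    id = cf$id, sequence = cf$sequence,
    relative_energy = cf$relative_energy,
    protonated = cf$protonated,
    atoms = as.list(cf$atoms),
    modes = list(frequency = cf$modes$frequency,
                 raman_activity = cf$modes$raman_activity),
    displacements = lapply(cf$displacements, function(m) {
      dimnames(m) <- NULL
      m
    }),
    hbonds = as.list(cf$hbonds)
  )
  if (!is.null(cf$backbone)) {
    out$backbone <- list(
      residues = as.list(cf$backbone$residues),
      nterm_N = cf$backbone$nterm_N, cterm_C = cf$backbone$cterm_C,
      cterm_O1 = cf$backbone$cterm_O1, cterm_O2 = cf$backbone$cterm_O2
    )
  }
  out
}

need_field <- function(x, field, where) {
  if (is.null(x[[field]]))
    stop2("schema violation: missing field '", field, "' in ", where)
  x[[field]]
}

conformer_from_list <- function(l, where = "conformer") {
  id <- need_field(l, "id", where)
  where <- paste0("conformer '", id, "'")
  atoms_l <- need_field(l, "atoms", where)
  for (f in c("element", "x", "y", "z"))
    need_field(atoms_l, f, paste0(where, "$atoms"))
  atoms <- atom_table(atoms_l$element, atoms_l$x, atoms_l$y, atoms_l$z,
                      atoms_l$density %||% NA_real_)
  modes_l <- l$modes %||% list(frequency = numeric(),
                               raman_activity = numeric())
  modes <- mode_table(modes_l$frequency %||% numeric(),
                      modes_l$raman_activity %||% numeric())
  disp_raw <- l$displacements %||% list()
  # jsonlite simplifies a list of same-shape matrices to a 3-d array
  disp <- if (is.array(disp_raw) && length(dim(disp_raw)) == 3)
    lapply(seq_len(dim(disp_raw)[1]), function(k) disp_raw[k, , ])
  else lapply(disp_raw, function(m) {
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  hb_l <- l$hbonds %||% list()
  hbonds <- if (length(hb_l$donor %||% integer()))
    hbond_table(hb_l$donor, hb_l$hydrogen, hb_l$acceptor,
                hb_l$delta_q %||% NA_real_)
  else hbond_table()
  bb <- NULL
  if (!is.null(l$backbone)) {
    r <- l$backbone$residues
    bb <- list(
      residues = data.frame(residue = as.integer(r$residue),
                            N = as.integer(r$N), CA = as.integer(r$CA),
                            C = as.integer(r$C), O = as.integer(r$O)),
      nterm_N = as.integer(l$backbone$nterm_N),
      cterm_C = as.integer(l$backbone$cterm_C),
      cterm_O1 = as.integer(l$backbone$cterm_O1),
      cterm_O2 = as.integer(l$backbone$cterm_O2)
    )
  }
  conformer(id = id,
            sequence = need_field(l, "sequence", where),
            relative_energy = need_field(l, "relative_energy", where),
            atoms = atoms, modes = modes, displacements = disp,
            hbonds = hbonds, backbone = bb,
            protonated = isTRUE(l$protonated))
}

#' Write an ensemble to the interchange JSON format
#'
#' @param x an `"ensemble"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_ensemble()]
#' @export
write_ensemble <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  payload <- list(
    schema = BZR_SCHEMA,
    fragment = x$fragment,
    temperature = x$temperature,
    conformers = lapply(x$conformers, conformer_to_list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a conformer ensemble
#'
#' Reads and validates an ensemble from the `"bzr-1"` interchange JSON (the
#' normal route, carrying energies, modes, densities and hydrogen bonds) or
#' from a directory of bare-coordinate XYZ files plus a `conformers.csv`
#' listing `id` and `relative_energy` (format `"xyz+csv"`).  Energies are
#' re-referenced so the minimum is 0.
#'
#' @param path file path (JSON) or directory (xyz+csv).
#' @param format `"interchange-json"` (default) or `"xyz+csv"`.
#' @return a validated `"ensemble"`.
#' @export
read_ensemble <- function(path, format = c("interchange-json", "xyz+csv")) {
  format <- match.arg(format)
  if (format == "xyz+csv") return(read_ensemble_xyzcsv(path))
  if (!file.exists(path)) stop2("read_ensemble: no such file: ", path)
  l <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  schema <- l$schema %||% "(absent)"
  if (!identical(schema, BZR_SCHEMA))
    stop2("schema violation: field 'schema' is '", schema,
          "', expected '", BZR_SCHEMA, "'")
  confs_l <- need_field(l, "conformers", "ensemble")
  if (!length(confs_l)) stop2("read_ensemble: empty ensemble")
  confs <- lapply(confs_l, conformer_from_list)
  ensemble(fragment = need_field(l, "fragment", "ensemble"),
           conformers = confs,
           temperature = l$temperature %||% 298)
}

read_ensemble_xyzcsv <- function(path) {
  csv <- file.path(path, "conformers.csv")
  if (!file.exists(csv))
    stop2("read_ensemble: missing ", csv)
  meta <- utils::read.csv(csv, stringsAsFactors = FALSE)
  for (f in c("id", "relative_energy"))
    if (is.null(meta[[f]]))
      stop2("schema violation: missing field '", f, "' in conformers.csv")
  confs <- lapply(seq_len(nrow(meta)), function(i) {
    atoms <- read_xyz(file.path(path, paste0(meta$id[i], ".xyz")))
    conformer(id = meta$id[i],
              sequence = meta$sequence[i] %||% "",
              relative_energy = meta$relative_energy[i],
              atoms = atoms)
  })
  ensemble(fragment = meta$fragment[1] %||% basename(path), conformers = confs)
}

#' Read bare coordinates from an XYZ file
#'
#' @param path XYZ file (atom count, comment, then `element x y z` lines).
#' @return an [atom_table()] (densities `NA`).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop2("read_xyz: no such file: ", path)
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop2("read_xyz: line 1 is not an atom count")
  if (length(lines) < n + 2) stop2("read_xyz: truncated file")
  fields <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  atom_table(
    element = vapply(fields, `[[`, character(1), 1),
    x = as.numeric(vapply(fields, `[[`, character(1), 2)),
    y = as.numeric(vapply(fields, `[[`, character(1), 3)),
    z = as.numeric(vapply(fields, `[[`, character(1), 4))
  )
}

#' Write bare coordinates to an XYZ file
#'
#' @param x a `"conformer"` or an [atom_table()].
#' @param path output file.
#' @param comment second-line comment string.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "") {
  atoms <- if (inherits(x, "conformer")) x$atoms else x
  lines <- c(
    as.character(nrow(atoms)),
    comment,
    sprintf("%-2s %18.10f %18.10f %18.10f",
            atoms$element, atoms$x, atoms$y, atoms$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a conformer as a minimal PDB file
#'
#' Backbone-aware single-model PDB writer for built or loaded peptides; atom
#' serials are 1-based, residue numbers follow the backbone map when present.
#'
#' @param x a `"conformer"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "conformer"))
  atoms <- x$atoms
  resid <- rep(1L, nrow(atoms))
  resname <- rep("UNK", nrow(atoms))
  if (!is.null(x$backbone)) {
    three <- c(A = "ALA", D = "ASP", E = "GLU", G = "GLY")
    seq1 <- strsplit(x$sequence, "")[[1]]
    res <- x$backbone$residues
    for (i in seq_len(nrow(res))) {
      lo <- res$N[i]
      hi <- if (i < nrow(res)) res$N[i + 1] - 1L else nrow(atoms) - 1L
      sel <- seq(lo, hi) + 1L
      resid[sel] <- i
      resname[sel] <- three[[seq1[i]]]
    }
  }
  rec <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), atoms$element, resname, resid,
    atoms$x, atoms$y, atoms$z, atoms$element
  )
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Parse the frequency block of a quantum-chemistry text log
#'
#' Parses the single supported log dialect (the one written by
#' [write_mock_log()]): a `Harmonic frequencies` block listing, per mode,
#' `Frequencies --`, `Raman Activ --` and per-atom displacement rows, plus an
#' optional `Natural Population Analysis` block carrying per-atom natural
#' electron densities.  IR-only jobs (no Raman activities) are rejected.
#'
#' @param path log file path.
#' @return list with `modes` (a [mode_table()]), `displacements` (list of
#'   matrices) and `atoms` (an [atom_table()]; densities `NA` when no
#'   population block is present).
#' @export
read_qc_frequency_block <- function(path) {
  if (!file.exists(path)) stop2("read_qc_frequency_block: no such file: ", path)
  lines <- readLines(path)
  start <- grep("^\\s*Harmonic frequencies", lines)
  if (!length(start))
    stop2("read_qc_frequency_block: no frequency block found in ", path)
  i <- 1L
  freq <- numeric(); act <- numeric(); disp <- list()
  atoms_el <- character(); atoms_xyz <- NULL; densities <- NULL
  num_after <- function(line, label, lineno) {
    if (!grepl(label, line))
      stop2("read_qc_frequency_block: truncated block at line ", lineno,
            " (expected '", label, "')")
    as.numeric(strsplit(sub(paste0(".*", label, "\\s*--\\s*"), "", line),
                        "\\s+")[[1]])
  }
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("^\\s*Mode\\s+\\d+", line)) {
      k <- length(freq) + 1L
      if (i + 1 > length(lines))
        stop2("read_qc_frequency_block: truncated block at line ", i + 1)
      if (grepl("IR Inten", lines[i + 1]) || !grepl("Frequencies",
                                                    lines[i + 1]))
        stop2("read_qc_frequency_block: truncated block at line ", i + 1,
              " (expected 'Frequencies')")
      freq[k] <- num_after(lines[i + 1], "Frequencies", i + 1)
      if (i + 2 > length(lines) || !grepl("Raman Activ", lines[i + 2]))
        stop2("read_qc_frequency_block: missing Raman activities ",
              "(IR-only jobs are unsupported), near line ", i + 2)
      act[k] <- num_after(lines[i + 2], "Raman Activ", i + 2)
      j <- i + 3L
      rows <- list()
      while (j <= length(lines) && grepl("^\\s*\\d+\\s+[A-Za-z]", lines[j])) {
        f <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        if (length(f) < 5)
          stop2("read_qc_frequency_block: truncated displacement row ",
                "at line ", j)
        rows[[length(rows) + 1L]] <- as.numeric(f[3:5])
        if (k == 1L) atoms_el <- c(atoms_el, f[2])
        j <- j + 1L
      }
      if (!length(rows))
        stop2("read_qc_frequency_block: truncated block at line ", j,
              " (no displacement rows for mode ", k, ")")
      disp[[k]] <- do.call(rbind, rows)
      i <- j
    } else if (grepl("Coordinates \\(Angstroms\\)", line)) {
      j <- i + 1L
      xyz <- list()
      while (j <= length(lines) && grepl("^\\s*\\d+\\s+[A-Za-z]", lines[j])) {
        f <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        xyz[[length(xyz) + 1L]] <- as.numeric(f[3:5])
        j <- j + 1L
      }
      atoms_xyz <- do.call(rbind, xyz)
      i <- j
    } else if (grepl("Natural Population Analysis", line)) {
      j <- i + 1L
      dens <- numeric()
      while (j <= length(lines) && grepl("^\\s*\\d+\\s+[A-Za-z]", lines[j])) {
        f <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        dens[length(dens) + 1L] <- as.numeric(f[3])
        j <- j + 1L
      }
      densities <- dens
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(freq))
    stop2("read_qc_frequency_block: no frequency block found in ", path)
  if (is.null(atoms_xyz)) atoms_xyz <- matrix(0, length(atoms_el), 3)
  atoms <- atom_table(atoms_el, atoms_xyz[, 1], atoms_xyz[, 2],
                      atoms_xyz[, 3], densities %||% NA_real_)
  list(modes = mode_table(freq, act), displacements = disp, atoms = atoms)
}

parse_printed <- function(s) as.numeric(s)

# unit in the last printed significant digit of strings like "9.74e-1", "1.00"
printed_ulp <- function(s) {
  mant <- sub("e.*$", "", s)
  ex <- ifelse(grepl("e", s), as.numeric(sub("^.*e", "", s)), 0)
  dec <- ifelse(grepl("\\.", mant),
                nchar(sub("^[^.]*\\.", "", mant)), 0)
  10^(ex - dec)
}

#' Load the per-conformer reference table
#'
#' Returns the packaged per-conformer reference data for the eleven peptide
#' fragments (EG ... EGEDEA): relative energies, Boltzmann populations,
#' hydrogen-bond counts and weighted magnitudes, Boltzmann-weighted total
#' charge transfer, and amide I / alpha-COO- band entries.  Band columns are
#' stored as printed -- an absolute position (cm-1) on each fragment's
#' lowest-energy A row and signed shifts relative to A elsewhere -- and are
#' resolved to absolute positions (`amide_I_position`, `acoo_position`) on
#' load.  Populations keep their printed strings (`n_i_printed`,
#' `qt_printed`) alongside numeric values so downstream checks know the
#' printed precision.
#'
#' The underlying study located 69 geometries but tabulates 6 per fragment
#' (66 rows); the three extra protonated geometries of EG, EGED and EGEDEA
#' are not tabulated and are recorded as absent in the `"missing_protonated"`
#' attribute rather than invented.
#'
#' @return `data.frame` of class `"table1_fixture"`, 66 rows.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "boltzbands",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(n_i = "character", qt = "character"))
  df$n_i_printed <- df$n_i
  df$qt_printed <- df$qt
  df$n_i <- parse_printed(df$n_i_printed)
  df$qt <- parse_printed(df$qt_printed)
  df$amide_I_position <- NA_real_
  df$acoo_position <- NA_real_
  for (f in unique(df$fragment)) {
    sel <- df$fragment == f
    a <- which(sel)[1]  # lowest-energy A row carries absolute positions
    df$amide_I_position[sel] <- c(df$amide_I[a],
                                  df$amide_I[a] + df$amide_I[sel][-1])
    df$acoo_position[sel] <- c(df$acoo[a], df$acoo[a] + df$acoo[sel][-1])
  }
  structure(df,
            class = c("table1_fixture", "data.frame"),
            missing_protonated = c("EG", "EGED", "EGEDEA"))
}

#' Load the ensemble-sum reference table
#'
#' Per-fragment Boltzmann sums: total hydrogen-bond charge transfer `q_bt`
#' (e-), amide I and alpha-COO- ensemble band positions (cm-1) and, where
#' measured, the experimental Raman band positions.
#'
#' @return `data.frame`, 11 rows.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2.csv", package = "boltzbands",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Filter an ensemble by a relative-energy window
#'
#' Keeps conformers with `relative_energy <= max_delta_e` (order preserved).
#' The default 50 kcal/mol window matches the range over which ensembles were
#' collected so the Boltzmann distribution is fully representative.
#'
#' @param x an `"ensemble"`.
#' @param max_delta_e window width, kcal/mol (> 0).
#' @return the filtered `"ensemble"`.
#' @export
filter_by_energy_window <- function(x, max_delta_e = 50) {
  stopifnot(inherits(x, "ensemble"))
  if (!is_number(max_delta_e) || max_delta_e <= 0)
    stop2("filter_by_energy_window: max_delta_e must be > 0")
  keep <- relative_energies(x) <= max_delta_e
  if (!any(keep))
    stop2("filter_by_energy_window: window ", max_delta_e,
          " kcal/mol removes every conformer")
  x$conformers <- x$conformers[keep]
  x
}
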