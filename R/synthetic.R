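# Synthetic conformer-ensemble generator.
#
# Builds mock ensembles with the statistical and structural features the
# analysis pipeline assumes -- relative-energy spreads in the 0-50 kcal/mol
# window with a dominant minimum, C=O-localized normal modes in the
# 1600-1700 cm-1 amide window, zwitterionic or self-protonated termini,
# 2-7 planned intramolecular hydrogen bonds with delta_q up to ~0.4 e-, and
# constructed backbone phi/psi geometry -- so every pipeline stage is
# testable without electronic-structure software.  Geometries are
# constructed from ideal internal coordinates, not optimized; side chains
# are reduced to a C-beta stub (except glycine) because no analysis stage
# reads further side-chain atoms.

BOND_LENGTHS <- c(
  N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
  C_OXT = 1.251, CA_CB = 1.530, N_H = 1.010, O_H = 0.980
)
BOND_ANGLES <- c(
  N_CA_C = 111.0, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.5,
  CA_C_OXT = 117.0, N_CA_CB = 110.5, C_N_H = 119.0, CA_N_H = 109.5,
  C_O_H = 106.0
)

#' Specification for a synthetic conformer ensemble
#'
#' @param sequence one-letter peptide string over A, D, E, G.
#' @param n_conformers number of conformers (>= 1).
#' @param seed integer seed; every random draw is reproducible from it and
#'   no global RNG state leaks.
#' @param phi_psi_targets optional list (one element per conformer) of
#'   `data.frame(phi, psi)` backbone targets in degrees; by default each
#'   conformer draws uniform dihedrals.
#' @param energy_spread scale (kcal/mol) of the exponential relative-energy
#'   draw, truncated at 50 kcal/mol; default 2, the dominant-minimum regime
#'   in which the lowest conformer typically carries > 0.9 of the
#'   population.
#' @param relative_energies optional explicit energies overriding the draw.
#' @param mode_plan optional list (per conformer) of data.frames with
#'   columns `target` (`"amide_I"`, `"alphaCOO"` or `"other"`), `frequency`
#'   (raw cm-1), `activity` (A^4/amu) and `localization` (fraction in
#'   (0, 1]); by default one 0.9-localized amide mode drawn from
#'   U(1650, 1750) raw cm-1, one carboxylate mode from U(1650, 1700) and
#'   five delocalized background modes outside the 1550-1750 window.
#' @param hbond_plan optional list (per conformer) of data.frames with
#'   columns `donor_role`, `acceptor_role` and `delta_q` (e-, in
#'   [0, 0.5]); roles name terminal/backbone atoms (see Details).  By
#'   default 2-7 bonds per conformer: one strong amino-terminus bond with
#'   delta_q ~ U(0.2, 0.4) plus weaker ones ~ U(0.001, 0.1).
#' @param zwitterionic build charged termini (default `TRUE`); the first
#'   conformer of a non-zwitterionic spec is flagged protonated.
#' @param temperature K, default 298.
#'
#' @details Hydrogen-bond roles: `"nh3_H1"`, `"nh3_H2"`, `"nh3_H3"` (amino-
#'   terminus hydrogens, donors), `"coo_O1"`, `"coo_O2"` (carboxylate
#'   oxygens) and `"carbonyl_O<i>"` (backbone C=O oxygen of residue i) as
#'   acceptors.  Atom densities are constructed so that the acceptor /
#'   bridging-hydrogen density difference reproduces the planned `delta_q`
#'   exactly, letting recomputation tests round-trip.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(sequence, n_conformers = 6, seed = 1,
                           phi_psi_targets = NULL, energy_spread = 2,
                           relative_energies = NULL, mode_plan = NULL,
                           hbond_plan = NULL, zwitterionic = TRUE,
                           temperature = 298) {
  if (!grepl("^[ADEG]+$", sequence))
    stop2("synthetic_spec: sequence must be over the A/D/E/G alphabet")
  if (!is_count(n_conformers))
    stop2("synthetic_spec: n_conformers must be a positive integer")
  structure(
    list(sequence = sequence, n_conformers = as.integer(n_conformers),
         seed = as.integer(seed), phi_psi_targets = phi_psi_targets,
         energy_spread = energy_spread,
         relative_energies = relative_energies,
         mode_plan = mode_plan, hbond_plan = hbond_plan,
         zwitterionic = isTRUE(zwitterionic), temperature = temperature),
    class = "synthetic_spec"
  )
}

#' Build an idealized peptide conformer from internal coordinates
#'
#' Constructs backbone atoms (N, CA, C, carbonyl O), a C-beta stub for
#' non-glycine residues, amide hydrogens, an amino-terminal NH3+ (NH2 when
#' not zwitterionic, plus a carboxylate proton) and a C-terminal
#' carboxylate, with ideal bond lengths/angles and planar trans peptide
#' bonds (omega = 180).  Backbone torsions are set exactly to the supplied
#' phi/psi targets, so [phi_psi()] recovers them to numerical precision.
#'
#' @param sequence one-letter string over A, D, E, G.
#' @param phi_psi `data.frame(phi, psi)` in degrees, one row per residue
#'   (`phi[1]` and `psi[n]` are ignored -- undefined at the termini), or a
#'   length-2 vector recycled to all residues.
#' @param zwitterionic charged termini (default `TRUE`).
#' @return a `"conformer"` with atoms and backbone map (no modes).
#' @export
build_peptide <- function(sequence, phi_psi, zwitterionic = TRUE) {
  if (!grepl("^[ADEG]+$", sequence))
    stop2("build_peptide: unsupported residue letter in '", sequence,
          "' (alphabet is A, D, E, G)")
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  if (n < 2) stop2("build_peptide: need at least 2 residues")
  if (is.numeric(phi_psi) && length(phi_psi) == 2)
    phi_psi <- data.frame(phi = rep(phi_psi[1], n),
                          psi = rep(phi_psi[2], n))
  if (nrow(phi_psi) != n)
    stop2("build_peptide: phi_psi must have one row per residue")

  el <- character(); xyz <- list()
  add <- function(element, pos) {
    el[length(el) + 1L] <<- element
    xyz[[length(xyz) + 1L]] <<- pos
    length(el) - 1L  # 0-based index
  }
  BL <- BOND_LENGTHS; BA <- BOND_ANGLES

  res <- data.frame(residue = seq_len(n), N = NA_integer_,
                    CA = NA_integer_, C = NA_integer_, O = NA_integer_)
  # residue 1 backbone in the xy-plane
  res$N[1] <- add("N", c(0, 0, 0))
  res$CA[1] <- add("C", c(BL["N_CA"], 0, 0))
  th <- deg2rad(BA["N_CA_C"])
  res$C[1] <- add("C", c(BL["N_CA"] - BL["CA_C"] * cos(th),
                         BL["CA_C"] * sin(th), 0))
  pos <- function(i) xyz[[i + 1L]]
  for (i in seq_len(n - 1)) {
    psi_i <- phi_psi$psi[i]
    res$N[i + 1] <- add("N", place_atom(
      pos(res$N[i]), pos(res$CA[i]), pos(res$C[i]),
      BL["C_N"], BA["CA_C_N"], psi_i))
    res$O[i] <- add("O", place_atom(
      pos(res$N[i]), pos(res$CA[i]), pos(res$C[i]),
      BL["C_O"], BA["CA_C_O"], wrap180(psi_i + 180)))
    res$CA[i + 1] <- add("C", place_atom(
      pos(res$CA[i]), pos(res$C[i]), pos(res$N[i + 1]),
      BL["N_CA"], BA["C_N_CA"], 180))
    res$C[i + 1] <- add("C", place_atom(
      pos(res$C[i]), pos(res$N[i + 1]), pos(res$CA[i + 1]),
      BL["CA_C"], BA["N_CA_C"], phi_psi$phi[i + 1]))
    add("H", place_atom(  # amide H, anti to the carbonyl O
      pos(res$CA[i]), pos(res$C[i]), pos(res$N[i + 1]),
      BL["N_H"], BA["C_N_H"], 0))
  }
  # C-terminal carboxylate (or acid) oxygens
  o1 <- add("O", place_atom(pos(res$N[n]), pos(res$CA[n]), pos(res$C[n]),
                            BL["C_OXT"], BA["CA_C_OXT"], 0))
  o2 <- add("O", place_atom(pos(res$N[n]), pos(res$CA[n]), pos(res$C[n]),
                            BL["C_OXT"], BA["CA_C_OXT"], 180))
  # amino-terminus hydrogens
  n_h <- if (zwitterionic) c(60, 180, -60) else c(60, -60)
  for (t in n_h)
    add("H", place_atom(pos(res$C[1]), pos(res$CA[1]), pos(res$N[1]),
                        BL["N_H"], BA["CA_N_H"], t))
  if (!zwitterionic)  # self-protonated: acid proton on O2
    add("H", place_atom(pos(res$CA[n]), pos(res$C[n]), pos(o2),
                        BL["O_H"], BA["C_O_H"], 180))
  # C-beta stubs
  for (i in seq_len(n)) {
    if (letters1[i] != "G")
      add("C", place_atom(pos(res$C[i]), pos(res$N[i]), pos(res$CA[i]),
                          BL["CA_CB"], BA["N_CA_CB"], -120))
  }

  m <- do.call(rbind, xyz)
  conformer(
    id = sequence, sequence = sequence, relative_energy = 0,
    atoms = atom_table(el, m[, 1], m[, 2], m[, 3]),
    backbone = list(residues = res, nterm_N = res$N[1],
                    cterm_C = res$C[n], cterm_O1 = o1, cterm_O2 = o2),
    protonated = !zwitterionic
  )
}

# map a hydrogen-bond role name to a 0-based atom index
role_index <- function(conformer, role) {
  bb <- conformer$backbone
  el <- conformer$atoms$element
  if (grepl("^nh3_H[123]$", role)) {
    k <- as.integer(sub("^nh3_H", "", role))
    # terminus hydrogens are bonded to nterm_N; find them by distance
    xyz <- coords(conformer)
    hs <- which(el == "H") - 1L
    near <- hs[vapply(hs, function(h)
      vnorm(xyz[h + 1L, ] - xyz[bb$nterm_N + 1L, ]) < 1.2, logical(1))]
    if (k > length(near)) stop2("role ", role, ": no such terminal hydrogen")
    return(near[k])
  }
  if (role == "coo_O1") return(bb$cterm_O1)
  if (role == "coo_O2") return(bb$cterm_O2)
  if (grepl("^carbonyl_O\\d+$", role)) {
    i <- as.integer(sub("^carbonyl_O", "", role))
    o <- bb$residues$O[i]
    if (is.na(o)) stop2("role ", role, ": residue ", i, " has no carbonyl O")
    return(o)
  }
  stop2("unknown hydrogen-bond role '", role, "'")
}

default_mode_plan <- function() {
  data.frame(
    target = c("amide_I", "alphaCOO", rep("other", 5)),
    frequency = c(stats::runif(1, 1650, 1750), stats::runif(1, 1650, 1700),
                  stats::runif(3, 400, 1500), stats::runif(2, 2900, 3600)),
    activity = stats::runif(7, 1, 20),
    localization = c(0.9, 0.9, rep(NA_real_, 5))
  )
}

default_hbond_plan <- function(sequence, n_term_h = 3) {
  k <- sample(2:7, 1)
  acceptors <- c("coo_O1", "coo_O2",
                 paste0("carbonyl_O", seq_len(nchar(sequence) - 1)))
  acc <- sample(acceptors, min(k, length(acceptors)))
  data.frame(
    donor_role = paste0("nh3_H", rep_len(seq_len(n_term_h), length(acc))),
    acceptor_role = acc,
    delta_q = c(stats::runif(1, 0.2, 0.4),
                stats::runif(length(acc) - 1, 0.001, 0.1))
  )
}

# displacement matrix with fraction `loc` of squared norm on the planned
# C=O stretch pair(s), remainder spread over other atoms
planted_displacement <- function(conformer, target, loc) {
  if (is.na(loc %||% NA_real_)) loc <- 1
  xyz <- coords(conformer)
  n <- nrow(xyz)
  d <- matrix(0, n, 3)
  pair_atoms <- integer()
  if (identical(target, "amide_I")) {
    p <- band_pairs(conformer, "amide_I")[[1]]
    axis <- unitv(xyz[p[2] + 1L, ] - xyz[p[1] + 1L, ])
    amp <- sqrt(loc / 2)
    d[p[2] + 1L, ] <- amp * axis
    d[p[1] + 1L, ] <- -amp * axis
    pair_atoms <- p + 1L
  } else if (identical(target, "alphaCOO")) {
    ps <- band_pairs(conformer, "alphaCOO")
    amp <- sqrt(loc / 2)
    for (s in c(1, -1)) {
      p <- ps[[if (s == 1) 1 else 2]]
      axis <- unitv(xyz[p[2] + 1L, ] - xyz[p[1] + 1L, ])
      d[p[2] + 1L, ] <- s * amp * axis
      pair_atoms <- c(pair_atoms, p[2] + 1L)
    }
    pair_atoms <- c(pair_atoms, ps[[1]][1] + 1L)
  }
  rest <- setdiff(seq_len(n), pair_atoms)
  resid <- if (identical(target, "other")) 1 else 1 - sum(d^2)
  if (resid > 1e-12 && length(rest)) {
    r <- matrix(stats::rnorm(length(rest) * 3), ncol = 3)
    r <- r / sqrt(sum(r^2)) * sqrt(resid)
    d[rest, ] <- r
  }
  d
}

BASE_DENSITY <- c(H = 0.450, C = 5.900, N = 7.600, O = 8.600)

#' Generate a synthetic conformer ensemble
#'
#' Draws relative energies (minimum forced to 0), builds each conformer's
#' geometry at its phi/psi targets, plants normal modes on the requested
#' bonds with the requested localization, installs the planned hydrogen
#' bonds with their delta_q, and sets atomic densities so the
#' acceptor-hydrogen density difference reproduces each planned delta_q
#' exactly.  Bit-reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return an `"ensemble"`.
#' @export
synthesize_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_conformers
    energies <- spec$relative_energies %||%
      c(0, sort(pmin(stats::rexp(n - 1, 1 / spec$energy_spread), 50)))
    if (length(energies) != n)
      stop2("synthesize_ensemble: relative_energies length != n_conformers")
    confs <- lapply(seq_len(n), function(i) {
      pp <- if (!is.null(spec$phi_psi_targets)) spec$phi_psi_targets[[i]]
      else data.frame(phi = stats::runif(nchar(spec$sequence), -180, 180),
                      psi = stats::runif(nchar(spec$sequence), -180, 180))
      zwit <- spec$zwitterionic || i > 1
      cf <- build_peptide(spec$sequence, pp, zwitterionic = zwit)
      cf$id <- paste0(spec$sequence, "-", LETTERS[i])
      cf$relative_energy <- energies[i]

      plan <- if (!is.null(spec$mode_plan)) spec$mode_plan[[i]]
      else default_mode_plan()
      cf$modes <- mode_table(plan$frequency, plan$activity)
      cf$displacements <- lapply(seq_len(nrow(plan)), function(k)
        planted_displacement(cf, plan$target[k],
                             plan$localization[k] %||% NA_real_))

      hplan <- if (!is.null(spec$hbond_plan)) spec$hbond_plan[[i]]
      else default_hbond_plan(spec$sequence, n_term_h = if (zwit) 3 else 2)
      dens <- BASE_DENSITY[cf$atoms$element]
      if (!is.null(hplan) && nrow(hplan)) {
        don_n <- cf$backbone$nterm_N
        hb <- do.call(rbind, lapply(seq_len(nrow(hplan)), function(j) {
          h <- role_index(cf, hplan$donor_role[j])
          a <- role_index(cf, hplan$acceptor_role[j])
          hbond_table(don_n, h, a, hplan$delta_q[j])
        }))
        # densities constructed to encode the planned delta_q exactly
        dens[hb$hydrogen + 1L] <- BASE_DENSITY["H"]
        dens[hb$acceptor + 1L] <- BASE_DENSITY["H"] + hb$delta_q
        cf$hbonds <- hb
      }
      cf$atoms$density <- unname(dens)
      validate_conformer(cf)
      cf
    })
    ensemble(spec$sequence, confs, temperature = spec$temperature)
  })
}

#' Write a conformer (or ensemble) as a mock quantum-chemistry log
#'
#' Emits the single log dialect understood by
#' [read_qc_frequency_block()]: a coordinates block, a
#' `Harmonic frequencies` block with per-mode `Frequencies --`,
#' `Raman Activ --` and displacement rows, and a
#' `Natural Population Analysis` block.  Numbers are printed with 17
#' significant digits so the mode table round-trips bit-exactly.
#'
#' @param x a `"conformer"`, or an `"ensemble"` (one log per conformer is
#'   then written into the directory `path`).
#' @param path output file (conformer) or directory (ensemble).
#' @return the path(s) written, invisibly.
#' @export
write_mock_log <- function(x, path) {
  if (inherits(x, "ensemble")) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(x$conformers, function(cf) {
      p <- file.path(path, paste0(cf$id, ".log"))
      write_mock_log(cf, p)
      p
    }, character(1))
    return(invisible(paths))
  }
  stopifnot(inherits(x, "conformer"))
  g <- function(v) sprintf("%.17g", v)
  lines <- c(
    "Mock electronic-structure log (dialect bzr-log-1)",
    sprintf("Fragment: %s  Conformer: %s", x$sequence, x$id),
    "",
    "Coordinates (Angstroms)",
    sprintf(" %4d %-2s %s %s %s", seq_len(nrow(x$atoms)), x$atoms$element,
            g(x$atoms$x), g(x$atoms$y), g(x$atoms$z)),
    "",
    "Harmonic frequencies (cm**-1), Raman scattering activities (A**4/AMU)"
  )
  for (k in seq_len(nrow(x$modes))) {
    d <- x$displacements[[k]]
    lines <- c(
      lines,
      sprintf(" Mode %d", k),
      sprintf(" Frequencies -- %s", g(x$modes$frequency[k])),
      sprintf(" Raman Activ -- %s", g(x$modes$raman_activity[k])),
      sprintf(" %4d %-2s %s %s %s", seq_len(nrow(x$atoms)),
              x$atoms$element, g(d[, 1]), g(d[, 2]), g(d[, 3]))
    )
  }
  if (!all(is.na(x$atoms$density))) {
    lines <- c(
      lines, "",
      "Natural Population Analysis (total natural electron density)",
      sprintf(" %4d %-2s %s", seq_len(nrow(x$atoms)), x$atoms$element,
              g(x$atoms$density))
    )
  }
  writeLines(lines, path)
  invisible(path)
}
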