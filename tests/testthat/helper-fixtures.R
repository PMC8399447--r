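# Shared helpers: tiny constructed conformers and synthetic-spec shortcuts.

kT298 <- boltzbands::R_KCAL_MOL * 298

empty_mode_plan <- data.frame(target = character(), frequency = numeric(),
                              activity = numeric(), localization = numeric())
empty_hbond_plan <- data.frame(donor_role = character(),
                               acceptor_role = character(),
                               delta_q = numeric())

cross_prod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# unit in the last printed significant digit of e.g. "9.74e-1" or "1.00"
ulp_of <- function(s) {
  mant <- sub("e.*$", "", s)
  ex <- ifelse(grepl("e", s), as.numeric(sub("^.*e", "", s)), 0)
  dec <- ifelse(grepl("\\.", mant), nchar(sub("^[^.]*\\.", "", mant)), 0)
  10^(ex - dec)
}

# bare ensemble with given relative energies (no geometry needed)
energy_only_ensemble <- function(energies, fragment = "TEST") {
  confs <- lapply(seq_along(energies), function(i)
    conformer(id = paste0(fragment, "-", LETTERS[i]), sequence = "EG",
              relative_energy = energies[i],
              atoms = atom_table("C", 0, 0, 0)))
  ensemble(fragment, confs)
}

# synthetic spec with planted band modes, fast to generate
planted_spec <- function(sequence = "EGEDEA", energies = c(0, 1),
                         amide_raw = 1709.3, acoo_raw = 1680,
                         seed = 42, ...) {
  n <- length(energies)
  plan <- data.frame(target = c("amide_I", "alphaCOO"),
                     frequency = c(amide_raw, acoo_raw),
                     activity = c(12, 8), localization = c(1, 0.9))
  synthetic_spec(sequence, n_conformers = n, seed = seed,
                 relative_energies = energies,
                 mode_plan = rep(list(plan), n), ...)
}

# random proper rotation matrix (det +1; deterministic under calling seed)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rotation <- function(cf, rot, shift = c(0, 0, 0)) {
  xyz <- as.matrix(cf$atoms[, c("x", "y", "z")]) %*% t(rot)
  cf$atoms$x <- xyz[, 1] + shift[1]
  cf$atoms$y <- xyz[, 2] + shift[2]
  cf$atoms$z <- xyz[, 3] + shift[3]
  cf$displacements <- lapply(cf$displacements, function(d) d %*% t(rot))
  cf
}
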