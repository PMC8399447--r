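# Synthetic-ensemble generator: construction fidelity, determinism,
# round trips and the statistical regime it emulates.

test_that("generation is bit-reproducible from the seed", {
  spec <- synthetic_spec("EGED", n_conformers = 4, seed = 123)
  expect_identical(synthesize_ensemble(spec), synthesize_ensemble(spec))
  # a different seed changes the draw
  spec2 <- synthetic_spec("EGED", n_conformers = 4, seed = 124)
  expect_false(identical(synthesize_ensemble(spec),
                         synthesize_ensemble(spec2)))
  # and the global RNG stream is left untouched
  set.seed(555); before <- .Random.seed
  invisible(synthesize_ensemble(spec))
  expect_identical(.Random.seed, before)
})

test_that("planted energies propagate to closed-form weights", {
  spec <- planted_spec("EG", energies = c(0, kT298 * log(2)))
  w <- weight_ensemble(synthesize_ensemble(spec))
  expect_equal(w$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("a planted localized amide mode lands at the scaled position", {
  ens <- synthesize_ensemble(planted_spec("EGEDEA", energies = 0,
                                          amide_raw = 1709.3))
  a <- assign_band(ens$conformers[[1]], "amide_I")
  expect_equal(a$position, 1658.021, tolerance = 1e-9)
  expect_equal(round_half_away(a$position), 1658)
})

test_that("built geometries keep the documented bond lengths", {
  cf <- build_peptide("EGEDEA", c(-57, -47))
  xyz <- as.matrix(cf$atoms[, c("x", "y", "z")])
  bb <- cf$backbone$residues
  d <- function(i, j) sqrt(sum((xyz[i + 1, ] - xyz[j + 1, ])^2))
  for (i in 1:6) {
    expect_equal(d(bb$N[i], bb$CA[i]), 1.458, tolerance = 0.01)
    expect_equal(d(bb$CA[i], bb$C[i]), 1.525, tolerance = 0.01)
    if (i < 6) {
      expect_equal(d(bb$C[i], bb$O[i]), 1.231, tolerance = 0.01)
      expect_equal(d(bb$C[i], bb$N[i + 1]), 1.329, tolerance = 0.01)
    }
  }
  expect_equal(d(cf$backbone$cterm_C, cf$backbone$cterm_O1), 1.251,
               tolerance = 0.01)
  expect_equal(d(cf$backbone$cterm_C, cf$backbone$cterm_O2), 1.251,
               tolerance = 0.01)
  expect_error(build_peptide("EGW", c(180, 180)), "unsupported")
})

test_that("termini bookkeeping distinguishes zwitterion and protonated", {
  zw <- build_peptide("EGEDEA", c(-57, -47))
  expect_false(zw$protonated)
  # three hydrogens on the terminal nitrogen
  xyz <- as.matrix(zw$atoms[, c("x", "y", "z")])
  nh <- sum(zw$atoms$element == "H" &
              sqrt(rowSums((xyz - matrix(xyz[zw$backbone$nterm_N + 1, ],
                                         nrow(xyz), 3,
                                         byrow = TRUE))^2)) < 1.2)
  expect_equal(nh, 3)
  pr <- build_peptide("EGEDEA", c(-57, -47), zwitterionic = FALSE)
  expect_true(pr$protonated)
  xyzp <- as.matrix(pr$atoms[, c("x", "y", "z")])
  nhp <- sum(pr$atoms$element == "H" &
               sqrt(rowSums((xyzp - matrix(xyzp[pr$backbone$nterm_N + 1, ],
                                           nrow(xyzp), 3,
                                           byrow = TRUE))^2)) < 1.2)
  expect_equal(nhp, 2)
})

test_that("mock logs round-trip the generator's tables bit-exactly", {
  ens <- synthesize_ensemble(synthetic_spec("EGED", n_conformers = 2,
                                            seed = 9))
  path <- withr::local_tempfile(fileext = ".log")
  write_mock_log(ens$conformers[[1]], path)
  p <- read_qc_frequency_block(path)
  expect_identical(p$modes$frequency, ens$conformers[[1]]$modes$frequency)
  expect_identical(p$modes$raman_activity,
                   ens$conformers[[1]]$modes$raman_activity)
  expect_identical(p$atoms$density, ens$conformers[[1]]$atoms$density)
  expect_equal(p$displacements, lapply(ens$conformers[[1]]$displacements,
                                       unname))
  expect_equal(p$atoms$x, ens$conformers[[1]]$atoms$x)

  # a conformer without modes writes a log the parser must reject
  bare <- build_peptide("EG", c(180, 180))
  p2 <- withr::local_tempfile(fileext = ".log")
  write_mock_log(bare, p2)
  expect_error(read_qc_frequency_block(p2), "no frequency block")

  # ensemble input writes one log per conformer
  dir <- withr::local_tempdir()
  paths <- write_mock_log(ens, dir)
  expect_length(paths, 2)
  expect_true(all(file.exists(paths)))
})

test_that("planted hydrogen-bond charges are encoded in the densities", {
  plan <- data.frame(donor_role = c("nh3_H1", "nh3_H3"),
                     acceptor_role = c("coo_O1", "carbonyl_O2"),
                     delta_q = c(0.31, 0.04))
  spec <- synthetic_spec("EGED", n_conformers = 1, seed = 12,
                         relative_energies = 0,
                         mode_plan = list(empty_mode_plan),
                         hbond_plan = list(plan))
  cf <- synthesize_ensemble(spec)$conformers[[1]]
  expect_equal(cf$hbonds$delta_q, plan$delta_q)
  for (i in seq_len(nrow(cf$hbonds)))
    expect_equal(hbond_delta_q(cf, cf$hbonds[i, ]), plan$delta_q[i],
                 tolerance = 1e-12)
})

test_that("default draws sit in the dominant-minimum regime", {
  # with the default 2 kcal/mol exponential energy spread the lowest
  # conformer dominates: mean lowest-conformer weight over 1000 seeds > 0.5
  w1 <- vapply(1:1000, function(s) {
    sp <- synthetic_spec("EG", n_conformers = 6, seed = s,
                         mode_plan = rep(list(empty_mode_plan), 6),
                         hbond_plan = rep(list(empty_hbond_plan), 6))
    weight_ensemble(synthesize_ensemble(sp))$weights[1]
  }, numeric(1))
  expect_gt(mean(w1), 0.5)
  # energies respect the collection window and the zero minimum
  es <- relative_energies(synthesize_ensemble(
    synthetic_spec("EG", n_conformers = 8, seed = 77, energy_spread = 20,
                   mode_plan = rep(list(empty_mode_plan), 8),
                   hbond_plan = rep(list(empty_hbond_plan), 8))))
  expect_equal(min(es), 0)
  expect_true(all(es <= 50))
})
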