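# Interchange I/O, fixture loading, log parsing, energy windows.

test_that("reading re-references energies so the minimum is zero", {
  cf <- conformer("X-A", "EG", 3.0, atom_table("C", 0, 0, 0))
  ens <- ensemble("X", list(cf))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(relative_energies(back), 0)
  # idempotent
  expect_equal(relative_energies(rereference_energies(back)), 0)
})

test_that("write/read round-trips every conformer field", {
  for (seed in c(1, 7, 23)) {
    ens <- synthesize_ensemble(synthetic_spec("EGED", n_conformers = 3,
                                              seed = seed))
    path <- withr::local_tempfile(fileext = ".json")
    write_ensemble(ens, path)
    back <- read_ensemble(path)
    expect_equal(back$fragment, ens$fragment)
    expect_equal(back$temperature, ens$temperature)
    for (i in seq_along(ens$conformers)) {
      a <- ens$conformers[[i]]; b <- back$conformers[[i]]
      expect_identical(b$id, a$id)
      expect_equal(b$atoms, a$atoms)
      expect_equal(b$modes, a$modes)
      expect_equal(b$displacements, a$displacements)
      expect_equal(b$hbonds, a$hbonds)
      expect_equal(b$backbone, a$backbone)
      expect_identical(b$protonated, a$protonated)
    }
  }
})

test_that("schema violations are rejected with the field named", {
  ens <- synthesize_ensemble(synthetic_spec("EG", n_conformers = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  l <- jsonlite::read_json(path, simplifyVector = FALSE)

  l2 <- l; l2$conformers[[1]]$relative_energy <- NULL
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(l2, p2, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(p2), "relative_energy")

  l3 <- l; l3$conformers[[2]]$id <- l3$conformers[[1]]$id
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(l3, p3, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(p3), "duplicate")

  l4 <- l; l4$conformers <- list()
  p4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(l4, p4, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(p4), "empty")

  l5 <- l; l5$schema <- "other-9"
  p5 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(l5, p5, auto_unbox = TRUE, digits = NA)
  expect_error(read_ensemble(p5), "schema")
})

test_that("a displacement list inconsistent with the atom count is rejected", {
  atoms <- atom_table(c("C", "O"), c(0, 1.2), 0, 0)
  modes <- mode_table(1700, 10)
  expect_error(
    conformer("X-A", "EG", 0, atoms, modes,
              displacements = list(matrix(0, 3, 3))),
    "displacements"
  )
})

test_that("the per-conformer reference table loads as printed", {
  t1 <- load_table1_fixture()
  expect_equal(nrow(t1), 66)
  expect_equal(length(unique(t1$fragment)), 11)
  expect_setequal(attr(t1, "missing_protonated"), c("EG", "EGED", "EGEDEA"))
  ega <- t1[t1$structure == "EG-A", ]
  expect_equal(ega$delta_e, 0)
  expect_equal(ega$n_i, 0.974)
  expect_equal(ega$qt, 0.594)
  expect_equal(ega$amide_I_position, 1655)
  expect_equal(ega$acoo_position, 1645)
  egb <- t1[t1$structure == "EGEDEA-B", ]
  expect_equal(egb$delta_e, 1.44)
  expect_equal(egb$amide_I, -1)   # signed shift as printed
  expect_equal(egb$acoo, 1)
  expect_equal(egb$amide_I_position, 1658 - 1)
  # shift resolution applies the A-row absolute position
  expect_equal(t1[t1$structure == "ED-B", "amide_I_position"], 1631 + 34)
})

test_that("energy windows filter conformers as tabulated", {
  t1 <- load_table1_fixture()
  edea <- energy_only_ensemble(t1$delta_e[t1$fragment == "EDEA"], "EDEA")
  expect_length(filter_by_energy_window(edea, 50)$conformers, 6)
  kept <- filter_by_energy_window(edea, 10)
  expect_equal(relative_energies(kept), c(0, 1.53, 7.87))
  # re-referenced ensembles always retain the zero-energy minimum
  expect_length(filter_by_energy_window(edea, 0.5)$conformers, 1)
  expect_length(filter_by_energy_window(edea, 1e-12)$conformers, 1)
  expect_error(filter_by_energy_window(edea, -1), "max_delta_e")
})

test_that("the qc log parser echoes a minimal hand-written block", {
  path <- withr::local_tempfile(fileext = ".log")
  writeLines(c(
    "Harmonic frequencies (cm**-1), Raman scattering activities (A**4/AMU)",
    " Mode 1",
    " Frequencies -- 1650.0",
    " Raman Activ -- 10.0",
    "    1 C  0.1 0.0 0.0",
    "    2 O  -0.1 0.0 0.0",
    " Mode 2",
    " Frequencies -- 1700.0",
    " Raman Activ -- 5.0",
    "    1 C  0.0 0.1 0.0",
    "    2 O  0.0 -0.1 0.0"
  ), path)
  p <- read_qc_frequency_block(path)
  expect_equal(p$modes$frequency, c(1650, 1700))
  expect_equal(p$modes$raman_activity, c(10, 5))
  expect_equal(p$atoms$element, c("C", "O"))
  expect_equal(p$displacements[[1]][, 1], c(0.1, -0.1))
})

test_that("qc log error paths name the problem", {
  p1 <- withr::local_tempfile(fileext = ".log")
  writeLines(c("just a greeting", "no data here"), p1)
  expect_error(read_qc_frequency_block(p1), "no frequency block")

  p2 <- withr::local_tempfile(fileext = ".log")
  writeLines(c(
    "Harmonic frequencies",
    " Mode 1",
    " Frequencies -- 1650.0",
    " IR Inten    -- 3.0",
    "    1 C  0.1 0.0 0.0"
  ), p2)
  expect_error(read_qc_frequency_block(p2), "Raman")

  p3 <- withr::local_tempfile(fileext = ".log")
  writeLines(c("Harmonic frequencies", " Mode 1"), p3)
  expect_error(read_qc_frequency_block(p3), "line 3")
})

test_that("xyz and xyz+csv routes carry bare coordinates", {
  cf <- build_peptide("EG", c(180, 180))
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cf, p, comment = "extended EG")
  atoms <- read_xyz(p)
  expect_equal(atoms$element, cf$atoms$element)
  expect_equal(atoms$x, cf$atoms$x, tolerance = 1e-9)

  dir <- withr::local_tempdir()
  write_xyz(cf, file.path(dir, "EG-A.xyz"))
  write_xyz(cf, file.path(dir, "EG-B.xyz"))
  utils::write.csv(data.frame(id = c("EG-A", "EG-B"),
                              relative_energy = c(2.0, 1.0),
                              sequence = "EG", fragment = "EG"),
                   file.path(dir, "conformers.csv"), row.names = FALSE)
  ens <- read_ensemble(dir, format = "xyz+csv")
  expect_equal(relative_energies(ens), c(1.0, 0.0))  # re-referenced
  expect_equal(ens$fragment, "EG")
})

test_that("pdb export writes one ATOM record per atom", {
  cf <- build_peptide("EGE", c(-57, -47))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(cf, p)
  lines <- readLines(p)
  expect_equal(sum(grepl("^ATOM", lines)), nrow(cf$atoms))
  expect_true(any(grepl("GLU", lines)) && any(grepl("GLY", lines)))
})
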