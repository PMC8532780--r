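test_that("PDB write/read round-trips the model at format precision", {
  m <- ala_helix(3)
  p1 <- tempfile(fileext = ".pdb")
  p2 <- tempfile(fileext = ".pdb")
  write_structure(m, p1, "pdb")
  m2 <- read_structure(p1, "pdb")
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(unique(paste(m2$atoms$resid, m2$atoms$resno)),
               unique(paste(m$atoms$resid, m$atoms$resno)))
  expect_lt(max(abs(as.matrix(m2$atoms[c("x", "y", "z")]) -
                    as.matrix(m$atoms[c("x", "y", "z")]))), 5e-4)
  # write of the re-read model is bit-identical
  write_structure(m2, p2, "pdb")
  expect_identical(readLines(p1), readLines(p2))
})

test_that("mmCIF write/read round-trips exactly and keeps cell metadata", {
  m <- ala_helix(3)
  m$cell <- list(lengths = c(14.1, 20, 30), angles = c(90, 95.5, 90))
  m$space_group <- "P 21"
  p <- tempfile(fileext = ".cif")
  write_structure(m, p, "mmcif")
  m2 <- read_structure(p, "mmcif")
  expect_equal(as.matrix(m2$atoms[c("x", "y", "z")]),
               as.matrix(m$atoms[c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$cell$lengths, m$cell$lengths, tolerance = 1e-3)
  expect_equal(m2$space_group, "P 21")
  # nonstandard residue names survive both dialects
  alm <- build_helix(helix_spec())
  pa <- tempfile(fileext = ".cif")
  write_structure(alm, pa, "mmcif")
  expect_true(all(c("AIB", "PHL", "ACE") %in%
                  read_structure(pa)$atoms$resid))
})

test_that("mmCIF reader handles missing cell values and fractional coords", {
  p <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_x",
    "_cell.length_a 14.1000",
    "_cell.length_b ?",
    "_cell.length_c ?",
    "loop_", "_atom_site.type_symbol", "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "N N ALA A 1 1.0 2.0 3.0"), p)
  m <- read_structure(p, "mmcif")
  expect_equal(m$cell$lengths[1], 14.1)
  expect_true(is.na(m$cell$lengths[2]))

  # fractional coordinates in an orthorhombic cell convert via the cell
  pf <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_y",
    "_cell.length_a 10.0", "_cell.length_b 20.0", "_cell.length_c 30.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0",
    "_cell.angle_gamma 90.0",
    "loop_", "_atom_site.type_symbol", "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.fract_x", "_atom_site.fract_y",
    "_atom_site.fract_z",
    "N N ALA A 1 0.5 0.25 0.1"), pf)
  mf <- read_structure(pf, "mmcif")
  expect_equal(as.numeric(mf$atoms[1, c("x", "y", "z")]), c(5, 5, 3),
               tolerance = 1e-9)
})

test_that("structure model invariants are enforced", {
  atoms <- data.frame(element = "N", name = "N", resid = "ALA",
                      resno = 1L, chain = "A", x = 0, y = 0, z = 0)
  expect_error(structure_model(rbind(atoms, atoms)), "duplicate atom key")
  bad <- atoms; bad$x <- NaN
  expect_error(structure_model(bad), "finite")
  # insertion codes rejected on read
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1A     0.000   0.000   0.000  1.00  0.00           N",
    "END"), p)
  expect_error(read_structure(p, "pdb"), "insertion")
  # malformed record names the line
  p2 <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1", "END"), p2)
  expect_error(read_structure(p2, "pdb"), "line 1")
})

test_that("empty model writes a header-only file", {
  m0 <- structure_model(data.frame(element = character(0),
                                   name = character(0),
                                   resid = character(0),
                                   resno = integer(0), chain = character(0),
                                   x = numeric(0), y = numeric(0),
                                   z = numeric(0)))
  p <- tempfile(fileext = ".pdb")
  write_structure(m0, p, "pdb")
  expect_identical(readLines(p), "END")
})

test_that("MAGRES fixture with a diagonal tensor reads back verbatim", {
  p <- tempfile(fileext = ".magres")
  writeLines(c("#$magres-abinitio-v1.0",
               "[atoms]", "units atom Angstrom",
               "atom N N 1 0.0 0.0 0.0", "[/atoms]",
               "[magres]", "units ms ppm",
               "ms N 1 100 0 0 0 150 0 0 0 200", "[/magres]"), p)
  recs <- read_magres(p)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$matrix, diag(c(100, 150, 200)))
  expect_equal(recs[[1]]$site_key$resno, 1)
})

test_that("planted MAGRES bundle round-trips against its structure", {
  alm <- build_helix(helix_spec())
  resnos <- c(1, 3:13, 15:19)   # amide sites excluding the two prolines
  sites <- data.frame(resno = resnos, nucleus = "15N", s11 = 155,
                      s22 = 140, s33 = 20, alpha = 4, beta = 13,
                      gamma = 30)
  pl <- plant_tensors(alm, sites)
  d <- tempfile()
  paths <- write_fixture_bundle(alm, pl, d)
  recs <- read_magres(paths[["magres"]], read_structure(paths[["structure"]]))
  expect_length(recs, length(resnos))
  expect_equal(recs[[1]]$matrix, pl$records[[1]]$matrix, tolerance = 1e-6)
})

test_that("malformed MAGRES input is rejected with a line reference", {
  p <- tempfile()
  writeLines(c("[atoms]", "units atom Angstrom",
               "atom N N 1 0 0 0", "[/atoms]",
               "[magres]", "ms N 1 1 2 3"), p)
  expect_error(read_magres(p), "3x3")
  p2 <- tempfile()
  writeLines(c("[atoms]", "atom N N 1 0 0 0", "[/atoms]", "[magres]",
               "ms N 2 1 0 0 0 1 0 0 0 1"), p2)
  expect_error(read_magres(p2), "unknown atom")
  p3 <- tempfile()
  writeLines(c("[magres]", "units ms ppm"), p3)
  expect_error(read_magres(p3), "truncated")
  # record with no matching atom site in the companion model
  p4 <- tempfile()
  writeLines(c("[magres]", "ms CX 99 1 0 0 0 1 0 0 0 1", "[/magres]"), p4)
  expect_error(read_magres(p4, model = ala_helix(3)), "no matching atom")
})
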