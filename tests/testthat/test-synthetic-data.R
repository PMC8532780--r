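test_that("helix specs validate their inputs", {
  expect_error(helix_spec("ALA"), "at least 2")
  expect_error(helix_spec(c("ALA", "XXX")), "unknown residue")
  expect_error(helix_spec(rep("ALA", 3), coordinate_noise_sd = -1), ">= 0")
  m2 <- build_helix(helix_spec(c("ALA", "ALA"), cap = FALSE))
  expect_equal(sort(unique(m2$atoms$resno)), c(1, 2))
})

test_that("generated helices have alpha-helical rise and twist", {
  m <- ala_helix(12)
  f <- fit_helix_axis(m)
  expect_equal(f$rise, 1.5, tolerance = 0.1)
  expect_equal(f$radius, 2.3, tolerance = 0.1)
  inc <- diff(residue_azimuth(m, f)) %% 360
  expect_true(all(abs(inc - 100) < 1))
})

test_that("the default peptaibol build honours residue chemistry", {
  alm <- build_helix(helix_spec())
  a <- alm$atoms
  expect_equal(a$resid[a$resno == 0][1], "ACE")       # acetyl cap
  expect_false(any(a$name[a$resno == 2] == "H"))      # Pro2 lacks amide H
  expect_false(any(a$name[a$resno == 14] == "H"))
  expect_false(any(a$name[a$resno == 20] == "O"))     # Phl20 lacks a carbonyl
  expect_false(any(a$name[a$resno == 11] == "CB"))    # Gly11 lacks CB
  expect_true(all(c("N", "H", "CA", "CB", "C", "O") %in%
                  a$name[a$resno == 8]))
})

test_that("coordinate noise is seeded and reproducible", {
  m1 <- build_helix(helix_spec(rep("ALA", 6), cap = FALSE,
                               coordinate_noise_sd = 0.05, seed = 11))
  m2 <- build_helix(helix_spec(rep("ALA", 6), cap = FALSE,
                               coordinate_noise_sd = 0.05, seed = 11))
  m3 <- build_helix(helix_spec(rep("ALA", 6), cap = FALSE,
                               coordinate_noise_sd = 0.05, seed = 12))
  expect_identical(m1$atoms, m2$atoms)
  expect_gt(max(abs(m1$atoms$x - m3$atoms$x)), 0)
})

test_that("infeasible planted angle combinations are rejected", {
  alm <- build_helix(helix_spec())
  bad <- data.frame(resno = 8, nucleus = "15N", s11 = 155, s22 = 140,
                    s33 = 20, alpha = 30, beta = 5, gamma = 40)
  expect_error(plant_tensors(alm, bad), "infeasible")
  unsorted <- data.frame(resno = 8, nucleus = "15N", s11 = 20, s22 = 140,
                         s33 = 155, alpha = 1, beta = 5, gamma = 5)
  expect_error(plant_tensors(alm, unsorted), "s11 >= s22")
  pro <- data.frame(resno = 2, nucleus = "15N", s11 = 155, s22 = 140,
                    s33 = 20, alpha = 1, beta = 5, gamma = 5)
  expect_error(plant_tensors(alm, pro), "undefined")
})

test_that("noisy planted tensors recover angles without bias", {
  alm <- build_helix(helix_spec())
  truth <- c(4.2, 12.9, 51.5)
  errs <- t(vapply(1:40, function(s)
    recover_15N(alm, 8, truth, noise = 2, seed = s) - truth, numeric(3)))
  # unbiased within Monte-Carlo error (3 sigma of the mean)
  mc <- 3 * apply(errs, 2, sd) / sqrt(nrow(errs))
  expect_true(all(abs(colMeans(errs)) < pmax(mc, 0.2)))

  # estimator error shrinks as the noise vanishes
  err_small <- abs(recover_15N(alm, 8, truth, noise = 0.1, seed = 5) - truth)
  err_zero <- abs(recover_15N(alm, 8, truth, noise = 0, seed = 5) - truth)
  expect_true(all(err_zero < 1e-6))
  expect_true(all(err_small < 1))
})

test_that("a zero-noise fixture bundle closes the full pipeline", {
  spec <- helix_spec()
  alm <- build_helix(spec)
  resnos <- c(1, 3:13, 15:19)
  sites <- data.frame(resno = resnos, nucleus = "15N",
                      s11 = seq(160, 145, length.out = length(resnos)),
                      s22 = 140, s33 = 20,
                      alpha = rep(c(2, 4, 6), length.out = length(resnos)),
                      beta = rep(c(13, 17), length.out = length(resnos)),
                      gamma = seq(10, 70, length.out = length(resnos)))
  pl <- plant_tensors(alm, sites)
  d <- tempfile()
  paths <- write_fixture_bundle(alm, pl, d)

  m <- read_structure(paths[["structure"]])
  recs <- read_magres(paths[["magres"]], m)
  truth <- read.csv(paths[["truth"]])

  # dihedrals and hydrogen bonds as planted
  r <- ramachandran(m)
  expect_lt(max(abs(r$phi[-1] - spec$phi[-1])), 0.1)
  hb <- detect_hbonds(m)
  expect_true(all(hb$span == 4))

  # azimuth increments ~100 degrees in the regular segment (Phl20 has no
  # carbonyl site vector and is reported NA with a warning)
  f <- fit_helix_axis(m, window = c(3, 9))
  expect_warning(rho <- residue_azimuth(m, f), "undefined")
  inc <- diff(rho[as.character(3:9)]) %% 360
  expect_true(all(abs(inc - 100) < 2))

  # tensor angles and calibrated shifts round-trip through the files
  line <- shift_calibration("15N")
  for (i in seq_along(recs)) {
    pf <- principal_frame(recs[[i]]$matrix)
    expect_equal(pf$sigma,
                 as.numeric(truth[i, c("s11", "s22", "s33")]),
                 tolerance = 1e-5, ignore_attr = TRUE)
    oa <- orientation_angles_15N(pf, plane_N(m, truth$resno[i]))
    # PDB stores coordinates at 3 decimals; plane normals inherit that
    # precision, so angle closure through the files is good to ~0.05 deg
    expect_equal(c(oa$alpha, oa$beta, oa$gamma),
                 as.numeric(truth[i, c("alpha", "beta", "gamma")]),
                 tolerance = 0.05, ignore_attr = TRUE)
    ts <- shielding_to_shift(pf$sigma, line)
    expect_equal(ts$eps,
                 sort(line$slope * pf$sigma + line$intercept),
                 tolerance = 1e-9)
  }
})

test_that("structure-only bundles omit tensor files", {
  d <- tempfile()
  paths <- write_fixture_bundle(ala_helix(4), NULL, d)
  expect_true(file.exists(paths[["structure"]]))
  expect_false(file.exists(file.path(d, "tensors.magres")))
})
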