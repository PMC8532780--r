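test_that("peptide planes are built from the defining atom triples", {
  atoms <- data.frame(
    element = c("N", "H", "C"), name = c("N", "H", "CA"),
    resid = "ALA", resno = 1L, chain = "A",
    x = c(0, 1, 0), y = c(0, 0, 1), z = c(0, 0, 0))
  m <- structure_model(atoms)
  pl <- plane_N(m, 1)
  expect_true(pl$defined)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-9)  # cross(x, y)
  expect_equal(pl$in_plane_bond, c(1, 0, 0))
  expect_lt(abs(sum(pl$normal * pl$in_plane_bond)), 1e-8)

  alm <- build_helix(helix_spec())
  expect_false(plane_N(alm, 2)$defined)    # Pro2: no amide H
  expect_false(plane_N(alm, 14)$defined)   # Pro14
  expect_true(plane_C(alm, 2)$defined)     # prolines do have carbonyls
  expect_false(plane_C(alm, 20)$defined)   # Phl20: no carbonyl
  expect_true(plane_N(alm, 20)$defined)
})

test_that("aligned and perpendicular eigenframes give limiting angles", {
  atoms <- data.frame(
    element = c("N", "H", "C"), name = c("N", "H", "CA"),
    resid = "ALA", resno = 1L, chain = "A",
    x = c(0, 1, 0), y = c(0, 0, 1), z = c(0, 0, 0))
  pl <- plane_N(structure_model(atoms), 1)
  # xi3 along N->H (in plane), xi2 along the normal: all angles zero
  V <- cbind(c(0, -1, 0), c(0, 0, 1), c(1, 0, 0))
  fr <- structure(list(sigma = c(3, 2, 1), vectors = V, degenerate = FALSE),
                  class = "principal_frame")
  oa <- orientation_angles_15N(fr, pl)
  expect_equal(c(oa$alpha, oa$beta, oa$gamma), c(0, 0, 0), tolerance = 1e-9)

  # xi3 along the plane normal: alpha = 90
  V2 <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  fr2 <- structure(list(sigma = c(3, 2, 1), vectors = V2,
                        degenerate = FALSE), class = "principal_frame")
  expect_equal(orientation_angles_15N(fr2, pl)$alpha, 90, tolerance = 1e-9)

  # 13C: xi2 perpendicular to the plane -> alpha = 90
  expect_equal(orientation_angles_13C(fr2, pl)$alpha, 0, tolerance = 1e-9)
  fr3 <- structure(list(sigma = c(3, 2, 1),
                        vectors = cbind(c(1, 0, 0), c(0, 0, 1),
                                        c(0, -1, 0)),
                        degenerate = FALSE), class = "principal_frame")
  expect_equal(orientation_angles_13C(fr3, pl)$alpha, 90, tolerance = 1e-9)

  degen <- structure(list(sigma = c(2, 2, 2), vectors = diag(3),
                          degenerate = TRUE), class = "principal_frame")
  expect_error(orientation_angles_15N(degen, pl), "degenerate")
  expect_error(orientation_angles_15N(fr, plane_N(build_helix(helix_spec()),
                                                  2)), "undefined")
})

test_that("planted tensors are recovered to numerical precision", {
  alm <- build_helix(helix_spec())
  # 15N targets echoing an Aib-like row
  rec <- recover_15N(alm, 8, c(4.2, 12.9, 51.5))
  expect_equal(rec, c(4.2, 12.9, 51.5), tolerance = 1e-6)

  # 13C targets echoing a carbonyl row
  sites <- data.frame(resno = 1, nucleus = "13C", s11 = 80, s22 = 20,
                      s33 = -70, alpha = 1.2, beta = 4.8, gamma = 1.4)
  pl <- plant_tensors(alm, sites)
  oa <- orientation_angles_13C(principal_frame(pl$records[[1]]$matrix),
                               plane_C(alm, 1))
  expect_equal(c(oa$alpha, oa$beta, oa$gamma), c(1.2, 4.8, 1.4),
               tolerance = 1e-6)
})

test_that("orientation angles are insensitive to eigenvector sign flips", {
  alm <- build_helix(helix_spec())
  sites <- data.frame(resno = 5, nucleus = "15N", s11 = 155, s22 = 140,
                      s33 = 20, alpha = 4.3, beta = 13.1, gamma = 31.3)
  M <- plant_tensors(alm, sites)$records[[1]]$matrix
  fr <- principal_frame(M)
  pl <- plane_N(alm, 5)
  ref <- orientation_angles_15N(fr, pl)
  for (signs in list(c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(-1, -1, -1))) {
    fr2 <- fr
    fr2$vectors <- fr$vectors %*% diag(signs)
    oa <- orientation_angles_15N(fr2, pl)
    expect_equal(c(oa$alpha, oa$beta, oa$gamma),
                 c(ref$alpha, ref$beta, ref$gamma), tolerance = 1e-9)
  }
})

test_that("angles are invariant when structure and tensor rotate together", {
  alm <- build_helix(helix_spec())
  sites <- data.frame(resno = 8, nucleus = "15N", s11 = 155, s22 = 140,
                      s33 = 20, alpha = 4.2, beta = 12.9, gamma = 51.5)
  M <- plant_tensors(alm, sites)$records[[1]]$matrix
  for (seed in 1:3) {
    R <- seeded_rotation(seed + 55)
    mt <- transform_model(alm, R, tr = c(3, -2, 8))
    Mt <- R %*% M %*% t(R)
    oa <- orientation_angles_15N(principal_frame(Mt), plane_N(mt, 8))
    expect_equal(c(oa$alpha, oa$beta, oa$gamma), c(4.2, 12.9, 51.5),
                 tolerance = 1e-6)
  }
})

test_that("carbonyl tensors near the canonical orientation have all small angles", {
  # all three angles small simultaneously iff xi2 ~ C=O and xi1 ~ normal
  alm <- build_helix(helix_spec())
  sites <- data.frame(resno = 6, nucleus = "13C", s11 = 80, s22 = 20,
                      s33 = -70, alpha = 0.4, beta = 1.1, gamma = 0.8)
  M <- plant_tensors(alm, sites)$records[[1]]$matrix
  fr <- principal_frame(M)
  pl <- plane_C(alm, 6)
  expect_lt(helixnmr:::axis_angle(fr$vectors[, 2], pl$in_plane_bond), 1.5)
  expect_lt(helixnmr:::axis_angle(fr$vectors[, 1], pl$normal), 1.5)

  # conversely, a tilted frame cannot have all angles small
  sites2 <- within(sites, gamma <- 40)
  M2 <- plant_tensors(alm, sites2)$records[[1]]$matrix
  oa2 <- orientation_angles_13C(principal_frame(M2), pl)
  expect_gt(max(oa2$alpha, oa2$beta, oa2$gamma), 10)
})
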