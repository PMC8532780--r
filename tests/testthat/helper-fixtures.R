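# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

ala_helix <- function(n = 12, phi = -57, psi = -47, cap = FALSE, ...) {
  build_helix(helix_spec(rep("ALA", n), phi = phi, psi = psi, cap = cap,
                         ...))
}

# analytic helix point set: radius r about the z axis, rise d per point,
# twist omega degrees per point
parametric_helix_points <- function(n = 12, r = 2.3, d = 1.5,
                                    omega = 100) {
  t <- seq_len(n) - 1
  cbind(r * cos(helixnmr:::deg2rad(omega * t)),
        r * sin(helixnmr:::deg2rad(omega * t)),
        d * t)
}

# apply a rigid motion (rotation R, translation tr) to a structure_model
transform_model <- function(model, R, tr = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  model$atoms[c("x", "y", "z")] <- sweep(xyz, 2, -tr)
  model
}

seeded_rotation <- function(seed) {
  set.seed(seed)
  helixnmr:::random_rotation()
}

# one planted 15N site on a model, returning recovered-vs-planted angles
recover_15N <- function(model, resno, angles, noise = 0, seed = 1) {
  sites <- data.frame(resno = resno, nucleus = "15N",
                      s11 = 155, s22 = 140, s33 = 20,
                      alpha = angles[1], beta = angles[2],
                      gamma = angles[3])
  pl <- plant_tensors(model, sites, tensor_noise_sd = noise, seed = seed)
  pf <- principal_frame(pl$records[[1]]$matrix)
  oa <- orientation_angles_15N(pf, plane_N(model, resno))
  c(oa$alpha, oa$beta, oa$gamma)
}
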