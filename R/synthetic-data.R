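#' Specification of an ideal helical peptide
#'
#' Defines the ground truth for a generated helix: sequence, backbone
#' dihedrals (defaults phi = -57, psi = -47 degrees, the ideal
#' right-handed alpha-helix with about 1.5 Angstrom rise and 3.6 residues,
#' i.e. ~100 degrees, per turn), optional N-terminal acetyl cap (residue
#' index 0), coordinate noise and seed.
#'
#' @param sequence residue codes; default the 20-residue alamethicin E18
#'   sequence ([alm_e18_sequence()]).
#' @param phi,psi backbone dihedrals in degrees (scalar or per-residue).
#' @param rise,residues_per_turn nominal helix parameters implied by the
#'   default dihedrals, recorded for reference; geometry is built from the
#'   dihedrals, not from these.
#' @param cap include an acetyl cap as residue 0 (supplies the carbonyl
#'   that defines phi of residue 1).
#' @param coordinate_noise_sd Gaussian noise on coordinates (Angstrom).
#' @param seed RNG seed used when noise is drawn.
#' @return object of class `helix_spec`.
#' @export
helix_spec <- function(sequence = alm_e18_sequence(), phi = -57, psi = -47,
                       rise = 1.5, residues_per_turn = 3.6, cap = TRUE,
                       coordinate_noise_sd = 0, seed = 1L) {
  if (length(sequence) < 2) stop("sequence must have at least 2 residues")
  if (coordinate_noise_sd < 0) stop("coordinate_noise_sd must be >= 0")
  sequence <- toupper(sequence)
  known <- c(aa3_codes(), "AIB", "PHL")
  unknown <- setdiff(sequence, known)
  if (length(unknown) > 0)
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  n <- length(sequence)
  structure(list(sequence = sequence, phi = rep_len(phi, n),
                 psi = rep_len(psi, n), rise = rise,
                 residues_per_turn = residues_per_turn, cap = cap,
                 coordinate_noise_sd = coordinate_noise_sd,
                 seed = as.integer(seed)),
            class = "helix_spec")
}

# standard backbone internal coordinates (Angstrom / degrees)
.bb <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.01,
  b_CACB = 1.521, a_CNCA = 121.7, a_NCAC = 111.2, a_CACN = 116.2,
  a_NCO = 123.0, a_CACO = 120.5, omega = 180)

#' Build an ideal helical peptide structure
#'
#' Constructs backbone coordinates (N, H, CA, C', O', and a CB stub where
#' applicable) from internal coordinates with standard bond lengths and
#' angles, realizing the spec's phi/psi exactly. Prolines are built
#' without the amide H; a phenylalaninol terminus is built without the
#' carbonyl; an acetyl cap (residue 0: CA methyl, C', O') is added when
#' requested. Optional Gaussian coordinate noise is seeded and
#' reproducible.
#'
#' @param spec a [helix_spec] (or arguments forwarded to one).
#' @param ... forwarded to [helix_spec()] when `spec` is missing.
#' @return a [structure_model]; the spec is attached as attribute
#'   `"helix_spec"`.
#' @export
build_helix <- function(spec = helix_spec(...), ...) {
  if (!inherits(spec, "helix_spec")) stop("spec must be a helix_spec")
  seqs <- spec$sequence
  n <- length(seqs)
  g <- .bb
  # backbone N/CA/C chain via NeRF
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_NCA, 0, 0)
  ang <- deg2rad(g$a_NCAC)
  C[[1]] <- CA[[1]] + g$b_CAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]],
                             g$b_CN, g$a_CACN, spec$psi[i])
    CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]],
                              g$b_NCA, g$a_CNCA, g$omega)
    C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]],
                             g$b_CAC, g$a_NCAC, spec$phi[i + 1])
  }
  # carbonyl O: anti to the following N about the CA-C bond
  # (torsion N-CA-C-O = psi + 180 since torsion N-CA-C-N(next) = psi)
  O <- vector("list", n)
  for (i in seq_len(n)) {
    O[[i]] <- nerf_place(N[[i]], CA[[i]], C[[i]], g$b_CO, g$a_CACO,
                         spec$psi[i] + 180)
  }
  rows <- list()
  add <- function(element, name, resid, resno, p)
    rows[[length(rows) + 1]] <<- data.frame(
      element = element, name = name, resid = resid, resno = resno,
      chain = "A", x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)

  if (spec$cap) {
    # acetyl cap: C' placed so that phi(1) is defined; methyl CA trans
    c0 <- nerf_place(C[[1]], CA[[1]], N[[1]], g$b_CN, g$a_CNCA, spec$phi[1])
    ca0 <- nerf_place(CA[[1]], N[[1]], c0, 1.507, g$a_CACN, g$omega)
    o0 <- nerf_place(CA[[1]], N[[1]], c0, g$b_CO, g$a_NCO, 180)
    add("C", "CA", "ACE", 0L, ca0)
    add("C", "C", "ACE", 0L, c0)
    add("O", "O", "ACE", 0L, o0)
  }
  for (i in seq_len(n)) {
    resid <- seqs[i]
    is_pro <- resid == "PRO"
    is_phl <- resid == "PHL"
    add("N", "N", resid, i, N[[i]])
    if (!is_pro && (i > 1 || spec$cap)) {
      c_prev <- if (i > 1) C[[i - 1]]
        else atom_from_rows(rows, 0L, "C")
      add("H", "H", resid, i, amide_h_position(c_prev, N[[i]], CA[[i]]))
    }
    add("C", "CA", resid, i, CA[[i]])
    if (resid != "GLY") {
      bis <- -(vunit(N[[i]] - CA[[i]]) + vunit(C[[i]] - CA[[i]]))
      side <- vcross(vunit(C[[i]] - CA[[i]]), vunit(N[[i]] - CA[[i]]))
      add("C", "CB", resid, i, CA[[i]] + g$b_CACB * vunit(bis + side))
    }
    if (!is_phl) {
      add("C", "C", resid, i, C[[i]])
      add("O", "O", resid, i, O[[i]])
    } else {
      # amino alcohol: hydroxymethyl carbon, no carbonyl oxygen
      add("C", "C", resid, i, C[[i]])
    }
  }
  atoms <- do.call(rbind, rows)
  if (spec$coordinate_noise_sd > 0) {
    set.seed(spec$seed)
    atoms[c("x", "y", "z")] <- atoms[c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(atoms), sd = spec$coordinate_noise_sd),
             ncol = 3)
  }
  model <- structure_model(atoms)
  attr(model, "helix_spec") <- spec
  model
}

atom_from_rows <- function(rows, resno, name) {
  for (r in rows) if (r$resno == resno && r$name == name)
    return(as.numeric(r[c("x", "y", "z")]))
  NULL
}

#' Plant shielding tensors with prescribed peptide-plane orientations
#'
#' For each requested site, constructs a symmetric 3x3 shielding tensor
#' whose eigenvectors realize the prescribed (alpha, beta, gamma) angles
#' relative to the site's peptide plane exactly, with prescribed principal
#' values sigma11 >= sigma22 >= sigma33, and optional symmetric Gaussian
#' noise added afterwards. The construction places the elevated
#' eigenvector (xi3 for amide 15N, xi2 for carbonyl 13C) at out-of-plane
#' elevation alpha and at angle beta from the in-plane bond, then the
#' normal-referenced eigenvector (xi2 for 15N, xi1 for 13C) at angle gamma
#' from the plane normal within the perpendicular subspace; this requires
#' beta >= alpha and gamma >= alpha (otherwise the three angles cannot be
#' realized by an orthonormal frame and an error is raised). The returned
#' ground truth is exact pre-noise.
#'
#' @param model a [structure_model] with defined peptide planes at the
#'   target sites (e.g. from [build_helix()]).
#' @param sites data.frame with columns `resno`, `nucleus` (`"15N"` /
#'   `"13C"`), `s11`, `s22`, `s33` (shielding principal values, ppm,
#'   descending) and `alpha`, `beta`, `gamma` (degrees in [0, 90]).
#' @param tensor_noise_sd sd of symmetric Gaussian noise added to the
#'   tensor (ppm).
#' @param seed RNG seed for the noise.
#' @param chain chain identifier.
#' @return list with `records` (tensor records as in [read_magres()]) and
#'   `truth` (the input data.frame, the exact planted ground truth).
#' @export
plant_tensors <- function(model, sites, tensor_noise_sd = 0, seed = 1L,
                          chain = "A") {
  need <- c("resno", "nucleus", "s11", "s22", "s33", "alpha", "beta",
            "gamma")
  if (!all(need %in% names(sites)))
    stop("sites must have columns ", paste(need, collapse = ", "))
  if (any(sites$s11 < sites$s22 | sites$s22 < sites$s33))
    stop("shielding principal values must satisfy s11 >= s22 >= s33")
  if (any(c(sites$alpha, sites$beta, sites$gamma) < 0) ||
      any(c(sites$alpha, sites$beta, sites$gamma) > 90))
    stop("target angles must lie in [0, 90] degrees")
  set.seed(seed)
  records <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    plane <- if (s$nucleus == "15N") plane_N(model, s$resno, chain)
             else plane_C(model, s$resno, chain)
    if (!plane$defined)
      stop("peptide plane undefined for residue ", s$resno, " (",
           plane$reason, ")")
    V <- planted_eigenvectors(plane, s$alpha, s$beta, s$gamma, s$nucleus)
    M <- V %*% diag(c(s$s11, s$s22, s$s33)) %*% t(V)
    if (tensor_noise_sd > 0) {
      E <- matrix(stats::rnorm(9, sd = tensor_noise_sd), 3, 3)
      M <- M + (E + t(E)) / 2
    }
    name <- if (s$nucleus == "15N") "N" else "C"
    records[[i]] <- list(site_key = list(chain = chain, resno = s$resno,
                                         name = name), matrix = M)
  }
  list(records = records, truth = sites)
}

# Construct eigenvector columns (xi1, xi2, xi3) realizing the plane-frame
# angles exactly. u: in-plane bond, nrm: plane normal.
planted_eigenvectors <- function(plane, alpha, beta, gamma, nucleus) {
  u <- plane$in_plane_bond
  nrm <- plane$normal
  w <- vcross(nrm, u)
  ca <- cos(deg2rad(alpha))
  if (cos(deg2rad(beta)) > ca + 1e-12 || cos(deg2rad(gamma)) > ca + 1e-12)
    stop("infeasible angle combination: beta and gamma must be >= alpha ",
         "for an orthonormal eigenframe")
  theta <- acos(min(1, cos(deg2rad(beta)) / ca))
  elev <- ca * (cos(theta) * u + sin(theta) * w) + sin(deg2rad(alpha)) * nrm
  n_perp <- nrm - sum(nrm * elev) * elev
  e1 <- vunit(n_perp)
  e2 <- vcross(elev, e1)
  t_ang <- acos(min(1, cos(deg2rad(gamma)) / ca))
  ref <- cos(t_ang) * e1 + sin(t_ang) * e2
  if (nucleus == "15N") {
    xi3 <- elev; xi2 <- ref; xi1 <- vcross(xi2, xi3)
  } else {
    xi2 <- elev; xi1 <- ref; xi3 <- vcross(xi1, xi2)
  }
  cbind(xi1, xi2, xi3)
}

#' Write a synthetic fixture bundle
#'
#' Writes a generated structure (PDB), planted shielding tensors (MAGRES)
#' and the exact ground truth (CSV) to a directory, all readable back by
#' the package's own readers.
#'
#' @param model a [structure_model].
#' @param planted a [plant_tensors()] result (or `NULL` for a
#'   structure-only bundle).
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(model, planted = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(structure = file.path(dir, "structure.pdb"))
  write_structure(model, paths["structure"], "pdb")
  if (!is.null(planted)) {
    paths["magres"] <- file.path(dir, "tensors.magres")
    write_magres(planted$records, model, paths["magres"])
    paths["truth"] <- file.path(dir, "truth.csv")
    utils::write.csv(planted$truth, paths["truth"], row.names = FALSE)
  }
  invisible(paths)
}
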