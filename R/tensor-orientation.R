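#' Peptide planes for amide and carbonyl tensor analysis
#'
#' The local orientation of a shift tensor is referred to the peptide
#' plane of its site. For an amide nitrogen the plane P_N is defined by
#' the {N, H, CA} coordinates with the in-plane bond N->H; for a carbonyl
#' carbon the plane P_C is defined by {C', O', CA} with the in-plane bond
#' C'->O'. The normal sign is chosen toward the +z hemisphere of the
#' molecular frame; all derived angles are sign-insensitive.
#'
#' `plane_N` is undefined for prolines (no amide H) and returns an object
#' flagged `defined = FALSE`; `plane_C` is undefined for residues without
#' a carbonyl (e.g. a C-terminal amino alcohol).
#'
#' @param residue one entry of the internal per-residue backbone list, or
#'   a [structure_model] together with `resno` (and optionally `chain`).
#' @param resno residue index when `residue` is a model.
#' @param chain chain identifier when `residue` is a model.
#' @return object of class `peptide_plane`: `origin`, `normal`,
#'   `in_plane_bond` (unit vectors), `defined`, `reason`.
#' @export
plane_N <- function(residue, resno = NULL, chain = NULL) {
  r <- resolve_residue(residue, resno, chain)
  if (r$class == "Pro")
    return(undefined_plane("proline has no amide hydrogen"))
  if (is.null(r$N) || is.null(r$H) || is.null(r$CA))
    return(undefined_plane("missing N, H or CA atom"))
  make_plane(origin = r$N, bond = r$H - r$N, ref = r$CA - r$N)
}

#' @rdname plane_N
#' @export
plane_C <- function(residue, resno = NULL, chain = NULL) {
  r <- resolve_residue(residue, resno, chain)
  if (is.null(r$C) || is.null(r$O) || is.null(r$CA))
    return(undefined_plane("missing C', O' or CA atom"))
  make_plane(origin = r$C, bond = r$O - r$C, ref = r$CA - r$C)
}

resolve_residue <- function(residue, resno, chain) {
  if (inherits(residue, "structure_model")) {
    if (is.null(resno)) stop("resno required when passing a structure_model")
    res <- residue_frames(residue, chain)
    r <- res[[as.character(resno)]]
    if (is.null(r)) stop("no residue with index ", resno)
    r
  } else residue
}

make_plane <- function(origin, bond, ref) {
  if (vnorm(vcross(bond, ref)) < 1e-8 * vnorm(bond) * vnorm(ref))
    return(undefined_plane("defining atoms are collinear"))
  normal <- vunit(vcross(vunit(bond), vunit(ref)))
  if (normal[3] < 0) normal <- -normal
  structure(list(origin = origin, normal = normal,
                 in_plane_bond = vunit(bond), defined = TRUE, reason = NULL),
            class = "peptide_plane")
}

undefined_plane <- function(reason) {
  structure(list(origin = NULL, normal = NULL, in_plane_bond = NULL,
                 defined = FALSE, reason = reason),
            class = "peptide_plane")
}

#' @export
print.peptide_plane <- function(x, ...) {
  if (!x$defined) cat("peptide_plane: undefined (", x$reason, ")\n", sep = "")
  else cat(sprintf("peptide_plane: normal (%.4f, %.4f, %.4f)\n",
                   x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Orientation angles of a shift tensor in its peptide plane
#'
#' For an amide 15N tensor: alpha is the out-of-plane elevation of the
#' xi3 eigenvector (the departure of the delta33 direction from the
#' peptide plane), beta the angle between xi3 and the N-H bond, and gamma
#' the angle between xi2 and the plane normal. For a carbonyl 13C tensor
#' the roles shift down one index: alpha is the elevation of xi2, beta the
#' angle between xi2 and the C'=O' bond, gamma the angle between xi1 and
#' the plane normal. Eigenvectors are axes (sign-free), so all three
#' angles are reported as acute values in [0, 90] degrees.
#'
#' Degenerate principal frames are refused: their eigenvector directions
#' carry no information.
#'
#' @param frame a [principal_frame].
#' @param plane a defined [plane_N()] / [plane_C()] result.
#' @param site_key optional identifier attached to the result.
#' @return object of class `orientation_angles` with `alpha`, `beta`,
#'   `gamma` (degrees), `site_key`.
#' @export
orientation_angles_15N <- function(frame, plane, site_key = NULL) {
  check_orientation_inputs(frame, plane)
  xi2 <- frame$vectors[, 2]; xi3 <- frame$vectors[, 3]
  orientation_angles(
    alpha = 90 - axis_angle(xi3, plane$normal),
    beta = axis_angle(xi3, plane$in_plane_bond),
    gamma = axis_angle(xi2, plane$normal),
    site_key = site_key)
}

#' @rdname orientation_angles_15N
#' @export
orientation_angles_13C <- function(frame, plane, site_key = NULL) {
  check_orientation_inputs(frame, plane)
  xi1 <- frame$vectors[, 1]; xi2 <- frame$vectors[, 2]
  orientation_angles(
    alpha = 90 - axis_angle(xi2, plane$normal),
    beta = axis_angle(xi2, plane$in_plane_bond),
    gamma = axis_angle(xi1, plane$normal),
    site_key = site_key)
}

check_orientation_inputs <- function(frame, plane) {
  if (!inherits(frame, "principal_frame")) stop("frame must be a principal_frame")
  if (frame$degenerate)
    stop("degenerate principal frame: eigenvector directions are undefined")
  if (!inherits(plane, "peptide_plane") || !plane$defined)
    stop("peptide plane is undefined",
         if (inherits(plane, "peptide_plane") && !is.null(plane$reason))
           paste0(" (", plane$reason, ")") else "")
}

orientation_angles <- function(alpha, beta, gamma, site_key = NULL) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 site_key = site_key),
            class = "orientation_angles")
}

#' @export
print.orientation_angles <- function(x, ...) {
  cat(sprintf("orientation_angles: alpha %.1f, beta %.1f, gamma %.1f deg\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}
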