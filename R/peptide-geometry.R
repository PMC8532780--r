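#' Signed torsion angle of four points
#'
#' Standard IUPAC dihedral: looking down the p2->p3 bond, the angle from
#' the p1 side to the p4 side, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 Cartesian points (Angstrom).
#' @return degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("consecutive points coincide; torsion undefined")
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("collinear points; torsion undefined")
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Split a model into per-residue lists of backbone atom coordinates.
# Returns a list keyed in residue order with entries:
#   resno, resid, class, N, H, CA, C, O (coordinates or NULL)
residue_frames <- function(model, chain = NULL) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms in chain ", chain)
  out <- list()
  for (rn in sort(unique(a$resno))) {
    sub <- a[a$resno == rn, , drop = FALSE]
    getter <- function(nm) {
      i <- which(sub$name == nm)
      if (length(i) == 0) NULL else as.numeric(sub[i[1], c("x", "y", "z")])
    }
    name <- sub$resid[1]
    out[[length(out) + 1]] <- list(
      resno = rn, resid = name,
      class = classify_residue(name),
      N = getter("N"), H = getter("H"), CA = getter("CA"),
      C = getter("C"), O = getter("O"))
  }
  names(out) <- vapply(out, function(r) as.character(r$resno), character(1))
  out
}

#' Ramachandran angles along the backbone
#'
#' phi(i) is the C'(i-1)-N(i)-CA(i)-C'(i) torsion and psi(i) the
#' N(i)-CA(i)-C'(i)-N(i+1) torsion. Angles are `NA` where the flanking
#' atoms are missing: phi of an uncapped first residue, psi of a
#' C-terminal residue without a following nitrogen (e.g. an amino-alcohol
#' terminus, which also lacks the carbonyl). An N-terminal acetyl cap
#' (residue index 0) supplies the C' needed for phi of residue 1 and is
#' itself excluded from the table.
#'
#' @param model a [structure_model].
#' @param chain chain to analyze (default: first chain).
#' @return data.frame with `resno`, `resid`, `phi`, `psi`, `phi_psi_sum`
#'   (signed sum phi + psi).
#' @export
ramachandran <- function(model, chain = NULL) {
  res <- residue_frames(model, chain)
  keep <- vapply(res, function(r) r$class != "cap", logical(1))
  idx <- which(keep)
  out <- data.frame(resno = integer(0), resid = character(0),
                    phi = numeric(0), psi = numeric(0),
                    phi_psi_sum = numeric(0))
  for (k in idx) {
    r <- res[[k]]
    if (is.null(r$CA)) {
      warning("residue ", r$resno, " (", r$resid, ") has no CA; skipped")
      next
    }
    prev <- if (k > 1) res[[k - 1]] else NULL
    nxt <- if (k < length(res)) res[[k + 1]] else NULL
    phi <- NA_real_; psi <- NA_real_
    if (!is.null(prev) && !is.null(prev$C) && !is.null(r$N) && !is.null(r$C))
      phi <- dihedral(prev$C, r$N, r$CA, r$C)
    if (!is.null(nxt) && !is.null(nxt$N) && !is.null(r$N) && !is.null(r$C))
      psi <- dihedral(r$N, r$CA, r$C, nxt$N)
    out <- rbind(out, data.frame(
      resno = r$resno, resid = r$resid, phi = phi, psi = psi,
      phi_psi_sum = phi + psi))
  }
  out
}

#' Reconstruct missing amide hydrogens
#'
#' Places H in the C'(i-1)-N-CA plane, 1.01 Angstrom from N along the
#' external bisector of the C'(i-1)-N-CA angle. XRD-derived coordinate
#' files often lack hydrogens; this standard planar-amide construction
#' restores them for hydrogen-bond detection and peptide-plane definition.
#' Prolines and residues without a preceding carbonyl are left untouched.
#'
#' @param model a [structure_model].
#' @return a [structure_model] with H atoms added where reconstructable.
#' @export
add_amide_hydrogens <- function(model) {
  a <- model$atoms
  for (ch in unique(a$chain)) {
    res <- residue_frames(model, ch)
    for (k in seq_along(res)) {
      r <- res[[k]]
      if (!is.null(r$H) || is.null(r$N) || is.null(r$CA)) next
      if (r$class %in% c("Pro", "cap")) next
      if (k == 1) next
      prev <- res[[k - 1]]
      if (is.null(prev$C)) next
      h <- amide_h_position(prev$C, r$N, r$CA)
      a <- rbind(a, data.frame(element = "H", name = "H", resid = r$resid,
                               resno = r$resno, chain = ch,
                               x = h[1], y = h[2], z = h[3]))
    }
  }
  ord <- order(match(a$chain, unique(a$chain)), a$resno)
  structure_model(a[ord, , drop = FALSE], cell = model$cell,
                  space_group = model$space_group)
}

amide_h_position <- function(c_prev, n, ca) {
  n + 1.01 * vunit(-(vunit(c_prev - n) + vunit(ca - n)))
}

#' Detect backbone hydrogen bonds
#'
#' Assigns to each amide N-H donor at most one backbone carbonyl acceptor:
#' the closest H...O contact satisfying the geometric criteria. Spans are
#' reported from the acceptor's perspective (span = donor - acceptor, so an
#' alpha-helical bond i -> i+4 has span 4). Default criteria: H...O <= 2.5
#' Angstrom and N-H...O angle >= 120 degrees.
#'
#' @param model a [structure_model].
#' @param max_dist maximum H...O distance (Angstrom).
#' @param min_angle minimum N-H...O angle (degrees).
#' @param reconstruct_h reconstruct missing amide hydrogens with
#'   [add_amide_hydrogens()] before detection.
#' @param chain chain to analyze.
#' @return data.frame with `donor`, `acceptor` (residue indices),
#'   `span`, `dist` (Angstrom), `angle` (degrees).
#' @export
detect_hbonds <- function(model, max_dist = 2.5, min_angle = 120,
                          reconstruct_h = TRUE, chain = NULL) {
  res <- residue_frames(model, chain)
  has_h <- any(vapply(res, function(r) !is.null(r$H), logical(1)))
  if (!has_h) {
    if (!reconstruct_h)
      stop("no amide hydrogens present and reconstruction is disabled")
    model <- add_amide_hydrogens(model)
    res <- residue_frames(model, chain)
  }
  out <- data.frame(donor = integer(0), acceptor = integer(0),
                    span = integer(0), dist = numeric(0), angle = numeric(0))
  for (d in res) {
    if (is.null(d$H) || is.null(d$N)) next
    best <- NULL
    for (acc in res) {
      span <- d$resno - acc$resno
      if (span < 2) next
      if (is.null(acc$C) || is.null(acc$O)) next
      dist <- vnorm(d$H - acc$O)
      if (dist > max_dist) next
      ang <- vangle(d$N - d$H, acc$O - d$H)
      if (ang < min_angle) next
      if (is.null(best) || dist < best$dist)
        best <- data.frame(donor = d$resno, acceptor = acc$resno,
                           span = span, dist = dist, angle = ang)
    }
    if (!is.null(best)) out <- rbind(out, best)
  }
  out
}

#' Fit a helix axis to C-alpha positions
#'
#' Least-squares cylinder fit: the axis direction, a point on the axis and
#' the radius are chosen to minimize the spread of point-to-axis distances.
#' The direction is initialized from the singular directions of the
#' centered point cloud and refined by Nelder-Mead over the two direction
#' angles, with the in-plane circle center solved in closed form (Kasa
#' algebraic fit) at each step. The axis sign points from the N- to the
#' C-terminal end of the point sequence.
#'
#' @param ca_coords n x 3 matrix of ordered C-alpha positions (n >= 4), or
#'   a [structure_model] from which C-alpha positions are taken.
#' @param window optional residue-index range `c(first, last)` when
#'   `ca_coords` is a model.
#' @param chain chain to use when `ca_coords` is a model.
#' @return object of class `helix_frame` with `axis` (unit vector),
#'   `anchor` (point on axis), `radius` (Angstrom), `rise` (mean axial
#'   spacing, Angstrom), `rss` (residual sum of squares).
#' @export
fit_helix_axis <- function(ca_coords, window = NULL, chain = NULL) {
  if (inherits(ca_coords, "structure_model")) {
    res <- residue_frames(ca_coords, chain)
    res <- Filter(function(r) !is.null(r$CA) && r$class != "cap", res)
    if (!is.null(window))
      res <- Filter(function(r) r$resno >= window[1] && r$resno <= window[2],
                    res)
    ca_coords <- do.call(rbind, lapply(res, function(r) r$CA))
  }
  p <- as.matrix(ca_coords)
  n <- nrow(p)
  if (n < 4) stop("at least 4 C-alpha points are required")
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  sv <- svd(pc)
  if (sv$d[2] < 1e-8) stop("degenerate fit: points are collinear")

  objective <- function(ang) {
    axis <- c(cos(ang[1]) * sin(ang[2]), sin(ang[1]) * sin(ang[2]),
              cos(ang[2]))
    circle_rss(pc, axis)$rss
  }
  best <- NULL
  for (k in 1:3) {
    a0 <- sv$v[, k]
    ang0 <- c(atan2(a0[2], a0[1]), acos(max(-1, min(1, a0[3]))))
    if (!is.finite(objective(ang0))) next   # start collapses the projection
    opt <- stats::optim(ang0, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("degenerate fit: no viable axis initialization")
  ang <- best$par
  axis <- c(cos(ang[1]) * sin(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[2]))
  fit <- circle_rss(pc, axis)
  # orient N -> C
  if (sum(axis * (p[n, ] - p[1, ])) < 0) axis <- -axis
  t_axial <- pc %*% axis
  rise <- if (n > 1) mean(diff(as.numeric(t_axial))) else NA_real_
  structure(list(axis = vunit(axis), anchor = ctr + fit$center,
                 radius = fit$radius, rise = abs(rise), rss = best$value),
            class = "helix_frame")
}

# For a candidate axis direction through the centroid: project points onto
# the plane perpendicular to the axis, fit a circle center (linear Kasa
# fit), return the center (3D offset from centroid) and radius and the
# residual sum of squares of (distance - radius).
circle_rss <- function(pc, axis) {
  e1 <- vunit(if (abs(axis[1]) < 0.9) vcross(axis, c(1, 0, 0))
              else vcross(axis, c(0, 1, 0)))
  e2 <- vcross(axis, e1)
  u <- pc %*% e1
  v <- pc %*% e2
  # projections that collapse onto a line admit no circle fit: reject the
  # axis (degenerate "infinite radius" solutions otherwise win spuriously)
  sv2 <- svd(cbind(u - mean(u), v - mean(v)), nu = 0, nv = 0)$d
  if (sv2[2] < 1e-6 * max(sv2[1], 1))
    return(list(center = c(0, 0, 0), radius = Inf, rss = Inf))
  # Kasa: minimize sum((u-a)^2 + (v-b)^2 - r^2)^2, linear in (a, b, c)
  A <- cbind(2 * u, 2 * v, 1)
  b <- u^2 + v^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(list(center = c(0, 0, 0), radius = 0, rss = Inf))
  a <- sol[1]; bb <- sol[2]
  r <- sqrt(max(0, sol[3] + a^2 + bb^2))
  d <- sqrt((u - a)^2 + (v - bb)^2)
  list(center = as.numeric(a * e1 + bb * e2),
       radius = mean(d), rss = sum((d - mean(d))^2))
}

#' @export
print.helix_frame <- function(x, ...) {
  cat(sprintf("helix_frame: axis (%.4f, %.4f, %.4f), radius %.3f A, rise %.3f A\n",
              x$axis[1], x$axis[2], x$axis[3], x$radius, x$rise))
  invisible(x)
}

#' Per-residue azimuthal rotation about the helix axis
#'
#' The azimuth rho of a residue is the angle, about the helix axis and in
#' the right-handed sense, between the axis-perpendicular component of its
#' site vector and that of the reference residue (rho = 0 at the
#' reference). The default site vector is the carbonyl bond C'->O', whose
#' orientation governs the carbonyl shift-anisotropy oscillation; CA->C'
#' is available as an alternative. On an ideal alpha-helix successive
#' residues are spaced by about 100 degrees.
#'
#' @param model a [structure_model].
#' @param frame a [fit_helix_axis()] result.
#' @param site_vector `"CO"` (C'->O') or `"CAC"` (CA->C').
#' @param reference residue index defining rho = 0 (default: first residue
#'   with a defined site vector).
#' @param chain chain to analyze.
#' @return named numeric vector of rho in [0, 360) degrees per residue
#'   index; `NA` (with a warning) where the site vector is undefined or
#'   parallel to the axis.
#' @export
residue_azimuth <- function(model, frame, site_vector = c("CO", "CAC"),
                            reference = NULL, chain = NULL) {
  site_vector <- match.arg(site_vector)
  res <- residue_frames(model, chain)
  res <- Filter(function(r) r$class != "cap", res)
  axis <- frame$axis
  perp <- function(r) {
    v <- switch(site_vector,
                CO = if (!is.null(r$C) && !is.null(r$O)) r$O - r$C else NULL,
                CAC = if (!is.null(r$CA) && !is.null(r$C)) r$C - r$CA else NULL)
    if (is.null(v)) return(NULL)
    vp <- v - sum(v * axis) * axis
    if (vnorm(vp) < 1e-6 * vnorm(v)) return(NULL)
    vunit(vp)
  }
  perps <- lapply(res, perp)
  resnos <- vapply(res, function(r) r$resno, integer(1))
  defined <- !vapply(perps, is.null, logical(1))
  if (!any(defined)) stop("no residue has a defined site vector")
  if (is.null(reference)) reference <- resnos[which(defined)[1]]
  iref <- match(reference, resnos)
  if (is.na(iref) || !defined[iref])
    stop("reference residue ", reference, " has no defined site vector")
  vref <- perps[[iref]]
  rho <- rep(NA_real_, length(res))
  for (i in seq_along(res)) {
    if (!defined[i]) next
    v <- perps[[i]]
    ang <- rad2deg(atan2(sum(vcross(vref, v) * axis), sum(vref * v)))
    rho[i] <- ang %% 360
  }
  if (any(!defined))
    warning("site vector undefined for residue(s): ",
            paste(resnos[!defined], collapse = ", "))
  stats::setNames(rho, resnos)
}

#' Helix tilt relative to the membrane normal
#'
#' @param frame a [fit_helix_axis()] result (or a unit axis vector).
#' @param n membrane normal (unit vector).
#' @return tau, the acute angle between axis and normal, in [0, 90] degrees.
#' @export
helix_tilt <- function(frame, n) {
  axis <- if (inherits(frame, "helix_frame")) frame$axis else frame
  if (vnorm(axis) < 1e-12 || vnorm(n) < 1e-12)
    stop("zero vector supplied")
  axis_angle(axis, n)
}

#' Acute angle between a direction and the helix axis
#'
#' Used, e.g., to verify that the principal delta33 direction of an amide
#' nitrogen is nearly parallel to the helix axis, the assumption behind
#' tilt extraction from the parallel shift component.
#'
#' @param v direction (unit vector).
#' @param frame a [fit_helix_axis()] result (or a unit axis vector).
#' @return degrees in [0, 90].
#' @export
angle_to_axis <- function(v, frame) {
  axis <- if (inherits(frame, "helix_frame")) frame$axis else frame
  axis_angle(v, axis)
}

#' Full helix parametrization
#'
#' Convenience wrapper: fits the axis, computes per-residue azimuths and
#' the tilt versus a membrane normal, and returns a completed
#' `helix_frame`.
#'
#' @inheritParams fit_helix_axis
#' @inheritParams residue_azimuth
#' @param normal membrane normal unit vector.
#' @return a `helix_frame` with `residue_azimuth` (named vector),
#'   `tilt` (degrees) and `reference_residue` added.
#' @export
parametrize_helix <- function(model, normal = c(0, 0, 1), window = NULL,
                              site_vector = "CO", reference = NULL,
                              chain = NULL) {
  frame <- fit_helix_axis(model, window = window, chain = chain)
  rho <- residue_azimuth(model, frame, site_vector = site_vector,
                         reference = reference, chain = chain)
  frame$residue_azimuth <- rho
  frame$tilt <- helix_tilt(frame, normal)
  frame$reference_residue <- if (is.null(reference))
    as.integer(names(rho)[which(!is.na(rho))[1]]) else reference
  frame
}
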