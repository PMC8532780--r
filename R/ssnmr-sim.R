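#' Parallel shift component of an oriented helical site
#'
#' For a peptide aligned in a planar membrane with the sample normal along
#' the magnetic field, the measured parallel component of an amide 15N
#' shift tensor depends on the helix tilt tau as
#' `delta_par = d11 sin^2(tau) + d33 cos^2(tau)`,
#' the axially-averaged specialization in which the delta33 direction is
#' taken parallel to the helix axis.
#'
#' @param d11,d33 principal shift values (ppm), `d11 <= d33` typically.
#' @param tau tilt angle(s), degrees in [0, 90].
#' @return delta_par in ppm (vectorized over `tau`).
#' @export
delta_parallel <- function(d11, d33, tau) {
  if (any(!is.finite(tau)) || any(tau < 0 | tau > 90))
    stop("tau must lie in [0, 90] degrees")
  t <- deg2rad(tau)
  d11 * sin(t)^2 + d33 * cos(t)^2
}

#' Extract the helix tilt from a measured parallel shift component
#'
#' Inverts the tilt dependence of the parallel shift component:
#' `tau = asin(sqrt((d33 - delta_par) / (d33 - d11)))`, principal branch in
#' [0, 90] degrees. The complementary oriented-sample degeneracy
#' tau <-> 180 - tau is not enumerated. A `delta_par` outside the closed
#' interval [min(d11, d33), max(d11, d33)] is unreachable for any tilt and
#' raises a domain error naming the violated bound.
#'
#' @param delta_par measured parallel component (ppm).
#' @param d11,d33 principal shift values of the site (ppm).
#' @return tau in degrees.
#' @export
invert_tilt <- function(delta_par, d11, d33) {
  if (d11 == d33) stop("indeterminate: d11 equals d33")
  lo <- min(d11, d33); hi <- max(d11, d33)
  if (delta_par > hi)
    stop(sprintf(paste0("delta_par = %.4g ppm exceeds the upper bound ",
                        "max(d11, d33) = %.4g ppm; no tilt reproduces it"),
                 delta_par, hi))
  if (delta_par < lo)
    stop(sprintf(paste0("delta_par = %.4g ppm is below the lower bound ",
                        "min(d11, d33) = %.4g ppm; no tilt reproduces it"),
                 delta_par, lo))
  s <- (d33 - delta_par) / (d33 - d11)
  rad2deg(asin(sqrt(max(0, min(1, s)))))
}

#' Total chemical-shift anisotropy of an oriented carbonyl site
#'
#' The total anisotropy `Ddelta = delta_par - delta_perp` of a carbonyl
#' 13C site in a tilted helix decomposes into the axially symmetric term
#' `d22 - (d11 + d33)/2` plus an orientation-dependent oscillation in the
#' azimuth rho:
#' `Ddelta = 3/2 sin^2(tau) (d11 cos^2(rho) + d33 sin^2(rho) - d22)
#'           + d22 - (d11 + d33)/2`,
#' valid under the assumption that the d22 direction is parallel to the
#' helix axis (the carbonyl d22 axis is nearly collinear with C'=O').
#'
#' @param d11,d22,d33 principal shift values sorted ascending (ppm).
#' @param rho azimuthal rotation angle(s), degrees.
#' @param tau tilt angle, degrees in [0, 90].
#' @return Ddelta in ppm (vectorized over `rho`).
#' @export
total_anisotropy <- function(d11, d22, d33, rho, tau) {
  if (is.unsorted(c(d11, d22, d33)))
    stop("principal values must be sorted ascending (d11 <= d22 <= d33)")
  if (!is.finite(tau) || tau < 0 || tau > 90)
    stop("tau must lie in [0, 90] degrees")
  r <- deg2rad(rho); t <- deg2rad(tau)
  3 / 2 * sin(t)^2 * (d11 * cos(r)^2 + d33 * sin(r)^2 - d22) +
    d22 - (d11 + d33) / 2
}

#' Tilt dependence of the parallel shift component for a set of sites
#'
#' Evaluates [delta_parallel()] on a tilt grid for each named (d11, d33)
#' pair, the per-site curves underlying tilt-extraction plots.
#'
#' @param shift_sets data.frame with columns `site`, `d11`, `d33`.
#' @param tau_grid strictly increasing tilt values, degrees in [0, 90].
#' @return object of class `scan_result`: data.frame `curves` with
#'   `site`, `tau`, `delta_par`.
#' @export
scan_tilt <- function(shift_sets, tau_grid) {
  if (length(tau_grid) == 0) stop("empty tilt grid")
  if (is.unsorted(tau_grid, strictly = TRUE))
    stop("tau_grid must be strictly increasing")
  need <- c("site", "d11", "d33")
  if (!all(need %in% names(shift_sets)))
    stop("shift_sets must have columns site, d11, d33")
  curves <- do.call(rbind, lapply(seq_len(nrow(shift_sets)), function(i) {
    data.frame(site = shift_sets$site[i], tau = tau_grid,
               delta_par = delta_parallel(shift_sets$d11[i],
                                          shift_sets$d33[i], tau_grid))
  }))
  structure(list(kind = "tilt", curves = curves), class = "scan_result")
}

#' Azimuthal oscillation of the total 13C anisotropy
#'
#' Models the oscillation of the carbonyl total shift anisotropy along a
#' helical segment at fixed tilt: a continuous curve from the
#' segment-average principal values over `rho_grid`, plus one discrete
#' point per site at its own azimuth computed from its own principal
#' values. Sites with undefined azimuth are skipped with a warning.
#'
#' @param sites data.frame with columns `residue`, `d11`, `d22`, `d33`,
#'   `rho` (degrees).
#' @param tau tilt angle, degrees.
#' @param rho_grid strictly increasing azimuth grid, degrees.
#' @return object of class `scan_result`: `curve` (`rho`, `delta`) and
#'   `points` (`residue`, `rho`, `delta`).
#' @export
scan_oscillation <- function(sites, tau, rho_grid = seq(0, 360, by = 1)) {
  need <- c("residue", "d11", "d22", "d33", "rho")
  if (!all(need %in% names(sites)))
    stop("sites must have columns residue, d11, d22, d33, rho")
  if (length(rho_grid) == 0) stop("empty azimuth grid")
  if (is.unsorted(rho_grid, strictly = TRUE))
    stop("rho_grid must be strictly increasing")
  drop <- !is.finite(sites$rho)
  if (any(drop)) {
    warning("site(s) with undefined azimuth skipped: ",
            paste(sites$residue[drop], collapse = ", "))
    sites <- sites[!drop, , drop = FALSE]
  }
  if (nrow(sites) == 0) stop("no site has a defined azimuth")
  curve <- data.frame(
    rho = rho_grid,
    delta = total_anisotropy(mean(sites$d11), mean(sites$d22),
                             mean(sites$d33), rho_grid, tau))
  points <- data.frame(
    residue = sites$residue, rho = sites$rho,
    delta = vapply(seq_len(nrow(sites)), function(i)
      total_anisotropy(sites$d11[i], sites$d22[i], sites$d33[i],
                       sites$rho[i], tau), numeric(1)))
  structure(list(kind = "oscillation", tau = tau, curve = curve,
                 points = points), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  if (x$kind == "tilt")
    cat("scan_result (tilt):", length(unique(x$curves$site)), "site(s),",
        length(unique(x$curves$tau)), "grid points\n")
  else
    cat("scan_result (oscillation): tau =", x$tau, "deg,",
        nrow(x$points), "site point(s)\n")
  invisible(x)
}
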