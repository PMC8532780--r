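# Small vector helpers shared by the geometry and tensor modules.
# All angles at the package surface are degrees; radians are internal.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors, degrees in [0, 180].
vangle <- function(a, b) {
  ca <- sum(vunit(a) * vunit(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# Acute angle between two axes (sign-insensitive), degrees in [0, 90].
axis_angle <- function(a, b) {
  ca <- abs(sum(vunit(a) * vunit(b)))
  rad2deg(acos(min(1, ca)))
}

# Natural-extension-reference-frame placement: position of atom D bonded to
# C, given bond length |C-D|, angle B-C-D (deg) and torsion A-B-C-D (deg).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)   # bc, m, n orthonormal
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Random 3x3 rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
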