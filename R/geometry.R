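# Small 3D geometry helpers shared by the descriptor code and the
# synthetic-structure builder. All coordinates in Angstroms, angles in
# degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral angle (degrees, in (-180, 180]) defined by points p1-p2-p3-p4
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# place atom D given bonded chain A-B-C, bond length |CD|, angle B-C-D and
# dihedral A-B-C-D (natural extension reference frame)
place_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  n <- n / vnorm(n)
  m <- vcross(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# unit sphere point set (deterministic golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
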