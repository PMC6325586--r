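#' Pseudo-bond angle at a C-alpha vertex
#'
#' The angle at `q` between the rays `q -> p` and `q -> r`, in degrees.
#' For three consecutive C-alpha atoms this is the trace-level curvature
#' measure: about 127 degrees in an extended beta-strand, about 90 degrees
#' in an alpha-helix, 180 degrees when collinear.  The cosine is clamped
#' to [-1, 1] before `acos` so near-degenerate geometry cannot produce
#' NaN.
#'
#' @param p,q,r Numeric 3-vectors (Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
pseudo_bond_angle <- function(p, q, r) {
  u <- as.numeric(p) - as.numeric(q)
  v <- as.numeric(r) - as.numeric(q)
  stopifnot(length(u) == 3L, length(v) == 3L)
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("pseudo_bond_angle: zero-length ray (coincident points)")
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

#' Pseudo-dihedral over four consecutive C-alpha atoms
#'
#' Signed torsion of the virtual bonds `p-q`, `q-r`, `r-s` in degrees,
#' in `(-180, 180]`.  Extended strands sit near +/-180 degrees,
#' alpha-helices near +50 degrees; the geometric sheet call uses
#' `|dihedral| >= 90` to exclude the helical band.
#'
#' @param p,q,r,s Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
pseudo_dihedral <- function(p, q, r, s) {
  b1 <- as.numeric(q) - as.numeric(p)
  b2 <- as.numeric(r) - as.numeric(q)
  b3 <- as.numeric(s) - as.numeric(r)
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 == 0 || all(n1 == 0) || all(n2 == 0))
    stop("pseudo_dihedral: degenerate (collinear or coincident) points")
  atan2(sum(.cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Pseudo-bond angle at every interior residue of a trace; NA at termini
# and at degenerate (coincident-point) vertices.
.chain_angles <- function(xyz) {
  n <- nrow(xyz)
  ang <- rep(NA_real_, n)
  if (n < 3L) return(ang)
  for (i in 2:(n - 1L))
    ang[i] <- tryCatch(
      pseudo_bond_angle(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ]),
      error = function(e) NA_real_)
  ang
}

# Pseudo-dihedral at interior residue i over residues (i-1, i, i+1, i+2),
# falling back to (i-2 .. i+1) at the last interior residue; NA where no
# four consecutive residues exist.
.chain_dihedrals <- function(xyz) {
  n <- nrow(xyz)
  dih <- rep(NA_real_, n)
  if (n < 4L) return(dih)
  for (i in 2:(n - 1L)) {
    dih[i] <- tryCatch(
      if (i + 2L <= n)
        pseudo_dihedral(xyz[i - 1L, ], xyz[i, ], xyz[i + 1L, ],
                        xyz[i + 2L, ])
      else
        pseudo_dihedral(xyz[i - 2L, ], xyz[i - 1L, ], xyz[i, ],
                        xyz[i + 1L, ]),
      error = function(e) NA_real_)  # collinear trace: no defined torsion
  }
  dih
}

# Apply a rigid-body transform (3x3 rotation R, translation t) to every
# chain of a record; used by tests and sensitivity checks.
#' Rigid-body transform of a structure record
#'
#' Rotates and translates every chain of a record (`xyz -> xyz %*% t(R) + t`).
#' All screening quantities (distance profiles, pseudo-bond angles and
#' dihedrals) are invariant under this map.
#'
#' @param record A [structure_record()].
#' @param R 3x3 rotation matrix.
#' @param t Translation 3-vector (Angstrom).
#' @return The transformed `StructureRecord`.
#' @export
transform_record <- function(record, R = diag(3), t = c(0, 0, 0)) {
  stopifnot(inherits(record, "StructureRecord"),
            all(dim(as.matrix(R)) == c(3L, 3L)), length(t) == 3L)
  record$chains <- lapply(record$chains, function(ch) {
    ch$xyz <- ch$xyz %*% t(R) + matrix(t, nrow(ch$xyz), 3L, byrow = TRUE)
    ch
  })
  record
}
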