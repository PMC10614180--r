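# Quasi-centroid construction. The quasi-centroid of a water molecule is
# built from the bead averages of its curvilinear coordinates (two O-H bond
# lengths and the H-O-H angle); the resulting rigid molecule is placed at
# the Cartesian-centroid molecule's center of mass and oriented as close as
# possible to it by a mass-weighted optimal rotation (quaternion method).

#' Curvilinear quasi-centroid geometry of one molecule
#'
#' Arithmetic bead means of the internal coordinates:
#' `r_i = mean_j r_i^(j)`, `theta = mean_j theta^(j)`.
#'
#' @param bead_geometries P x 3 matrix with columns (r1, r2, theta), one row
#'   per bead.
#' @return Named vector `c(r1 =, r2 =, theta =)`.
#' @export
curvilinear_geometry <- function(bead_geometries) {
  bead_geometries <- as.matrix(bead_geometries)
  if (nrow(bead_geometries) < 1) stop("empty bead list")
  if (ncol(bead_geometries) != 3)
    stop("bead geometries must have columns (r1, r2, theta)")
  if (any(bead_geometries[, 1:2] <= 0)) stop("bond lengths must be positive")
  g <- colMeans(bead_geometries)
  c(r1 = g[[1]], r2 = g[[2]], theta = g[[3]])
}

#' Mass-weighted optimal rotation (quaternion method)
#'
#' Finds the proper rotation U minimizing
#' `sum_X m_X |ref_X - U mov_X|^2` for two sets of points expressed
#' relative to their own mass centers, via the eigenproblem of the 4 x 4
#' quaternion matrix. The quaternion sign is fixed by a non-negative scalar
#' part; for (near-)collinear point sets the method falls back to a
#' two-vector alignment with a warning.
#'
#' @param ref,mov n x 3 matrices (reference and movable points).
#' @param masses Weights (length n).
#' @return 3 x 3 rotation matrix U with det +1 such that `mov %*% t(U)`
#'   best matches `ref`.
#' @export
optimal_rotation <- function(ref, mov, masses) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  w <- masses / sum(masses)
  ref <- sweep(ref, 2, colSums(ref * w))
  mov <- sweep(mov, 2, colSums(mov * w))

  cr <- crossprod_vec(mov[2, ] - mov[1, ], mov[3, ] - mov[1, ])
  if (nrow(mov) == 3 && sqrt(sum(cr^2)) <
      1e-10 * max(1, sum(mov^2))) {
    warning("collinear point set; using two-vector alignment")
    return(align_vector_rotation(mov[2, ] - mov[1, ], ref[2, ] - ref[1, ]))
  }

  S <- t(mov * w) %*% ref  # S[a, b] = sum_i w_i mov_ia ref_ib
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  if (q[1] < 0) q <- -q
  quaternion_to_rotation(q)
}

quaternion_to_rotation <- function(q) {
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    q0^2+q1^2-q2^2-q3^2, 2*(q1*q2-q0*q3),     2*(q1*q3+q0*q2),
    2*(q1*q2+q0*q3),     q0^2-q1^2+q2^2-q3^2, 2*(q2*q3-q0*q1),
    2*(q1*q3-q0*q2),     2*(q2*q3+q0*q1),     q0^2-q1^2-q2^2+q3^2),
    3, 3, byrow = TRUE)
}

crossprod_vec <- function(a, b) {
  c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3], a[1]*b[2]-a[2]*b[1])
}

# rotation taking unit(a) onto unit(b)
align_vector_rotation <- function(a, b) {
  ua <- a / sqrt(sum(a^2)); ub <- b / sqrt(sum(b^2))
  v <- crossprod_vec(ua, ub)
  s <- sqrt(sum(v^2)); cth <- sum(ua * ub)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(ua[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- crossprod_vec(ua, p); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 - cth) / s^2
}

# rigid molecule in a canonical frame: O at origin, H-O-H bisector along +z,
# molecule in the xz-plane
canonical_molecule <- function(r1, r2, theta) {
  h <- theta / 2
  rbind(O  = c(0, 0, 0),
        H1 = r1 * c(sin(h), 0, cos(h)),
        H2 = r2 * c(-sin(h), 0, cos(h)))
}

#' Place quasi-centroid molecules for a full ring-polymer configuration
#'
#' For every molecule: unwraps all beads to be contiguous with the O atom of
#' bead 1 (minimum image), averages the curvilinear internal coordinates
#' over beads, builds the rigid quasi-centroid molecule, and positions it at
#' the Cartesian-centroid molecule's center of mass with the mass-weighted
#' optimal orientation.
#'
#' @param bead_positions (n_atoms, 3, P) array of bead positions (a single
#'   n_atoms x 3 matrix is treated as P = 1).
#' @param cell A `simulation_cell`.
#' @param topo A `water_topology`.
#' @param template_frame Canonical frame used to build the rigid template
#'   ("bisector-z", default, or "bond-x"); the optimal rotation makes the
#'   placed coordinates independent of this choice.
#' @return Object of class `quasicentroid_frame`: `positions` (n_atoms x 3),
#'   `geometry` (n_mol x 3 matrix of r1, r2, theta), `cell`.
#' @export
place_quasicentroids <- function(bead_positions, cell, topo,
                                 template_frame = c("bisector-z", "bond-x")) {
  template_frame <- match.arg(template_frame)
  if (length(dim(bead_positions)) == 2)
    bead_positions <- array(bead_positions, dim = c(dim(bead_positions), 1))
  d <- dim(bead_positions)
  nat <- d[1]; P <- d[3]
  if (nat != topo$n_atoms) stop("bead array does not match topology")
  edges <- cell$edges
  nmol <- topo$n_mol

  # unwrap every bead relative to the O atom of bead 1 of its molecule
  refO <- bead_positions[seq(1, nat, by = 3), , 1, drop = FALSE]
  ref <- refO[topo$mol_id, , 1]
  pos_u <- bead_positions
  for (j in seq_len(P)) {
    dxy <- bead_positions[, , j] - ref
    dxy <- dxy - rep(edges, each = nat) * round(dxy / rep(edges, each = nat))
    pos_u[, , j] <- ref + dxy
  }

  # curvilinear coordinates per bead; big pseudo-cell disables wrapping
  bigcell <- rep(1e12, 3)
  gsum <- matrix(0, nmol, 3)
  for (j in seq_len(P)) {
    g <- intra_geometry_cpp(pos_u[, , j], bigcell)
    if (any(g[, 1:2] > 3))
      stop("O-H bond longer than 3 a0 after unwrapping; ",
           "molecule split across the periodic boundary?")
    gsum <- gsum + g
  }
  geom <- gsum / P

  # Cartesian centroid (bead mean) of the unwrapped atoms
  cen <- matrix(rowMeans(matrix(pos_u, nat * 3, P)), nat, 3)

  m3 <- topo$masses[1:3]
  wm <- m3 / sum(m3)
  qc <- matrix(NA_real_, nat, 3)
  for (m in seq_len(nmol)) {
    rows <- (3 * m - 2):(3 * m)
    cmol <- cen[rows, , drop = FALSE]
    rcm <- colSums(cmol * wm)
    cmol_c <- sweep(cmol, 2, rcm)
    tmpl <- canonical_molecule(geom[m, 1], geom[m, 2], geom[m, 3])
    if (template_frame == "bond-x") {
      # alternative canonical frame: first bond along +x, molecule in xy
      th <- geom[m, 3]
      tmpl <- rbind(O = c(0, 0, 0),
                    H1 = geom[m, 1] * c(1, 0, 0),
                    H2 = geom[m, 2] * c(cos(th), sin(th), 0))
    }
    tcm <- colSums(tmpl * wm)
    tmpl_c <- sweep(tmpl, 2, tcm)
    U <- optimal_rotation(cmol_c, tmpl_c, m3)
    qc[rows, ] <- sweep(tmpl_c %*% t(U), 2, -rcm)
  }
  structure(list(positions = qc, geometry = geom, cell = cell,
                 centroid = cen),
            class = "quasicentroid_frame")
}
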