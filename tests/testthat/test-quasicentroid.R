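test_that("curvilinear geometry is the arithmetic bead mean", {
  g <- rbind(c(1.8, 1.8, 1.9), c(1.8, 1.8, 1.9))
  expect_equal(unname(curvilinear_geometry(g)), c(1.8, 1.8, 1.9))
  g2 <- rbind(c(1.7, 1.8, 1.9), c(1.9, 1.8, 1.9))
  expect_equal(curvilinear_geometry(g2)[["r1"]], 1.8)
  set.seed(1)
  g3 <- cbind(stats::runif(32, 1.6, 2.0), stats::runif(32, 1.6, 2.0),
              stats::runif(32, 1.6, 2.2))
  ref <- c(mean(g3[, 1]), mean(g3[, 2]), mean(g3[, 3]))
  expect_equal(unname(curvilinear_geometry(g3)), ref, tolerance = 1e-14)
  expect_error(curvilinear_geometry(g3[0, , drop = FALSE]), "empty")
})

test_that("optimal rotation: identity, known-rotation recovery, proper orthogonal", {
  m <- fqcmd:::canonical_molecule(qp$r_eq, qp$r_eq * 1.05, qp$theta_eq)
  masses <- c(qp$m_O, qp$m_H, qp$m_H)
  wm <- masses / sum(masses)
  ref <- sweep(m, 2, colSums(m * wm))
  expect_lt(max(abs(optimal_rotation(ref, ref, masses) - diag(3))), 1e-12)
  set.seed(1)
  for (i in 1:5) {
    R <- fqcmd:::random_rotation()
    mov <- ref %*% t(R)
    U <- optimal_rotation(ref, mov, masses)
    expect_lt(max(abs(mov %*% t(U) - ref)), 1e-10)
    expect_equal(det(U), 1, tolerance = 1e-12)
    expect_lt(max(abs(t(U) %*% U - diag(3))), 1e-12)
  }
})

test_that("optimal rotation beats a Monte-Carlo sample of one million rotations", {
  m <- fqcmd:::canonical_molecule(qp$r_eq, qp$r_eq, qp$theta_eq)
  masses <- c(qp$m_O, qp$m_H, qp$m_H)
  wm <- masses / sum(masses)
  set.seed(2)
  mov <- m + matrix(stats::rnorm(9, 0, 0.3), 3, 3)
  ref <- sweep(m, 2, colSums(m * wm))
  mov <- sweep(mov, 2, colSums(mov * wm))
  U <- optimal_rotation(ref, mov, masses)
  resid <- function(U) sum(masses * rowSums((ref - mov %*% t(U))^2))
  ropt <- resid(U)
  # vectorized residual over sampled quaternions
  n <- 1e6
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  # residual = sum_i m_i (|ref_i|^2 + |mov_i|^2) - 2 sum_i m_i ref_i . (U mov_i)
  const <- sum(masses * (rowSums(ref^2) + rowSums(mov^2)))
  S <- t(mov * masses) %*% ref  # S[a,b] = sum_i m_i mov_ia ref_ib
  # trace(U S) for U(q): expand in quaternion components
  q0 <- q[, 1]; q1 <- q[, 2]; q2 <- q[, 3]; q3 <- q[, 4]
  trUS <-
    (q0^2 + q1^2 - q2^2 - q3^2) * S[1, 1] +
    2 * (q1 * q2 - q0 * q3) * S[2, 1] + 2 * (q1 * q3 + q0 * q2) * S[3, 1] +
    2 * (q1 * q2 + q0 * q3) * S[1, 2] +
    (q0^2 - q1^2 + q2^2 - q3^2) * S[2, 2] +
    2 * (q2 * q3 - q0 * q1) * S[3, 2] +
    2 * (q1 * q3 - q0 * q2) * S[1, 3] + 2 * (q2 * q3 + q0 * q1) * S[2, 3] +
    (q0^2 - q1^2 - q2^2 + q3^2) * S[3, 3]
  mc_min <- const - 2 * max(trUS)
  expect_lte(ropt, mc_min + 1e-10)
})

test_that("collinear degenerate input falls back with a warning", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  ref <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0))
  expect_warning(U <- optimal_rotation(ref, pts, c(16, 1, 1) * 1822),
                 "collinear")
  expect_equal(det(U), 1, tolerance = 1e-10)
})

test_that("quasi-centroid placement: P = 1 identity and rigid-bead invariance", {
  topo <- water_topology(2, qp)
  cell <- simulation_cell(30)
  cfg <- two_molecule_config(sep = 8)
  qc1 <- place_quasicentroids(cfg$positions, cell, topo)
  expect_lt(max(abs(qc1$positions - cfg$positions)), 1e-12)
  # beads generated by rigid rotation of one molecule about its mass center:
  # curvilinear averages equal the rigid geometry
  P <- 6
  m <- cfg$positions[1:3, ]
  wm <- topo$masses[1:3] / sum(topo$masses[1:3])
  cm <- colSums(m * wm)
  beads <- array(NA_real_, dim = c(6, 3, P))
  set.seed(3)
  for (j in 1:P) {
    R <- fqcmd:::random_rotation()
    beads[1:3, , j] <- sweep(sweep(m, 2, cm) %*% t(R), 2, -cm)
    beads[4:6, , j] <- cfg$positions[4:6, ]
  }
  qc <- place_quasicentroids(beads, cell, topo)
  g0 <- fqcmd:::intra_geometry_cpp(m, rep(1e12, 3))
  expect_equal(qc$geometry[1, ], as.numeric(g0), tolerance = 1e-10)
})

test_that("quasi-centroid bond length >= Cartesian-centroid bond length", {
  topo <- water_topology(2, qp)
  cell <- simulation_cell(30)
  cfg <- two_molecule_config(sep = 8)
  set.seed(7)
  for (rep in 1:5) {
    P <- 16
    beads <- array(rep(cfg$positions, P), dim = c(6, 3, P)) +
      array(stats::rnorm(6 * 3 * P, 0, 0.08), dim = c(6, 3, P))
    qc <- place_quasicentroids(beads, cell, topo)
    cen <- qc$centroid
    for (mol in 1:2) {
      for (b in 1:2) {
        cb <- sqrt(sum((cen[3 * mol - 2 + b, ] - cen[3 * mol - 2, ])^2))
        expect_gte(qc$geometry[mol, b] + 1e-12, cb)
      }
      # mass centers of quasi-centroid and centroid molecules coincide
      wm <- topo$masses[1:3] / sum(topo$masses[1:3])
      rows <- (3 * mol - 2):(3 * mol)
      expect_lt(max(abs(colSums(qc$positions[rows, ] * wm) -
                          colSums(cen[rows, ] * wm))), 1e-10)
    }
  }
})

test_that("placement is equivariant and independent of the template frame", {
  topo <- water_topology(2, qp)
  cell <- simulation_cell(30)
  cfg <- two_molecule_config(sep = 8)
  P <- 12
  set.seed(5)
  beads <- array(rep(cfg$positions, P), dim = c(6, 3, P)) +
    array(stats::rnorm(6 * 3 * P, 0, 0.08), dim = c(6, 3, P))
  qc <- place_quasicentroids(beads, cell, topo)
  qc_alt <- place_quasicentroids(beads, cell, topo,
                                 template_frame = "bond-x")
  expect_lt(max(abs(qc_alt$positions - qc$positions)), 1e-10)
  R <- fqcmd:::random_rotation()
  tvec <- c(1.2, -0.7, 2.0)
  beads_r <- beads
  for (j in 1:P) beads_r[, , j] <- sweep(beads[, , j] %*% t(R), 2, -tvec)
  qcr <- place_quasicentroids(beads_r, cell, topo)
  expect_lt(max(abs(qcr$positions -
                      sweep(qc$positions %*% t(R), 2, -tvec))), 1e-10)
})

test_that("molecules split across the boundary without unwrapping are detected", {
  topo <- water_topology(1, qp)
  cell <- simulation_cell(10)
  m <- fqcmd:::canonical_molecule(qp$r_eq, qp$r_eq, qp$theta_eq)
  m[2, ] <- m[2, ] + c(5, 0, 0)  # H teleported: unwrap cannot fix a 5 a0 bond
  expect_error(place_quasicentroids(m, cell, topo), "3 a0")
})
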