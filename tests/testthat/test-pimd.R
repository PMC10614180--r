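test_that("normal-mode transform: identity at P = 1, exact round trip, centroid mode", {
  nm1 <- normal_mode_matrix(1)
  expect_equal(nm1$C, matrix(1, 1, 1))
  for (P in c(2, 5, 8, 32)) {
    nm <- normal_mode_matrix(P)
    expect_lt(max(abs(nm$C %*% t(nm$C) - diag(P))), 1e-12)
    set.seed(P)
    x <- array(stats::rnorm(4 * 3 * P), dim = c(4, 3, P))
    modes <- normal_mode_transform(x, nm, "to_modes")
    back <- normal_mode_transform(modes, nm, "to_beads")
    expect_lt(max(abs(back - x)), 1e-12)
    # mode 0 is the arithmetic bead mean
    expect_lt(max(abs(modes[, , 1] - apply(x, c(1, 2), mean))), 1e-12)
  }
})

test_that("P = 1 PIMD with the thermostat off is classical velocity Verlet", {
  st <- small_liquid(equil_steps = 0)
  state <- ring_polymer_state(st$config, 1, 300, st$topo, seed = 9)
  state$velocities[, , 1] <- st$config$velocities
  nve <- integrator_settings(0.25, "none", temperature = 300)
  a <- run_water_pimd(state, st$cell, st$topo, qp, nve, 200,
                      record_stride = 200)
  b <- run_water_md(st$config, st$cell, st$topo, qp, nve, 200,
                    record_stride = 200)
  expect_lt(max(abs(a$final$positions[, , 1] - b$final$positions)), 1e-12)
  expect_equal(a$pe, b$pe, tolerance = 1e-12)
})

test_that("free ring polymer evolves exactly (closed-form normal-mode rotation)", {
  st <- small_liquid(n = 32, equil_steps = 0)
  p0 <- qp
  p0$D_r <- 1e-300; p0$k_theta <- 1e-300; p0$eps_OO <- 1e-300; p0$q_H <- 0
  P <- 8
  state <- ring_polymer_state(st$config, P, 300, st$topo, seed = 3)
  set.seed(4)
  state$positions <- state$positions +
    array(stats::rnorm(length(state$positions), 0, 0.1),
          dim = dim(state$positions))
  nve <- integrator_settings(0.25, "none", temperature = 300)
  n <- 40
  run <- run_water_pimd(state, st$cell, st$topo, p0, nve, n,
                        record_stride = n)
  nm <- normal_mode_matrix(P)
  omk <- nm$omega(state$beta)
  dt <- 0.25 / units$autime_fs
  # propagate a handful of atoms analytically
  for (a in c(1, 5, 17)) for (k in 1:3) {
    xn <- as.numeric(nm$C %*% state$positions[a, k, ])
    vn <- as.numeric(nm$C %*% state$velocities[a, k, ])
    for (s in 1:n) {
      x2 <- cos(omk * dt) * xn +
        ifelse(omk > 0, sin(omk * dt) / pmax(omk, 1e-300), dt) * vn
      v2 <- -omk * sin(omk * dt) * xn + cos(omk * dt) * vn
      xn <- x2; vn <- v2
    }
    xf <- as.numeric(t(nm$C) %*% xn)
    expect_lt(max(abs(xf - run$final$positions[a, k, ])), 1e-10)
  }
})

test_that("seeded PIMD runs are bitwise identical", {
  st <- small_liquid(equil_steps = 0)
  state <- ring_polymer_state(st$config, 4, 300, st$topo, seed = 5)
  s <- integrator_settings(0.25, "langevin", tau_fs = 50, temperature = 300,
                           seed = 11)
  a <- run_water_pimd(state, st$cell, st$topo, qp, s, 100, record_stride = 20)
  b <- run_water_pimd(state, st$cell, st$topo, qp, s, 100, record_stride = 20)
  expect_identical(a$pe, b$pe)
  expect_identical(a$final$positions, b$final$positions)
})

test_that("1-D harmonic oscillator bead variance matches the quantum closed form", {
  toy <- build_toy_system("oscillator", list(omega = 0.0089))
  temperature <- 300
  beta <- 1 / (units$kB * temperature)
  P <- 32
  force_fn <- function(x) -toy$mass * toy$omega^2 * x
  set.seed(2)
  x0 <- matrix(stats::rnorm(P, 0, 0.1), P, 1)
  v0 <- matrix(stats::rnorm(P, 0, sqrt(P / (beta * toy$mass))), P, 1)
  st <- integrator_settings(0.5, "langevin", tau_fs = 20,
                            temperature = temperature, seed = 3)
  run <- run_pimd_r(x0, v0, toy$mass, force_fn, beta, st, 30000,
                    record_stride = 5)
  xs <- run$positions[-(1:1000), , 1]
  v_est <- mean(xs^2)
  v_exact <- toy$quantum_variance(temperature)
  # 3 standard errors with a conservative correlation-length estimate
  se <- stats::sd(as.numeric(xs)^2) / sqrt(length(xs) / 60)
  expect_lt(abs(v_est - v_exact), 3 * se)
  # and the quantum result is far from classical at this temperature
  expect_gt(v_exact / toy$classical_variance(temperature), 3)
})

test_that("bead variance converges monotonically in P on the oscillator", {
  toy <- build_toy_system("oscillator", list(omega = 0.0089))
  temperature <- 300
  beta <- 1 / (units$kB * temperature)
  force_fn <- function(x) -toy$mass * toy$omega^2 * x
  st <- integrator_settings(0.5, "langevin", tau_fs = 20,
                            temperature = temperature, seed = 3)
  vars <- sapply(c(1, 2, 4, 8, 16), function(P) {
    set.seed(2)
    x0 <- matrix(stats::rnorm(P, 0, 0.1), P, 1)
    v0 <- matrix(stats::rnorm(P, 0, sqrt(P / (beta * toy$mass))), P, 1)
    run <- run_pimd_r(x0, v0, toy$mass, force_fn, beta, st, 15000,
                      record_stride = 5)
    mean(run$positions[-(1:600), , 1]^2)
  })
  expect_true(all(diff(vars) > 0))
  expect_lt(vars[5], toy$quantum_variance(temperature))
})

test_that("primitive and virial kinetic-energy estimators agree", {
  st <- small_liquid(n = 32, equil_steps = 4000)
  state <- ring_polymer_state(st$config, 8, 300, st$topo, seed = 6)
  s <- integrator_settings(0.25, "langevin", tau_fs = 50, temperature = 300,
                           seed = 12)
  eq <- run_water_pimd(state, st$cell, st$topo, qp, s, 600,
                       record_stride = 600)
  run <- run_water_pimd(eq$final, st$cell, st$topo, qp, s, 2500,
                        record_stride = 10)
  prim <- run$ke_primitive[-(1:50)]
  vir <- run$ke_virial[-(1:50)]
  se <- sqrt(stats::sd(prim)^2 / (length(prim) / 25) +
               stats::sd(vir)^2 / (length(vir) / 25))
  expect_lt(abs(mean(prim) - mean(vir)), 4 * se)
  # both well above the classical kinetic energy (zero-point motion)
  expect_gt(mean(vir), 1.5 * 1.5 * st$topo$n_atoms * units$kB * 300)
})
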