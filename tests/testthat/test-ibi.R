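kT300 <- units$kB * 300

test_that("zero correction gives exactly zero energy and forces", {
  st <- small_liquid(equil_steps = 0)
  corr <- correction_potential(qp)
  fe <- evaluate_correction(corr, st$config, st$cell, st$topo, qp)
  expect_equal(fe$energy, 0)
  expect_lt(max(abs(fe$forces)), 1e-250)
})

test_that("pair tables reproduce nodal values exactly and extrapolate linearly", {
  r <- seq(4, 11, by = 0.05)
  V <- 1e-3 * exp(-(r - 6)^2)
  tab <- fqcmd:::make_pair_table(r, V, r_cut = 11, smooth_window = 0)
  ev <- fqcmd:::eval_pair_table(tab, r)
  expect_equal(ev$V[10], tab$V[10])         # exact at the nodes
  expect_equal(ev$V, tab$V, tolerance = 1e-14)
  # below the inner edge: linear continuation at constant force, counted
  ev2 <- fqcmd:::pair_table_eval_cpp(tab, c(3.5, 3.9))
  expect_equal(ev2$n_extrapolated, 2)
  slope <- tab$dV[1]
  expect_equal(ev2$V, tab$V[1] + slope * (c(3.5, 3.9) - 4), tolerance = 1e-12)
  # zero at and beyond the cutoff
  expect_equal(fqcmd:::eval_pair_table(tab, c(11, 12))$V, c(0, 0))
})

test_that("correction forces match central differences", {
  st <- small_liquid(equil_steps = 0)
  corr <- correction_potential(qp)
  corr$dv_r <- c(0, 1e-3, 2e-3, -1e-3, 5e-3)
  corr$dv_r_range <- c(-0.2, 0.2)
  corr$dv_theta <- c(0, 5e-4, 3e-3)
  corr$dv_theta_range <- c(-0.35, 0.35)
  rmax <- min(st$cell$edges) / 2
  r <- seq(4.2, rmax, by = 0.1)
  corr$pair_OO <- fqcmd:::make_pair_table(r, 4e-4 * sin(r), rmax,
                                          smooth_window = 0)
  corr$pair_OH <- fqcmd:::make_pair_table(r, 2e-4 * cos(r), rmax,
                                          smooth_window = 0)
  pos <- st$config$positions
  fe <- evaluate_correction(corr, st$config, st$cell, st$topo, qp)
  h <- 1e-5
  maxerr <- 0
  set.seed(2)
  for (i in sample(st$topo$n_atoms, 5)) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    num <- -(evaluate_correction(corr, configuration(pp), st$cell, st$topo,
                                 qp)$energy -
             evaluate_correction(corr, configuration(pm), st$cell, st$topo,
                                 qp)$energy) / (2 * h)
    maxerr <- max(maxerr, abs(num - fe$forces[i, k]))
  }
  expect_lt(maxerr / max(abs(fe$forces)), 1e-6)
})

test_that("IBI fixed point: identical distributions give zero update for all eps", {
  r <- seq(0.05, 10, by = 0.1)
  g <- pmax(0, 1.8 * exp(-(r - 5.2)^2) + 1 - exp(-(r - 5)^2 / 8)) *
    (r > 4) * pmin(1, (r - 4) / 0.5)
  for (eps in c(0, 0.5, 1, 5, 50)) {
    tab <- ibi_inter_update(NULL, g, g, r, eps, kT300, r_cut = 10)
    expect_equal(max(abs(tab$V)), 0)
    # and an existing table is left exactly unchanged
    tab0 <- fqcmd:::make_pair_table(seq(4.5, 10, 0.1),
                                    1e-3 * exp(-(seq(4.5, 10, 0.1) - 6)^2),
                                    10, smooth_window = 0)
    tab1 <- ibi_inter_update(tab0, g[r >= 4.45], g[r >= 4.45], r[r >= 4.45],
                             eps, kT300, r_cut = 10)
    rq <- r[r >= 4.45 & r < 10 - 0.1]  # inside the table support
    ev0 <- fqcmd:::eval_pair_table(tab0, rq)
    ev1 <- fqcmd:::eval_pair_table(tab1, rq)
    expect_equal(ev1$V, ev0$V, tolerance = 1e-12)
  }
})

test_that("unregularized single-bin update is exactly kT ln 2", {
  r <- seq(4.05, 10.05, by = 0.1)
  g_target <- rep(1, length(r))
  g_trial <- g_target
  i <- 25
  g_trial[i] <- 2  # g_trial / g_target = 2 in one bin
  tab <- ibi_inter_update(NULL, g_trial, g_target, r, 0, kT300, r_cut = 11,
                          smooth_window = 0, switch_width = 1e-6)
  expect_equal(tab$V[i], kT300 * log(2), tolerance = 1e-12)
  expect_lt(max(abs(tab$V[-i])), 1e-18)
})

test_that("regularized update is monotonically damped in eps", {
  r <- seq(4.05, 10.05, by = 0.1)
  g_target <- rep(1, length(r)); g_trial <- g_target
  i <- 25; g_trial[i] <- 2
  prev <- Inf
  for (eps in c(0, 1, 5, 50, 500)) {
    tab <- ibi_inter_update(NULL, g_trial, g_target, r, eps, kT300,
                            r_cut = 11, smooth_window = 0,
                            switch_width = 1e-6)
    expect_lte(abs(tab$V[i]), prev + 1e-18)
    prev <- abs(tab$V[i])
  }
  expect_lt(prev, kT300 * log(2) / 50)  # strong damping at eps = 500
  # eps = 0 with a 0/0 bin is an error
  gz <- g_target; gz[40] <- 0
  gt <- g_trial; gt[40] <- 0
  expect_error(ibi_inter_update(NULL, gt, gz, r, 0, kT300, r_cut = 11),
               "0/0|vanish")
})

test_that("noise suppression: low-density update obeys the first-order bound", {
  r <- seq(4.05, 10.05, by = 0.1)
  set.seed(6)
  g_target <- rep(1, length(r))
  g_trial <- rep(1, length(r))
  # a low-density region with noise-scale differences
  low <- 30:40
  eps <- 1
  G <- 1.5
  g_target[low] <- 0.01; g_trial[low] <- 0.01 + stats::rnorm(11, 0, 0.003)
  g_target[5] <- G  # sets the peak height
  g_trial[5] <- G
  tab <- ibi_inter_update(NULL, pmax(g_trial, 0), g_target, r, eps, kT300,
                          r_cut = 11, smooth_window = 0,
                          switch_width = 1e-6)
  # in bins where both g << eps G, |update| <= ~ kT |diff| / (eps G)
  bound <- kT300 * abs(g_trial[low] - g_target[low]) / (eps * G)
  expect_true(all(abs(tab$V[low]) <= bound * 1.05 + 1e-18))
})

test_that("intramolecular refit recovers a known perturbation from Boltzmann densities", {
  beta <- 1 / kT300
  r <- seq(1.21, 2.59, by = 0.02)
  a <- qp$a_r
  Vr <- function(x) {
    d <- x - qp$r_eq
    qp$D_r * (a^2 * d^2 - a^3 * d^3 + 7 / 12 * a^4 * d^4)
  }
  dV <- function(x) {
    d <- x - qp$r_eq
    1e-3 * d^2 - 4e-3 * d^3 + 2e-3 * d^4
  }
  rho_t <- exp(-beta * (Vr(r) + dV(r))); rho_t <- rho_t / sum(rho_t) / 0.02
  rho_0 <- exp(-beta * Vr(r)); rho_0 <- rho_0 / sum(rho_0) / 0.02
  th <- seq(1.0, 2.8, by = 0.5 * pi / 180)
  th <- th[-length(th)] + 0.25 * pi / 180
  Vt <- function(x) 0.5 * qp$k_theta * (x - qp$theta_eq)^2
  dVt <- function(x) 2e-3 * (x - qp$theta_eq) + 5e-3 * (x - qp$theta_eq)^2
  tt <- exp(-beta * (Vt(th) + dVt(th))); tt <- tt / sum(tt) / (0.5 * pi / 180)
  t0 <- exp(-beta * Vt(th)); t0 <- t0 / sum(t0) / (0.5 * pi / 180)
  trial <- list(rho_r = data.frame(r = r, density = rho_0),
                rho_theta = data.frame(theta = th, density = t0))
  target <- list(rho_r = data.frame(r = r, density = rho_t),
                 rho_theta = data.frame(theta = th, density = tt))
  upd <- ibi_intra_refit(numeric(5), numeric(3), trial, target, kT300,
                         qp$r_eq, qp$theta_eq)
  mask <- rho_t > 0.01 * max(rho_t)
  x <- r[mask] - qp$r_eq
  rec <- sapply(x, function(z) sum(upd$dv_r * z^(0:4)))
  truth <- dV(r[mask])
  resid <- rec - truth - mean(rec - truth)
  expect_lt(sqrt(mean(resid^2)) / diff(range(truth)), 0.10)
  # masking: bins below 1% of the maxima carry zero weight (assert directly)
  expect_equal(upd$n_bins_r, sum(mask & rho_0 > 0.01 * max(rho_0)))
  # trivial fixed point
  upd0 <- ibi_intra_refit(numeric(5), numeric(3), target, target, kT300,
                          qp$r_eq, qp$theta_eq)
  expect_equal(max(abs(upd0$dv_r)), 0)
  expect_equal(max(abs(upd0$dv_theta)), 0)
  # too few usable bins is an error
  shrunk <- list(rho_r = target$rho_r[30:32, ],
                 rho_theta = target$rho_theta[100:102, ])
  expect_error(ibi_intra_refit(numeric(5), numeric(3), shrunk, shrunk,
                               kT300, qp$r_eq, qp$theta_eq), "usable bins")
})

test_that("tabulated forces are continuous and improve under grid refinement", {
  r_cut <- 10
  f_of <- function(dr) {
    r <- seq(4, r_cut, by = dr)
    tab <- fqcmd:::make_pair_table(r, 1e-3 * exp(-(r - 6)^2 / 1.5), r_cut,
                                   smooth_window = 0)
    rf <- seq(4.2, 9.5, by = dr / 7)
    fqcmd:::eval_pair_table(tab, rf)$dV
  }
  jump <- function(f) max(abs(diff(f)))
  j1 <- jump(f_of(0.1))
  j2 <- jump(f_of(0.05))
  expect_lt(j2, j1)            # refinement shrinks force increments
  expect_lt(j1, 2e-4)          # and they are small in absolute terms
})

test_that("self-target IBI stays near zero and recovers a known pair perturbation", {
  toy <- build_toy_system("lj_liquid",
                          list(perturb_A = 6e-4, density_red = 0.4,
                               temperature = 160), seed = 4)
  kT <- units$kB * toy$temperature
  st <- integrator_settings(toy$dt_fs, "langevin", tau_fs = 200,
                            temperature = toy$temperature, seed = 5)
  adv <- function(tab, n, seed, pos, vel, frames = 0L) {
    fqcmd:::run_lj_md_cpp(pos, vel, toy$cell$edges, toy$eps, toy$sigma,
                          toy$rcut, toy$mass, tab,
                          toy$dt_fs / units$autime_fs, n, kT,
                          1 / (200 / units$autime_fs), 1L, seed,
                          n, frames)
  }
  eq <- adv(toy$perturbation$table, 5000, 6L, toy$config$positions,
            toy$config$velocities)
  tg <- adv(toy$perturbation$table, 60000, 7L, eq$positions, eq$velocities,
            frames = 4L)
  target <- fqcmd:::rdf_atoms(tg$frames, toy$cell, 0.1, min(toy$rcut, 14))
  fit <- run_ibi(target, toy$system, st, n_iterations = 12, epsilon = 0.2,
                 md_steps = 25000, equil_steps = 4000, frame_stride = 4,
                 seed = 11, smooth_window = 7)
  r <- target$table$r
  rec <- fqcmd:::eval_pair_table(fit$correction$pair_OO, r)$V
  truth <- toy$perturbation$fn(r)
  base <- r >= 11 & r <= 12.5
  rec0 <- rec - mean(rec[base]) + mean(truth[base])
  bump <- r >= 5.5 & r <= 11
  expect_gt(cor(rec0[bump], truth[bump]), 0.9)
  expect_lt(abs(r[bump][which.max(rec0[bump])] - toy$perturbation$r0), 0.75)
  amp <- max(rec0[bump]) / max(truth)
  expect_gt(amp, 0.55)
  expect_lt(amp, 1.4)
  # self-target: corrections remain at the noise scale (well below the
  # recovered perturbation)
  eq0 <- adv(list(), 5000, 16L, toy$config$positions, toy$config$velocities)
  tg0 <- adv(list(), 50000, 17L, eq0$positions, eq0$velocities, frames = 4L)
  target0 <- fqcmd:::rdf_atoms(tg0$frames, toy$cell, 0.1, min(toy$rcut, 14))
  fit0 <- run_ibi(target0, toy$system, st, n_iterations = 4, epsilon = 0.2,
                  md_steps = 25000, equil_steps = 4000, frame_stride = 4,
                  seed = 13, smooth_window = 7)
  rin <- r >= 5.5 & r <= 12.5  # table support, away from the extrapolated edge
  rec00 <- fqcmd:::eval_pair_table(fit0$correction$pair_OO, r)$V
  expect_lt(max(abs(rec00[rin] - mean(rec00[base]))), 0.35 * max(truth))
})
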