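test_that("ideal-gas frames give g = 1 within counting noise", {
  set.seed(3)
  N <- 40
  cell <- simulation_cell(20)
  topo <- water_topology(N, qp)
  nf <- 80
  frames <- array(stats::runif(3 * N * 3 * nf, 0, 20), dim = c(3 * N, 3, nf))
  for (pair in c("OO", "OH", "HH")) {
    g <- accumulate_rdf(frames, pair, cell, topo, bin_width = 0.5)
    sel <- g$table$r > 2
    counts <- g$counts[sel]
    expect_true(all(abs(g$table$g[sel] - 1) <= 3 / sqrt(pmax(counts, 1)) + 0.02))
  }
})

test_that("two particles at fixed separation put all mass in one bin", {
  topo2 <- water_topology(2, qp)
  cell <- simulation_cell(200)
  pos <- matrix(0, 6, 3)
  pos[4, 1] <- 5.3
  pos[2, ] <- pos[3, ] <- c(90, 90, 90)
  pos[5, ] <- pos[6, ] <- c(40, 0, 0)
  g <- accumulate_rdf(array(pos, dim = c(6, 3, 1)), "OO", cell, topo2,
                      bin_width = 0.1, r_max = 10)
  expect_equal(sum(g$counts), 1)
  expect_equal(g$table$r[g$counts == 1], 5.25)
})

test_that("histogram accumulation matches a naive double loop over pairs", {
  set.seed(4)
  N <- 12
  cell <- simulation_cell(14)
  topo <- water_topology(N, qp)
  frames <- array(stats::runif(3 * N * 3 * 10, 0, 14), dim = c(3 * N, 3, 10))
  oracle <- function(idx1, idx2, same, bw, nb) {
    counts <- numeric(nb)
    for (f in 1:10) {
      pos <- frames[, , f]
      for (i in idx1) for (j in (if (same) idx1 else idx2)) {
        if (same && j <= i) next
        if (topo$mol_id[i] == topo$mol_id[j]) next
        d <- pos[j, ] - pos[i, ]
        d <- d - cell$edges * round(d / cell$edges)
        b <- floor(sqrt(sum(d^2)) / bw) + 1
        if (b <= nb) counts[b] <- counts[b] + 1
      }
    }
    counts
  }
  oidx <- which(topo$species == "O"); hidx <- which(topo$species == "H")
  gOO <- accumulate_rdf(frames, "OO", cell, topo, 0.5)
  expect_equal(gOO$counts, oracle(oidx, NULL, TRUE, 0.5, length(gOO$counts)),
               tolerance = 1e-12)
  gOH <- accumulate_rdf(frames, "OH", cell, topo, 0.5)
  expect_equal(gOH$counts, oracle(oidx, hidx, FALSE, 0.5, length(gOH$counts)),
               tolerance = 1e-12)
  gHH <- accumulate_rdf(frames, "HH", cell, topo, 0.5)
  expect_equal(gHH$counts, oracle(hidx, NULL, TRUE, 0.5, length(gHH$counts)),
               tolerance = 1e-12)
})

test_that("range checks: histogram range above half box is rejected", {
  topo <- water_topology(4, qp)
  cell <- simulation_cell(10)
  expect_error(accumulate_rdf(array(0, dim = c(12, 3, 1)), "OO", cell, topo,
                              r_max = 6), "half")
})

test_that("intramolecular densities: spikes, unit integral, out-of-range counting", {
  g <- matrix(c(rep(1.8, 10), rep(1.85, 10), rep(1.9, 10)), 10, 3)
  di <- accumulate_intra(g)
  expect_equal(sum(di$rho_r$density) * di$r_bin, 1, tolerance = 1e-12)
  expect_equal(sum(di$rho_theta$density) * di$theta_bin, 1, tolerance = 1e-12)
  expect_equal(sum(di$rho_r$density > 0), 2)  # 1.8 and 1.85 bins
  expect_equal(sum(di$rho_theta$density > 0), 1)
  # out-of-grid values are counted and warned about, never silently dropped
  g2 <- rbind(g, c(0.5, 1.8, 1.9))
  expect_warning(di2 <- accumulate_intra(g2), "outside")
  expect_equal(di2$n_out_of_range, 1)
  expect_error(accumulate_intra(g[0, , drop = FALSE]), "empty")
})

test_that("the same accumulation path serves classical and quasi-centroid frames", {
  # source-agnosticism: feed the same frames once as raw matrices, once
  # through the quasi-centroid placement at P = 1 (identity)
  st <- small_liquid(equil_steps = 0)
  settings <- integrator_settings(0.25, "langevin", tau_fs = 50,
                                  temperature = 300, seed = 13)
  run <- run_water_md(st$config, st$cell, st$topo, qp, settings, 400,
                      record_stride = 400, frame_stride = 100)
  d1 <- accumulate_distribution_set(run$frames, st$cell, st$topo, 300)
  nf <- dim(run$frames)[3]
  qcf <- array(NA_real_, dim = dim(run$frames))
  for (f in seq_len(nf))
    qcf[, , f] <- place_quasicentroids(run$frames[, , f], st$cell,
                                       st$topo)$positions
  d2 <- accumulate_distribution_set(qcf, st$cell, st$topo, 300)
  expect_equal(d1$g_OO$table$g, d2$g_OO$table$g, tolerance = 1e-9)
  expect_equal(d1$intra$rho_r$density, d2$intra$rho_r$density,
               tolerance = 1e-9)
})

test_that("PIMD rho_r is broader and shifted outward relative to classical", {
  st <- small_liquid(n = 32, equil_steps = 8000)
  # classical reference
  settings <- integrator_settings(0.25, "langevin", tau_fs = 100,
                                  temperature = 300, seed = 21)
  run <- run_water_md(st$config, st$cell, st$topo, qp, settings, 4000,
                      record_stride = 4000, frame_stride = 10)
  dc <- accumulate_distribution_set(run$frames, st$cell, st$topo, 300)
  res <- sample_quasicentroid_ensemble(st, qp, P = 8, n_steps = 2500,
                                       equil_steps = 800, frame_stride = 10,
                                       seed = 22)
  dq <- res$distributions
  mom <- function(tab) {
    m1 <- sum(tab$density * tab$r) / sum(tab$density)
    list(mean = m1,
         sd = sqrt(sum(tab$density * (tab$r - m1)^2) / sum(tab$density)))
  }
  mq <- mom(dq$intra$rho_r); mc <- mom(dc$intra$rho_r)
  expect_gt(mq$sd, mc$sd)        # quantum broadening of the bead average
  expect_gt(mq$mean, mc$mean)    # anharmonic outward shift
})

test_that("distribution sets serialize to CSV tables", {
  st <- small_liquid(equil_steps = 0)
  settings <- integrator_settings(0.25, "langevin", tau_fs = 50,
                                  temperature = 300, seed = 13)
  run <- run_water_md(st$config, st$cell, st$topo, qp, settings, 200,
                      record_stride = 200, frame_stride = 100)
  d <- accumulate_distribution_set(run$frames, st$cell, st$topo, 300)
  dir <- tempfile()
  paths <- write_distribution_set(d, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["g_OO"]])
  expect_equal(back$g, d$g_OO$table$g, tolerance = 1e-12)
})
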