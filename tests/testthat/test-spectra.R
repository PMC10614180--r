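test_that("autocorrelation of a pure cosine matches the closed form", {
  dt <- 0.5; n <- 8000
  w_cm <- 1500
  f <- w_cm / units$cm1_per_invfs
  t <- (0:(n - 1)) * dt
  mud <- cbind(cos(2 * pi * f * t), 0, 0)
  acf <- dipole_autocorrelation(mud, dt, max_lag_fs = 500)
  cref <- 0.5 * cos(2 * pi * f * acf$table$t_fs)
  expect_lt(max(abs(acf$table$C - cref)), 1e-3)  # finite-length correction
})

test_that("white-noise autocorrelation vanishes at nonzero lag", {
  set.seed(1)
  n <- 6000
  mud <- matrix(stats::rnorm(n * 3), n, 3)
  acf <- dipole_autocorrelation(mud, 1, max_lag_fs = 100)
  lag0 <- acf$table$C[1]
  expect_equal(lag0, 3, tolerance = 0.1)
  expect_true(all(abs(acf$table$C[-1]) < 4 * sqrt(3 / (n - 100))))
})

test_that("FFT autocorrelation equals the direct double-loop oracle", {
  set.seed(2)
  mud <- matrix(stats::rnorm(900), 300, 3)
  a <- dipole_autocorrelation(mud, 0.5, 50)
  b <- fqcmd:::autocorrelation_direct(mud, 0.5, 50)
  expect_equal(a$table$C, b$C, tolerance = 1e-10)
  expect_error(dipole_autocorrelation(mud, 0.5, 80), "half")
})

test_that("windowed spectrum peaks at the oscillation frequency", {
  dt <- 0.5
  w_cm <- 1500
  f <- w_cm / units$cm1_per_invfs
  t <- seq(0, 4000, by = dt)
  C <- data.frame(t_fs = t, C = cos(2 * pi * f * t))
  # near-infinite window: peak within one grid spacing
  sp_inf <- windowed_spectrum(C, window_tau_fs = 4000)
  expect_lt(abs(find_band_peak(sp_inf, c(1000, 2000)) - w_cm),
            sp_inf$resolution_cm1)
  # finite window: peak position held, width matches the window transform
  sp <- windowed_spectrum(C, window_tau_fs = 600)
  pk <- find_band_peak(sp, c(1000, 2000))
  expect_lt(abs(pk - w_cm), sp$resolution_cm1)
  half <- sp$table$wavenumber[sp$table$intensity >= 0.5]
  fwhm <- max(half) - min(half)
  # analytic width of the cos^2 taper: transform computed from the window
  w <- ifelse(t <= 600, cos(pi * t / (2 * 600))^2, 0)
  m <- 2^18
  W <- abs(Re(stats::fft(c(w, numeric(m - length(w))))))
  freq <- (0:(m - 1)) / (m * dt) * units$cm1_per_invfs
  Whalf <- freq[which(W >= 0.5 * max(W))]
  fwhm_ref <- 2 * max(Whalf[Whalf < 100])  # one-sided half-width, doubled
  expect_equal(fwhm, fwhm_ref, tolerance = 0.15)
})

test_that("zero correlation gives an identically zero spectrum", {
  C <- data.frame(t_fs = seq(0, 1000, 0.5), C = 0)
  sp <- windowed_spectrum(C, 600)
  expect_true(all(sp$table$intensity == 0))
  expect_error(windowed_spectrum(C, 1200), "exceeds")
})

test_that("band-peak search refines and respects the range", {
  dt <- 0.5
  t <- seq(0, 3000, by = dt)
  f1 <- 700 / units$cm1_per_invfs
  f2 <- 1900 / units$cm1_per_invfs
  C <- data.frame(t_fs = t, C = cos(2 * pi * f1 * t) +
                    0.4 * cos(2 * pi * f2 * t))
  sp <- windowed_spectrum(C, 800)
  expect_lt(abs(find_band_peak(sp, c(400, 1200)) - 700), 2)
  expect_lt(abs(find_band_peak(sp, c(1500, 2400)) - 1900), 2)
  expect_error(find_band_peak(sp, c(4e4, 5e4)), "empty")
})

test_that("peak positions are invariant to normalization and trajectory length", {
  dt <- 0.5
  f <- 1200 / units$cm1_per_invfs
  for (Ttot in c(2400, 4800)) {
    t <- seq(0, Ttot, by = dt)
    C <- data.frame(t_fs = t, C = 5 * cos(2 * pi * f * t) * exp(-t / 2000))
    sp <- windowed_spectrum(C, 600)
    expect_lt(abs(find_band_peak(sp, c(800, 1600)) - 1200),
              1.5 * sp$resolution_cm1)
    expect_equal(max(sp$table$intensity), 1)
  }
})

test_that("gas-phase monomer bands sit at the harmonic normal-mode frequencies", {
  st <- build_liquid_box(structure_spec("monomer", 1, temperature = 50,
                                        seed = 2), qp, 0)
  # independent oracle: mass-weighted Hessian by central differences
  pos0 <- st$config$positions
  n3 <- 9
  h <- 1e-4
  H <- matrix(0, n3, n3)
  for (i in 1:n3) {
    at <- ceiling(i / 3); k <- (i - 1) %% 3 + 1
    pp <- pos0; pp[at, k] <- pp[at, k] + h
    pm <- pos0; pm[at, k] <- pm[at, k] - h
    fp <- water_energy_forces(configuration(pp), st$cell, st$topo, qp)$forces
    fm <- water_energy_forces(configuration(pm), st$cell, st$topo, qp)$forces
    H[i, ] <- -as.numeric(t(fp - fm)) / (2 * h)
  }
  mw <- rep(st$topo$masses, each = 3)
  ev <- eigen((H + t(H)) / 2 / sqrt(outer(mw, mw)), symmetric = TRUE)$values
  modes <- sort(sqrt(pmax(ev, 0)) * units$hartree_cm1, decreasing = TRUE)[1:3]
  sp <- spectrum_from_segments(st, qp, NULL, temperature = 50,
                               n_segments = 4, segment_fs = 1400,
                               equil_fs = 300, reseed_fs = 150,
                               window_tau_fs = 600, seed = 5)
  stretch <- find_band_peak(sp, c(3300, 4300))
  bend <- find_band_peak(sp, c(1300, 1900))
  # low-temperature classical bands approach the harmonic frequencies;
  # residual anharmonicity and window resolution set the tolerance
  expect_lt(abs(stretch - mean(modes[1:2])), 60)
  expect_lt(abs(bend - modes[3]), 60)
})

test_that("spectrum CSV round trip preserves the table", {
  C <- data.frame(t_fs = seq(0, 1000, 0.5),
                  C = cos(0.05 * seq(0, 1000, 0.5)))
  sp <- windowed_spectrum(C, 600)
  f <- tempfile(fileext = ".csv")
  write_spectrum(sp, f, meta = c(temperature = 300))
  back <- read_spectrum(f)
  expect_equal(back$window_tau_fs, 600)
  expect_equal(back$table$intensity, sp$table$intensity, tolerance = 1e-6)
})
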