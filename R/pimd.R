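# Path-integral MD of the ring-polymer system. Convention: each of the P
# beads feels the full physical potential and the composite system is
# sampled at inverse temperature beta/P, with spring frequency
# omega_P = P/(beta hbar); static bead averages then equal exact quantum
# thermal averages in the P -> infinity limit.

#' Ring-polymer normal-mode transform matrix
#'
#' Orthonormal real transform; row 0 is the centroid (bead mean) mode.
#'
#' @param P Bead count.
#' @return List with the P x P matrix `C` (rows = modes), the integer mode
#'   index `kfreq` (0, 1, 1, 2, 2, ...) and a closure `omega(beta)` giving
#'   the free-ring-polymer mode frequencies at inverse temperature `beta`.
#' @export
normal_mode_matrix <- function(P) {
  stopifnot(P >= 1)
  C <- matrix(0, P, P)
  j <- 0:(P - 1)
  C[1, ] <- sqrt(1 / P)
  kfreq <- 0L
  row <- 2
  lmax <- if (P %% 2 == 0) P / 2 - 1 else (P - 1) / 2
  if (lmax >= 1) {
    for (l in seq_len(lmax)) {
      C[row, ] <- sqrt(2 / P) * cos(2 * pi * l * j / P)
      C[row + 1, ] <- sqrt(2 / P) * sin(2 * pi * l * j / P)
      kfreq <- c(kfreq, l, l)
      row <- row + 2
    }
  }
  if (P %% 2 == 0 && P > 1) {
    C[P, ] <- sqrt(1 / P) * (-1)^j
    kfreq <- c(kfreq, as.integer(P / 2))
  }
  list(C = C, kfreq = as.integer(kfreq),
       omega = function(beta) 2 * (P / beta) * sin(pi * kfreq / P))
}

#' Transform between bead and normal-mode coordinates
#'
#' The last dimension of `x` indexes the beads. The transform is the
#' orthogonal ring-polymer mode decomposition scaled so that mode 0 is
#' exactly the arithmetic bead mean (the Cartesian centroid); a round trip
#' is the identity.
#'
#' @param x Matrix or array whose last dimension has length P.
#' @param nm A `normal_mode_matrix(P)` result.
#' @param direction `"to_modes"` or `"to_beads"`.
#' @return Object of the same shape as `x`.
#' @export
normal_mode_transform <- function(x, nm,
                                  direction = c("to_modes", "to_beads")) {
  direction <- match.arg(direction)
  d <- dim(x)
  if (is.null(d)) d <- c(1L, length(x))
  P <- d[length(d)]
  stopifnot(P == nrow(nm$C))
  m <- matrix(x, ncol = P)
  out <- if (direction == "to_modes") m %*% t(nm$C) / sqrt(P)
         else m %*% nm$C * sqrt(P)
  array(out, dim = d)
}

#' Ring-polymer state for the water system
#'
#' All beads start at the classical configuration; bead velocities are drawn
#' from the Maxwell distribution of the composite system (temperature P T).
#'
#' @param config A `configuration` (classical starting point).
#' @param P Bead count (the published protocol uses 32 at 300 K and 64 at
#'   150 K; smaller values are legitimate for scaled-down runs).
#' @param temperature Physical temperature in K.
#' @param topo A `water_topology` (for masses).
#' @param seed Seed for the velocity draw.
#' @return Object of class `ring_polymer_state` with bead positions and
#'   velocities as (n_atoms, 3, P) arrays, `P`, `beta` (1/hartree).
#' @export
ring_polymer_state <- function(config, P, temperature, topo, seed = 1) {
  stopifnot(P >= 1)
  nat <- nrow(config$positions)
  pos <- array(rep(as.numeric(config$positions), P), dim = c(nat, 3, P))
  set.seed(as.integer(seed))
  kTP <- .fq$kB * temperature * P
  vel <- array(stats::rnorm(nat * 3 * P), dim = c(nat, 3, P)) *
    sqrt(kTP / topo$masses)
  structure(list(positions = pos, velocities = vel, P = as.integer(P),
                 beta = 1 / (.fq$kB * temperature),
                 temperature = temperature),
            class = "ring_polymer_state")
}

#' PIMD run for the water system (compiled engine)
#'
#' OBABO splitting: half-step per-normal-mode stochastic thermostat,
#' half-step velocity update from the physical forces, exact free-ring-
#' polymer evolution in normal modes, then the mirror half-steps. Internal
#' modes are critically damped (friction 2 omega_k); the centroid mode is
#' thermostatted weakly with time constant `tau_fs`.
#'
#' @param state A `ring_polymer_state`.
#' @param cell A `simulation_cell`.
#' @param topo A `water_topology`.
#' @param params A `water_params`.
#' @param settings An `integrator_settings` (its `temperature` must match
#'   the state; `thermostat = "none"` gives constant-energy ring-polymer
#'   dynamics).
#' @param n_steps Number of steps.
#' @param correction Optional `correction_potential` applied to every bead.
#' @param record_stride Stride for scalar records (energies, kinetic-energy
#'   estimators).
#' @param frame_stride Stride for bead-frame records (0 = none).
#' @return A `pimd_trajectory` list with times (fs), per-record potential /
#'   kinetic / spring energies, primitive and centroid-virial kinetic-energy
#'   estimators, bead frames (n_atoms, 3, P, n_frames) and the final state.
#' @export
run_water_pimd <- function(state, cell, topo, params, settings, n_steps,
                           correction = NULL, record_stride = 5,
                           frame_stride = 0) {
  params <- resolve_cutoff(params, cell)
  P <- state$P
  nm <- normal_mode_matrix(P)
  omegak <- nm$omega(state$beta)
  res <- run_water_pimd_cpp(state$positions, state$velocities, P,
                            cell$edges, unclass(params),
                            corr_to_cpp(correction),
                            nm$C, omegak,
                            fs_to_au(settings$dt_fs), as.integer(n_steps),
                            state$beta, 1 / fs_to_au(settings$tau_fs),
                            as.integer(settings$thermostat == "langevin"),
                            settings$seed,
                            as.integer(record_stride),
                            as.integer(frame_stride))
  final <- structure(list(positions = res$positions,
                          velocities = res$velocities, P = P,
                          beta = state$beta,
                          temperature = state$temperature),
                     class = "ring_polymer_state")
  structure(list(time_fs = au_to_fs(res$time), pe = res$pe, ke = res$ke,
                 spring = res$spring, ke_primitive = res$ke_primitive,
                 ke_virial = res$ke_virial, frames = res$frames,
                 frame_time_fs = au_to_fs(res$frame_time), final = final,
                 P = P, settings = settings),
            class = "pimd_trajectory")
}

#' One PIMD step / short PIMD run for a generic (small) system, in R
#'
#' Same OBABO splitting as the compiled engine, for arbitrary potentials:
#' used by the one-dimensional oracle systems where closed-form quantum
#' results are available. `force_fn` receives a P x n_dof matrix of bead
#' positions and must return the matrix of forces (full potential per bead).
#'
#' @param positions,velocities P x n_dof matrices.
#' @param mass Mass (scalar or per-dof vector, m_e).
#' @param force_fn Bead-wise force function.
#' @param beta Inverse temperature (1/hartree).
#' @param settings An `integrator_settings`.
#' @param n_steps Number of steps.
#' @param record_stride Record stride.
#' @return List with `time_fs`, `positions` (n_rec x P x n_dof array),
#'   `final` state, and per-record spring energy.
#' @export
run_pimd_r <- function(positions, velocities, mass, force_fn, beta,
                       settings, n_steps, record_stride = 1) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  P <- nrow(positions)
  nd <- ncol(positions)
  mass <- rep_len(mass, nd)
  nm <- normal_mode_matrix(P)
  omegak <- nm$omega(beta)
  dt <- fs_to_au(settings$dt_fs)
  betaP <- beta / P
  thermo <- settings$thermostat == "langevin"
  gammak <- ifelse(nm$kfreq == 0, 1 / fs_to_au(settings$tau_fs), 2 * omegak)
  tc1 <- exp(-0.5 * gammak * dt)
  tc2 <- sqrt(1 - tc1^2)
  ec <- cos(omegak * dt)
  es <- sin(omegak * dt)
  sovw <- ifelse(omegak > 0, es / omegak, dt)
  set.seed(settings$seed)
  mmat <- matrix(mass, P, nd, byrow = TRUE)
  sig <- sqrt(1 / (betaP * mmat))
  thermo_half <- function(v) {
    vn <- nm$C %*% v
    vn <- tc1 * vn + tc2 * sig * matrix(stats::rnorm(P * nd), P, nd)
    t(nm$C) %*% vn
  }
  f <- force_fn(positions)
  nrec <- n_steps %/% record_stride
  rec <- array(NA_real_, dim = c(nrec, P, nd))
  rec_t <- numeric(nrec)
  rec_spring <- numeric(nrec)
  omegaP <- P / beta
  irec <- 0
  for (step in seq_len(n_steps)) {
    if (thermo) velocities <- thermo_half(velocities)
    velocities <- velocities + 0.5 * dt * f / mmat
    xn <- nm$C %*% positions
    vn <- nm$C %*% velocities
    xn2 <- ec * xn + sovw * vn
    vn2 <- -omegak * es * xn + ec * vn
    positions <- t(nm$C) %*% xn2
    velocities <- t(nm$C) %*% vn2
    f <- force_fn(positions)
    velocities <- velocities + 0.5 * dt * f / mmat
    if (thermo) velocities <- thermo_half(velocities)
    if (step %% record_stride == 0) {
      irec <- irec + 1
      rec[irec, , ] <- positions
      rec_t[irec] <- au_to_fs(step * dt)
      rec_spring[irec] <- if (P == 1) 0 else {
        dxp <- positions - positions[c(2:P, 1), , drop = FALSE]
        sum(0.5 * mmat * omegaP^2 * dxp^2)
      }
    }
  }
  list(time_fs = rec_t, positions = rec, spring = rec_spring,
       final = list(positions = positions, velocities = velocities))
}
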