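# Classical propagation: NVE and local stochastic (Langevin) NVT with the
# BAOAB splitting. The compiled engine drives the water model; a plain-R
# engine with the same splitting serves arbitrary user potentials (the toy
# systems used for oracle tests).

#' Integrator settings
#'
#' @param dt_fs Time step in fs (default 0.25).
#' @param thermostat `"none"` (NVE) or `"langevin"` (local stochastic NVT).
#' @param tau_fs Thermostat friction time constant in fs (default 100).
#' @param temperature Target temperature in K (required when thermostatted).
#' @param seed Integer RNG seed; every stochastic component of a run draws
#'   from a generator seeded from this value.
#' @return An object of class `integrator_settings`.
#' @export
integrator_settings <- function(dt_fs = 0.25,
                                thermostat = c("none", "langevin"),
                                tau_fs = 100, temperature = 300, seed = 1) {
  thermostat <- match.arg(thermostat)
  if (dt_fs <= 0) stop("time step must be positive")
  if (thermostat != "none" && temperature <= 0)
    stop("temperature must be positive when thermostatted")
  structure(list(dt_fs = dt_fs, thermostat = thermostat, tau_fs = tau_fs,
                 temperature = temperature, seed = as.integer(seed)),
            class = "integrator_settings")
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses Per-degree-of-freedom masses (m_e); recycled across the
#'   three Cartesian components when `n_dim = 3`.
#' @param temperature Temperature in K.
#' @param seed RNG seed.
#' @param n_dim Number of Cartesian components per particle.
#' @return Matrix (length(masses) x n_dim) of velocities in atomic units.
#' @export
maxwell_velocities <- function(masses, temperature, seed, n_dim = 3) {
  set.seed(as.integer(seed))
  kT <- .fq$kB * temperature
  v <- matrix(stats::rnorm(length(masses) * n_dim), length(masses), n_dim)
  v * sqrt(kT / masses)
}

#' One velocity-Verlet step (generic potential)
#'
#' Advances positions and velocities by one symplectic step; time reversible
#' (momentum reversal retraces the trajectory exactly in exact arithmetic).
#'
#' @param position,velocity Numeric vectors (any dimension).
#' @param mass Mass per degree of freedom (scalar or vector, m_e).
#' @param force_fn Function `position -> list(energy =, forces =)` in atomic
#'   units.
#' @param dt_fs Time step in fs.
#' @param forces Forces at the current position, if already known.
#' @return List with `position`, `velocity`, `forces`, `energy`.
#' @export
velocity_verlet_step <- function(position, velocity, mass, force_fn, dt_fs,
                                 forces = NULL) {
  dt <- fs_to_au(dt_fs)
  if (is.null(forces)) forces <- force_fn(position)$forces
  if (any(!is.finite(forces))) {
    bad <- which(!is.finite(forces))[1]
    stop("non-finite force on degree of freedom ", bad)
  }
  velocity <- velocity + 0.5 * dt * forces / mass
  position <- position + dt * velocity
  fe <- force_fn(position)
  if (any(!is.finite(fe$forces))) {
    bad <- which(!is.finite(fe$forces))[1]
    stop("non-finite force on degree of freedom ", bad)
  }
  velocity <- velocity + 0.5 * dt * fe$forces / mass
  list(position = position, velocity = velocity, forces = fe$forces,
       energy = fe$energy)
}

#' Thermostatted (or NVE) run with a generic potential
#'
#' BAOAB Langevin dynamics (or velocity Verlet when `thermostat = "none"`)
#' for an arbitrary potential contract; used by the analytic toy systems.
#' All randomness comes from the seed in `settings`.
#'
#' @param position,velocity Initial state (numeric vectors).
#' @param mass Mass per degree of freedom (m_e).
#' @param force_fn Function `position -> list(energy =, forces =)`.
#' @param settings An `integrator_settings`.
#' @param n_steps Number of steps.
#' @param record_stride Record every this many steps.
#' @return A `trajectory_record` list: `time_fs`, `positions` (matrix,
#'   one row per record), `velocities`, `pe`, `ke`.
#' @export
run_md_r <- function(position, velocity, mass, force_fn, settings, n_steps,
                     record_stride = 1) {
  dt <- fs_to_au(settings$dt_fs)
  kT <- .fq$kB * settings$temperature
  langevin <- settings$thermostat == "langevin"
  if (langevin) {
    gamma <- 1 / fs_to_au(settings$tau_fs)
    c1 <- exp(-gamma * dt)
    c2 <- sqrt(1 - c1^2)
    set.seed(settings$seed)
  }
  nd <- length(position)
  mass <- rep_len(mass, nd)
  nrec <- n_steps %/% record_stride
  out_x <- matrix(NA_real_, nrec, nd)
  out_v <- matrix(NA_real_, nrec, nd)
  out_pe <- numeric(nrec)
  out_ke <- numeric(nrec)
  out_t <- numeric(nrec)
  f <- force_fn(position)$forces
  irec <- 0
  for (step in seq_len(n_steps)) {
    velocity <- velocity + 0.5 * dt * f / mass
    position <- position + 0.5 * dt * velocity
    if (langevin)
      velocity <- c1 * velocity +
        c2 * sqrt(kT / mass) * stats::rnorm(nd)
    position <- position + 0.5 * dt * velocity
    fe <- force_fn(position)
    f <- fe$forces
    if (any(!is.finite(f))) {
      bad <- which(!is.finite(f))[1]
      stop("non-finite force on degree of freedom ", bad, " at step ", step)
    }
    velocity <- velocity + 0.5 * dt * f / mass
    if (step %% record_stride == 0) {
      irec <- irec + 1
      out_t[irec] <- au_to_fs(step * dt)
      out_x[irec, ] <- position
      out_v[irec, ] <- velocity
      out_pe[irec] <- fe$energy
      out_ke[irec] <- sum(0.5 * mass * velocity^2)
    }
  }
  structure(list(time_fs = out_t, positions = out_x, velocities = out_v,
                 pe = out_pe, ke = out_ke,
                 final = list(position = position, velocity = velocity),
                 settings = settings),
            class = "trajectory_record")
}

#' Molecular dynamics of the water system (compiled engine)
#'
#' Classical NVE or Langevin-NVT propagation of the full water model (plus
#' any correction potential) with periodic boundary conditions. Energies,
#' dipole and dipole derivative are recorded every `record_stride` steps;
#' full configurations every `frame_stride` steps (0 disables frames).
#'
#' @param config A `configuration` (positions and velocities).
#' @param cell A `simulation_cell`.
#' @param topo A `water_topology`.
#' @param params A `water_params`.
#' @param settings An `integrator_settings`.
#' @param n_steps Number of steps.
#' @param correction Optional `correction_potential`.
#' @param record_stride Observable recording stride (default 2 steps).
#' @param frame_stride Configuration recording stride (default 0 = none).
#' @return A `water_trajectory` list: `time_fs`, `pe`, `ke` (hartree), `mu`
#'   (e a0), `mudot` (e a0 / fs), `frames` (n_atoms x 3 x n_frames, a0),
#'   `frame_time_fs`, the final `configuration`, and the count of
#'   below-table extrapolations seen by the correction tables.
#' @export
run_water_md <- function(config, cell, topo, params, settings, n_steps,
                         correction = NULL, record_stride = 2,
                         frame_stride = 0) {
  check_topology(config, topo)
  params <- resolve_cutoff(params, cell)
  res <- run_water_md_cpp(config$positions, config$velocities, cell$edges,
                          unclass(params), corr_to_cpp(correction),
                          fs_to_au(settings$dt_fs), as.integer(n_steps),
                          .fq$kB * settings$temperature,
                          if (settings$thermostat == "langevin")
                            1 / fs_to_au(settings$tau_fs) else 0,
                          as.integer(settings$thermostat == "langevin"),
                          settings$seed,
                          as.integer(record_stride),
                          as.integer(frame_stride))
  structure(list(
    time_fs = au_to_fs(res$time), pe = res$pe, ke = res$ke, mu = res$mu,
    mudot = res$mudot / .fq$autime_fs,
    frames = res$frames, frame_time_fs = au_to_fs(res$frame_time),
    final = configuration(res$positions, res$velocities),
    n_extrapolated = res$n_extrapolated,
    settings = settings, n_steps = n_steps,
    temperature = settings$temperature
  ), class = "water_trajectory")
}

#' Instantaneous kinetic temperature of a trajectory record
#'
#' @param traj A `water_trajectory`.
#' @param n_dof Number of degrees of freedom (defaults to 3 x atoms).
#' @return Vector of temperatures in K.
#' @export
kinetic_temperature <- function(traj, n_dof) {
  2 * traj$ke / (n_dof * .fq$kB)
}
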