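# Classical q-TIP4P/f-style flexible four-site water model: energies, forces
# and the system dipole under orthorhombic periodic boundary conditions.
#
# Electrostatics are damped-shifted-force (Wolf-style) real-space Coulomb
# among the H and M charge sites of distinct molecules, which gives smooth
# forces that vanish at the cutoff; Lennard-Jones acts between oxygens and is
# likewise force-shifted. Atom ordering is O,H,H per molecule throughout.

#' Read water-model parameters from a key-value file
#'
#' Parses a flat `key = value` parameter block (in the published units:
#' Angstrom, kcal/mol, degrees, amu) and converts to atomic units.
#'
#' @param file Path to the parameter file.
#' @return An object of class `water_params`: a named list in atomic units
#'   with fields `r_eq`, `D_r`, `a_r`, `k_theta`, `theta_eq`, `sigma_OO`,
#'   `eps_OO`, `q_H`, `gamma_M`, `m_O`, `m_H`, plus the electrostatics
#'   controls `r_cut`, `dsf_alpha` and `dsf`.
#' @export
read_water_params <- function(file) {
  kv <- read_keyvalue(file)
  need <- c("r_eq_angstrom", "D_r_kcalmol", "a_r_invangstrom", "theta_eq_deg",
            "k_theta_kcalmol", "sigma_OO_angstrom", "eps_OO_kcalmol",
            "q_H_e", "gamma_M", "m_O_amu", "m_H_amu")
  miss <- setdiff(need, names(kv))
  if (length(miss) > 0)
    stop("parameter file is missing: ", paste(miss, collapse = ", "))
  num <- function(k) as.numeric(kv[[k]])
  p <- list(
    r_eq     = num("r_eq_angstrom") / .fq$bohr_A,
    D_r      = num("D_r_kcalmol") / .fq$hartree_kcal,
    a_r      = num("a_r_invangstrom") * .fq$bohr_A,
    theta_eq = num("theta_eq_deg") * pi / 180,
    k_theta  = num("k_theta_kcalmol") / .fq$hartree_kcal,
    sigma_OO = num("sigma_OO_angstrom") / .fq$bohr_A,
    eps_OO   = num("eps_OO_kcalmol") / .fq$hartree_kcal,
    q_H      = num("q_H_e"),
    gamma_M  = num("gamma_M"),
    m_O      = num("m_O_amu") * .fq$amu_me,
    m_H      = num("m_H_amu") * .fq$amu_me,
    r_cut    = NA_real_,                 # resolved per cell when used
    dsf_alpha = NA_real_,                # resolved as 2/r_cut when used
    dsf      = TRUE
  )
  validate_water_params(p)
  class(p) <- "water_params"
  p
}

validate_water_params <- function(p) {
  pos <- c("D_r", "a_r", "k_theta", "sigma_OO", "eps_OO", "r_eq",
           "m_O", "m_H")
  for (f in pos)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop("water parameter ", f, " must be positive")
  if (p$gamma_M <= 0 || p$gamma_M >= 1)
    stop("gamma_M must lie in (0, 1)")
  invisible(p)
}

#' Default q-TIP4P/f parameters
#'
#' Reads the packaged q-TIP4P/f parameter file. The per-molecule charge is
#' neutral by construction (the M site carries -2 q_H).
#'
#' @return A `water_params` object in atomic units.
#' @export
qtip4pf_params <- function() {
  read_water_params(system.file("extdata", "qtip4pf.params",
                                package = "fqcmd", mustWork = TRUE))
}

#' Orthorhombic simulation cell
#'
#' @param edges Numeric vector of three edge lengths in a0 (a scalar is
#'   recycled to a cubic cell).
#' @param periodic Logical, periodic boundary conditions (all three axes).
#' @return An object of class `simulation_cell`.
#' @export
simulation_cell <- function(edges, periodic = TRUE) {
  if (length(edges) == 1) edges <- rep(edges, 3)
  stopifnot(length(edges) == 3)
  if (any(!is.finite(edges)) || any(edges <= 0))
    stop("cell edges must be positive and finite")
  structure(list(edges = as.numeric(edges), periodic = periodic),
            class = "simulation_cell")
}

half_min_edge <- function(cell) min(cell$edges) / 2

resolve_cutoff <- function(params, cell) {
  rc <- params$r_cut
  if (is.na(rc)) rc <- half_min_edge(cell)
  if (rc > half_min_edge(cell) + 1e-9)
    stop("interaction cutoff (", signif(rc, 6),
         " a0) exceeds half the smallest cell edge (",
         signif(half_min_edge(cell), 6), " a0)")
  params$r_cut <- rc
  # damped-shifted-force damping: alpha * r_cut = 2 unless set explicitly
  if (is.na(params$dsf_alpha)) params$dsf_alpha <- 2 / rc
  params
}

#' System topology for an O,H,H-ordered water system
#'
#' @param n_mol Number of molecules.
#' @param params `water_params` providing the atomic masses.
#' @return An object of class `water_topology` with the species vector,
#'   per-atom masses (m_e), molecule ids and atom count.
#' @export
water_topology <- function(n_mol, params = qtip4pf_params()) {
  stopifnot(n_mol >= 1)
  structure(list(
    n_mol = as.integer(n_mol),
    n_atoms = 3L * as.integer(n_mol),
    species = rep(c("O", "H", "H"), n_mol),
    masses = rep(c(params$m_O, params$m_H, params$m_H), n_mol),
    mol_id = rep(seq_len(n_mol), each = 3L)
  ), class = "water_topology")
}

#' Phase-space configuration
#'
#' @param positions n_atoms x 3 matrix of positions (a0).
#' @param velocities Optional n_atoms x 3 matrix of velocities (a0 per
#'   atomic time unit); zeros if omitted.
#' @return An object of class `configuration`.
#' @export
configuration <- function(positions, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (any(!is.finite(positions))) stop("non-finite coordinates")
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 3)
  } else {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions)))
      stop("velocity array shape does not match positions")
  }
  structure(list(positions = positions, velocities = velocities),
            class = "configuration")
}

check_topology <- function(config, topo) {
  if (nrow(config$positions) != topo$n_atoms)
    stop("configuration has ", nrow(config$positions),
         " atoms but topology expects ", topo$n_atoms)
  invisible(TRUE)
}

corr_to_cpp <- function(correction) {
  if (is.null(correction)) return(list())
  unclass_correction(correction)
}

force_energy <- function(res) {
  structure(list(energy = res$energy, forces = res$forces,
                 components = res$components,
                 n_extrapolated = res$n_extrapolated),
            class = "force_energy")
}

#' Intramolecular energy and forces
#'
#' Sum over molecules of the quartic-expanded Morse stretch for both O-H
#' bonds plus the harmonic H-O-H bend, with exact analytic gradients.
#'
#' @param config A `configuration`.
#' @param topo A `water_topology`.
#' @param params A `water_params`.
#' @param cell Optional `simulation_cell` (intramolecular vectors use the
#'   minimum image when given; an effectively infinite cell otherwise).
#' @param correction Optional `correction_potential`; its intramolecular
#'   polynomial terms are included.
#' @return A `force_energy`: total energy (hartree), n_atoms x 3 forces
#'   (hartree/a0) and an energy-component breakdown.
#' @export
intra_energy_forces <- function(config, topo, params, cell = NULL,
                                correction = NULL) {
  check_topology(config, topo)
  edges <- if (is.null(cell)) rep(1e12, 3) else cell$edges
  force_energy(water_energy_forces_cpp(config$positions, edges,
                                       unclass(params),
                                       corr_to_cpp(correction),
                                       TRUE, FALSE))
}

#' Intermolecular energy and forces
#'
#' Force-shifted Lennard-Jones between oxygens plus damped-shifted-force
#' Coulomb among the H and M charge sites of distinct molecules, with
#' minimum-image periodic boundary conditions. Forces on the massless M site
#' are redistributed to O and H by the chain rule of its construction.
#'
#' @inheritParams intra_energy_forces
#' @param cell A `simulation_cell`.
#' @return A `force_energy`.
#' @export
inter_energy_forces <- function(config, cell, topo, params,
                                correction = NULL) {
  check_topology(config, topo)
  params <- resolve_cutoff(params, cell)
  force_energy(water_energy_forces_cpp(config$positions, cell$edges,
                                       unclass(params),
                                       corr_to_cpp(correction),
                                       FALSE, TRUE))
}

#' Total potential energy and forces
#'
#' @inheritParams inter_energy_forces
#' @return A `force_energy` with both intra- and intermolecular terms (and
#'   any correction-potential terms).
#' @export
water_energy_forces <- function(config, cell, topo, params,
                                correction = NULL) {
  check_topology(config, topo)
  params <- resolve_cutoff(params, cell)
  force_energy(water_energy_forces_cpp(config$positions, cell$edges,
                                       unclass(params),
                                       corr_to_cpp(correction),
                                       TRUE, TRUE))
}

#' System dipole moment and its time derivative
#'
#' The dipole is the charge-weighted sum over H and M sites,
#' `mu = sum(q_site r_site)`; with the M site at
#' `gamma_M r_O + (1 - gamma_M)(r_H1 + r_H2)/2` the per-molecule contribution
#' reduces to `q_H gamma_M (d1 + d2)` with `d_i` the O->H_i minimum-image
#' displacement, so the result is origin independent for neutral molecules.
#' The time derivative applies the same chain rule to the velocities.
#'
#' @inheritParams intra_energy_forces
#' @param velocities If `TRUE` (default) and the configuration carries
#'   velocities, the dipole derivative is returned as well.
#' @return List with `mu` (e a0) and, when available, `mudot` (e a0 per
#'   atomic time unit).
#' @export
system_dipole <- function(config, topo, params, cell = NULL,
                          velocities = TRUE) {
  check_topology(config, topo)
  edges <- if (is.null(cell)) rep(1e12, 3) else cell$edges
  vel <- if (velocities) config$velocities else NULL
  water_dipole_cpp(config$positions, vel, edges, unclass(params))
}

# flat "key = value" text, '#' comments
read_keyvalue <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop("cannot parse line: ", ln)
    kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}
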