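# Deterministic, seedable generators for every input the pipeline needs:
# liquid water boxes, proton-disordered hexagonal-ice cells, the gas-phase
# monomer, and analytic toy systems used as test oracles. All generators
# are pure functions of their spec + seed.

#' Structure specification
#'
#' @param phase One of "liquid", "iceIh", "monomer".
#' @param n_molecules Molecule count (96 for iceIh on the reference cell).
#' @param cell_edges Optional cell edges (a0); defaults: the reference
#'   density 216/35.24^3 a0^-3 for liquid (cubic), the reference
#'   orthorhombic cell scaled to the molecule count for ice.
#' @param temperature Temperature (K) for the velocity draw.
#' @param seed Integer seed.
#' @return Object of class `structure_spec`.
#' @export
structure_spec <- function(phase = c("liquid", "iceIh", "monomer"),
                           n_molecules, cell_edges = NULL,
                           temperature = 300, seed = 1) {
  phase <- match.arg(phase)
  if (!is.null(cell_edges) && any(cell_edges <= 0))
    stop("cell edges must be positive")
  structure(list(phase = phase, n_molecules = as.integer(n_molecules),
                 cell_edges = cell_edges, temperature = temperature,
                 seed = as.integer(seed)),
            class = "structure_spec")
}

# reference liquid number density (a0^-3): 216 molecules in a 35.24 a0 box
reference_density <- function() 216 / 35.24^3

#' Build a liquid water box
#'
#' Molecules at their equilibrium geometry are placed on a jittered cubic
#' lattice with random orientations (no O-O pair closer than 4.5 a0),
#' given Maxwell-Boltzmann velocities, and optionally pre-equilibrated with
#' a short strongly-coupled Langevin run so downstream stages start from a
#' thermalized state. Fully reproducible from the seed.
#'
#' @param spec A `structure_spec` with `phase = "liquid"` (or "monomer").
#' @param params A `water_params`.
#' @param equilibrate_steps Pre-equilibration steps (default 500; 0 gives
#'   the raw lattice).
#' @return Object of class `water_structure`: `config`, `cell`, `topo`,
#'   `spec`.
#' @export
build_liquid_box <- function(spec, params = qtip4pf_params(),
                             equilibrate_steps = 500) {
  N <- spec$n_molecules
  edges <- spec$cell_edges
  if (is.null(edges)) {
    edges <- if (spec$phase == "monomer" || N == 1) rep(40, 3)
             else rep((N / reference_density())^(1 / 3), 3)
  }
  if (length(edges) == 1) edges <- rep(edges, 3)
  cell <- simulation_cell(edges)
  topo <- water_topology(N, params)
  if (spec$phase == "monomer" || N == 1) {
    pos <- canonical_molecule(params$r_eq, params$r_eq, params$theta_eq)
    pos <- sweep(pos, 2, -edges / 2)  # center of the box
    set.seed(spec$seed)
    vel <- maxwell_velocities(topo$masses, spec$temperature, spec$seed)
    return(structure(list(config = configuration(pos, vel), cell = cell,
                          topo = topo, spec = spec),
                     class = "water_structure"))
  }

  set.seed(spec$seed)
  n_side <- ceiling(N^(1 / 3))
  spacing <- edges / n_side
  if (min(spacing) <= 4.55)
    stop("density too high: lattice spacing ", signif(min(spacing), 4),
         " a0 cannot guarantee a 4.5 a0 O-O separation")
  jitter_amp <- min(0.1 * min(spacing), (min(spacing) - 4.5) / 2 - 0.02)
  grid <- as.matrix(expand.grid(x = 0:(n_side - 1), y = 0:(n_side - 1),
                                z = 0:(n_side - 1)))
  sites <- sweep(grid, 2, spacing, "*")
  sites <- sweep(sites, 2, spacing / 2, "+")
  sites <- sites[sample(nrow(sites), N), , drop = FALSE]
  sites <- sites + matrix(stats::runif(3 * N, -jitter_amp, jitter_amp), N, 3)

  pos <- matrix(NA_real_, 3 * N, 3)
  for (m in seq_len(N)) {
    U <- random_rotation()
    mol <- canonical_molecule(params$r_eq, params$r_eq, params$theta_eq)
    pos[(3 * m - 2):(3 * m), ] <- sweep(mol %*% t(U), 2, -sites[m, ])
  }
  vel <- maxwell_velocities(topo$masses, spec$temperature,
                            derive_seed(spec$seed, 7L))
  config <- configuration(pos, vel)
  st <- structure(list(config = config, cell = cell, topo = topo,
                       spec = spec), class = "water_structure")
  if (equilibrate_steps > 0) {
    settings <- integrator_settings(dt_fs = 0.25, thermostat = "langevin",
                                    tau_fs = 20,
                                    temperature = spec$temperature,
                                    seed = derive_seed(spec$seed, 11L))
    run <- run_water_md(config, cell, topo, params, settings,
                        n_steps = equilibrate_steps,
                        record_stride = equilibrate_steps)
    st$config <- run$final
  }
  st
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  quaternion_to_rotation(q)
}

#' Build a proton-disordered hexagonal-ice cell
#'
#' Oxygens sit on the hexagonal-diamond (lonsdaleite) lattice commensurate
#' with the orthorhombic cell; protons are assigned by a seeded
#' rearrangement that enforces the Bernal-Fowler ice rules (two covalent H
#' per O, one H per O-O hydrogen bond), followed by directed-loop reversals
#' that reduce the net dipole below `max_dipole`. Two covalent H atoms are
#' placed at the equilibrium bond length along the donated hydrogen bonds.
#'
#' @param spec A `structure_spec` with `phase = "iceIh"`; the reference
#'   cell (96 molecules, 25.62 x 29.58 x 27.89 a0) is the default.
#' @param params A `water_params`.
#' @param max_dipole Net-dipole target in e a0 (default 0.5).
#' @param max_moves Loop-move budget for the dipole reduction.
#' @return A `water_structure`; also carries the hydrogen-bond `graph`
#'   (edge list with donor orientation).
#' @export
build_ice_cell <- function(spec, params = qtip4pf_params(),
                           max_dipole = 0.5, max_moves = 50000) {
  if (spec$phase != "iceIh") stop("spec phase must be iceIh")
  edges <- spec$cell_edges
  if (is.null(edges)) edges <- c(25.62, 29.58, 27.89)
  cell <- simulation_cell(edges)

  oxy <- ice_oxygen_lattice(edges)
  if (nrow(oxy) != spec$n_molecules)
    stop("ice lattice for this cell has ", nrow(oxy),
         " molecules; spec requests ", spec$n_molecules)
  N <- nrow(oxy)
  topo <- water_topology(N, params)

  # O-O neighbor graph (4 hydrogen bonds per O)
  bond_cut <- 5.8
  el <- list()
  for (i in seq_len(N - 1)) {
    d <- sweep(oxy[(i + 1):N, , drop = FALSE], 2, oxy[i, ])
    d <- d - rep(edges, each = nrow(d)) * round(d / rep(edges, each = nrow(d)))
    r <- sqrt(rowSums(d^2))
    hits <- which(r < bond_cut)
    if (length(hits) > 0)
      el[[length(el) + 1]] <- cbind(i, i + hits)
  }
  edge_mat <- do.call(rbind, el)
  n_edge <- nrow(edge_mat)
  deg <- tabulate(c(edge_mat), nbins = N)
  if (any(deg != 4))
    stop("oxygen lattice is not 4-coordinated (degrees ",
         paste(range(deg), collapse = "-"), ")")

  set.seed(spec$seed)
  # dir[e] = 1: edge_mat[e,1] donates; -1: edge_mat[e,2] donates
  dir <- sample(c(1L, -1L), n_edge, replace = TRUE)
  donations <- function(dir) {
    don <- numeric(N)
    don_tab1 <- tabulate(edge_mat[dir == 1L, 1], nbins = N)
    don_tab2 <- tabulate(edge_mat[dir == -1L, 2], nbins = N)
    don_tab1 + don_tab2
  }
  don <- donations(dir)
  budget <- 200L * n_edge
  tries <- 0L
  edges_of <- lapply(seq_len(N), function(i)
    which(edge_mat[, 1] == i | edge_mat[, 2] == i))
  while (any(don != 2) && tries < budget) {
    tries <- tries + 1L
    over <- which(don > 2)
    i <- if (length(over) > 0) over[sample.int(length(over), 1)] else
      which(don < 2)[1]
    ei <- edges_of[[i]]
    out_e <- ei[(edge_mat[ei, 1] == i & dir[ei] == 1L) |
                (edge_mat[ei, 2] == i & dir[ei] == -1L)]
    in_e <- setdiff(ei, out_e)
    flip <- if (don[i] > 2) out_e[sample.int(length(out_e), 1)] else
      in_e[sample.int(length(in_e), 1)]
    e1 <- edge_mat[flip, 1]; e2 <- edge_mat[flip, 2]
    dir[flip] <- -dir[flip]
    for (nd in c(e1, e2)) {
      ei2 <- edges_of[[nd]]
      don[nd] <- sum((edge_mat[ei2, 1] == nd & dir[ei2] == 1L) |
                     (edge_mat[ei2, 2] == nd & dir[ei2] == -1L))
    }
  }
  if (any(don != 2))
    stop("ice-rule assignment failed after ", budget,
         " moves (seed ", spec$seed, ")")

  # dipole of a proton configuration (e a0): q_H gamma_M sum(d1 + d2)
  bond_vec <- function(i, j) {
    d <- oxy[j, ] - oxy[i, ]
    d - edges * round(d / edges)
  }
  mol_dipole_sum <- function(dir) {
    mu <- c(0, 0, 0)
    for (e in seq_len(n_edge)) {
      i <- if (dir[e] == 1L) edge_mat[e, 1] else edge_mat[e, 2]
      j <- if (dir[e] == 1L) edge_mat[e, 2] else edge_mat[e, 1]
      d <- bond_vec(i, j)
      mu <- mu + d / sqrt(sum(d^2)) * params$r_eq
    }
    params$q_H * params$gamma_M * mu
  }
  mu <- mol_dipole_sum(dir)
  out_edges_of <- function(dir, i) {
    ei <- edges_of[[i]]
    ei[(edge_mat[ei, 1] == i & dir[ei] == 1L) |
       (edge_mat[ei, 2] == i & dir[ei] == -1L)]
  }
  moves <- 0L
  while (sqrt(sum(mu^2)) > max_dipole && moves < max_moves) {
    moves <- moves + 1L
    # random walk along donated bonds until a node repeats -> directed loop
    start <- sample.int(N, 1)
    path <- start
    repeat {
      cur <- path[length(path)]
      oe <- out_edges_of(dir, cur)
      e <- oe[sample.int(length(oe), 1)]
      nxt <- if (edge_mat[e, 1] == cur) edge_mat[e, 2] else edge_mat[e, 1]
      if (nxt %in% path) {
        loop <- c(path[which(path == nxt):length(path)], nxt)
        break
      }
      path <- c(path, nxt)
    }
    loop_edges <- integer(length(loop) - 1)
    ok <- TRUE
    for (k in seq_len(length(loop) - 1)) {
      i <- loop[k]; j <- loop[k + 1]
      e <- edges_of[[i]][edge_mat[edges_of[[i]], 1] == i &
                           edge_mat[edges_of[[i]], 2] == j |
                         edge_mat[edges_of[[i]], 2] == i &
                           edge_mat[edges_of[[i]], 1] == j]
      e <- e[1]
      # must currently be donated i -> j
      don_ij <- (edge_mat[e, 1] == i && dir[e] == 1L) ||
        (edge_mat[e, 2] == i && dir[e] == -1L)
      if (!don_ij) { ok <- FALSE; break }
      loop_edges[k] <- e
    }
    if (!ok) next
    new_dir <- dir
    new_dir[loop_edges] <- -new_dir[loop_edges]
    mu_new <- mol_dipole_sum(new_dir)
    if (sum(mu_new^2) < sum(mu^2)) {
      dir <- new_dir
      mu <- mu_new
    }
  }
  if (sqrt(sum(mu^2)) > max_dipole)
    stop("could not reduce the ice-cell dipole below ", max_dipole,
         " e a0 within ", max_moves, " loop moves (seed ", spec$seed, ")")

  # place H atoms along the two donated bonds of each O
  pos <- matrix(NA_real_, 3 * N, 3)
  for (i in seq_len(N)) {
    oe <- out_edges_of(dir, i)
    acceptors <- ifelse(edge_mat[oe, 1] == i, edge_mat[oe, 2],
                        edge_mat[oe, 1])
    pos[3 * i - 2, ] <- oxy[i, ]
    for (k in 1:2) {
      d <- bond_vec(i, acceptors[k])
      u <- d / sqrt(sum(d^2))
      pos[3 * i - 2 + k, ] <- oxy[i, ] + params$r_eq * u
    }
  }
  vel <- maxwell_velocities(topo$masses, spec$temperature,
                            derive_seed(spec$seed, 7L))
  structure(list(config = configuration(pos, vel), cell = cell,
                 topo = topo, spec = spec,
                 graph = list(edges = edge_mat, donor_dir = dir),
                 net_dipole = mu),
            class = "water_structure")
}

# Oxygen sublattice: hexagonal diamond (lonsdaleite) in the orthohexagonal
# setting; 8 molecules per orthorhombic cell (a, sqrt(3) a, c), tiled to the
# requested box. Expressed in fractional coordinates, so the lattice is
# exact for the printed cell even where that cell is very slightly strained
# from the ideal hexagonal ratios.
ice_oxygen_lattice <- function(edges) {
  nx <- max(1, round(edges[1] / 8.54))
  ny <- max(1, round(edges[2] / (8.54 * sqrt(3))))
  nz <- max(1, round(edges[3] / 13.945))
  base <- rbind(
    c(0,   1 / 3, 1 / 16), c(0,   1 / 3, 7 / 16),
    c(1 / 2, 1 / 6, 9 / 16), c(1 / 2, 1 / 6, 15 / 16),
    c(1 / 2, 5 / 6, 1 / 16), c(1 / 2, 5 / 6, 7 / 16),
    c(0,   2 / 3, 9 / 16), c(0,   2 / 3, 15 / 16))
  pts <- list()
  for (i in 0:(nx - 1)) for (j in 0:(ny - 1)) for (k in 0:(nz - 1)) {
    f <- sweep(base, 2, c(i, j, k), "+")
    f <- sweep(f, 2, c(nx, ny, nz), "/")
    pts[[length(pts) + 1]] <- sweep(f, 2, edges, "*")
  }
  do.call(rbind, pts)
}

#' Build an analytic toy system
#'
#' `"oscillator"`: a one-dimensional (an)harmonic oscillator with a
#' potential contract and closed-form classical and quantum position
#' variances in the harmonic limit. `"lj_liquid"`: a small argon-like
#' Lennard-Jones fluid with an optional known Gaussian pair perturbation,
#' the substrate for the IBI recovery oracle.
#'
#' @param kind "oscillator" or "lj_liquid".
#' @param params Named list of overrides (oscillator: `mass`, `omega`,
#'   `c3`, `c4`; lj_liquid: `n`, `eps`, `sigma`, `mass`, `density_red`,
#'   `temperature`, `perturb_A`, `perturb_r0`, `perturb_w`).
#' @param seed Integer seed.
#' @return A list bundle with the potential contract and initial state;
#'   for the LJ fluid also a `system` list directly usable by [run_ibi()]
#'   and the perturbation as both function and table.
#' @export
build_toy_system <- function(kind = c("oscillator", "lj_liquid"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "oscillator") {
    p <- utils::modifyList(list(mass = 1822.888486, omega = 0.0164,
                                c3 = 0, c4 = 0), params)
    force_fn <- function(x) {
      e <- 0.5 * p$mass * p$omega^2 * x^2 + p$c3 * x^3 + p$c4 * x^4
      f <- -(p$mass * p$omega^2 * x + 3 * p$c3 * x^2 + 4 * p$c4 * x^3)
      list(energy = sum(e), forces = f)
    }
    return(list(
      kind = kind, mass = p$mass, omega = p$omega, c3 = p$c3, c4 = p$c4,
      force_fn = force_fn,
      quantum_variance = function(temperature) {
        beta <- 1 / (.fq$kB * temperature)
        1 / (2 * p$mass * p$omega) / tanh(beta * p$omega / 2)
      },
      classical_variance = function(temperature) {
        .fq$kB * temperature / (p$mass * p$omega^2)
      },
      x0 = 0, seed = seed))
  }

  p <- utils::modifyList(list(n = 48, eps = 3.8e-4, sigma = 6.43,
                              mass = 39.948 * .fq$amu_me,
                              density_red = 0.65, temperature = 130,
                              perturb_A = 2e-4, perturb_r0 = 8,
                              perturb_w = 1.2), params)
  edge <- (p$n / p$density_red)^(1 / 3) * p$sigma
  cell <- simulation_cell(edge)
  rcut <- min(edge / 2, 3 * p$sigma)
  set.seed(seed)
  n_side <- ceiling(p$n^(1 / 3))
  spacing <- edge / n_side
  grid <- as.matrix(expand.grid(0:(n_side - 1), 0:(n_side - 1),
                                0:(n_side - 1)))
  sites <- sweep(grid * spacing, 2, spacing / 2, "+")
  sites <- sites[sample(nrow(sites), p$n), , drop = FALSE]
  sites <- sites + matrix(stats::runif(3 * p$n, -0.05, 0.05) * spacing,
                          p$n, 3)
  vel <- maxwell_velocities(rep(p$mass, p$n), p$temperature,
                            derive_seed(seed, 3L))
  perturb_fn <- function(r)
    p$perturb_A * exp(-(r - p$perturb_r0)^2 / (2 * p$perturb_w^2))
  rg <- seq(0.8 * p$sigma, rcut, by = 0.05)
  ptab <- make_pair_table(rg, perturb_fn(rg), rcut, switch_width = 1,
                          smooth_window = 0)
  list(kind = kind, n = p$n, eps = p$eps, sigma = p$sigma, mass = p$mass,
       rcut = rcut, cell = cell, temperature = p$temperature,
       config = configuration(sites, vel),
       perturbation = list(fn = perturb_fn, table = ptab,
                           A = p$perturb_A, r0 = p$perturb_r0,
                           w = p$perturb_w),
       system = list(kind = "lj", config = configuration(sites, vel),
                     cell = cell, eps = p$eps, sigma = p$sigma,
                     mass = p$mass, rcut = rcut),
       dt_fs = 5, seed = seed)
}
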