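# shared fixtures built in code; kept deliberately small so the default test
# run stays fast

units <- fqcmd_units()

qp <- qtip4pf_params()

# two-molecule configuration in a large box: molecule 1 canonical at the
# origin region, molecule 2 rotated and displaced
two_molecule_config <- function(sep = 6, perturb = 0, seed = 42) {
  m1 <- fqcmd:::canonical_molecule(qp$r_eq, qp$r_eq, qp$theta_eq)
  set.seed(seed)
  m2 <- sweep(fqcmd:::canonical_molecule(qp$r_eq * 1.03, qp$r_eq * 0.98,
                                         qp$theta_eq + 0.04) %*%
                t(fqcmd:::random_rotation()), 2, -c(sep, 0.7, -0.4))
  pos <- rbind(m1, m2)
  if (perturb > 0) pos <- pos + matrix(stats::rnorm(18, 0, perturb), 6, 3)
  configuration(pos)
}

# small equilibrated liquid box, cached across tests within a run
liquid_cache <- new.env()
small_liquid <- function(n = 32, temperature = 300, equil_steps = 8000) {
  key <- paste(n, temperature, equil_steps, sep = "_")
  if (!is.null(liquid_cache[[key]])) return(liquid_cache[[key]])
  st <- build_liquid_box(structure_spec("liquid", n,
                                        temperature = temperature, seed = 1),
                         qp, equilibrate_steps = 500)
  if (equil_steps > 0) {
    settings <- integrator_settings(0.25, "langevin", tau_fs = 100,
                                    temperature = temperature, seed = 4)
    st$config <- run_water_md(st$config, st$cell, st$topo, qp, settings,
                              equil_steps,
                              record_stride = equil_steps)$final
  }
  liquid_cache[[key]] <- st
  st
}

# central-difference force check helper; returns max relative deviation
fd_force_error <- function(pos, cell, topo, params, correction = NULL,
                           atoms = seq_len(nrow(pos)), h = 1e-5) {
  fe <- water_energy_forces(configuration(pos), cell, topo, params,
                            correction)
  maxerr <- 0
  for (i in atoms) for (k in 1:3) {
    pp <- pos; pp[i, k] <- pp[i, k] + h
    pm <- pos; pm[i, k] <- pm[i, k] - h
    num <- -(water_energy_forces(configuration(pp), cell, topo, params,
                                 correction)$energy -
             water_energy_forces(configuration(pm), cell, topo, params,
                                 correction)$energy) / (2 * h)
    maxerr <- max(maxerr, abs(num - fe$forces[i, k]))
  }
  maxerr / max(abs(fe$forces))
}
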