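# Stage (i): PIMD sampling of the quasi-centroid distribution functions.

#' Sample quasi-centroid distribution functions with PIMD
#'
#' Runs thermostatted PIMD from the given structure, constructs the
#' quasi-centroid frame of every sampled ring-polymer configuration and
#' accumulates all five distribution functions (g_OO, g_OH, g_HH, rho_r,
#' rho_theta) from those frames.
#'
#' @param st A `water_structure`.
#' @param params A `water_params`.
#' @param P Bead count.
#' @param n_steps Production PIMD steps.
#' @param equil_steps Discarded equilibration steps.
#' @param frame_stride Sampling stride for quasi-centroid frames.
#' @param dt_fs,tau_fs Time step and centroid thermostat time constant.
#' @param seed Seed (velocity draw and thermostat noise).
#' @param rdf_bin,r_max,intra_args Histogram controls (see
#'   [accumulate_distribution_set()]).
#' @return List with `distributions` (a `distribution_set`), `qc_frames`
#'   (n_atoms, 3, n_frames array of quasi-centroid positions), `geometries`
#'   (list of per-frame n_mol x 3 curvilinear coordinates), and the
#'   `pimd_trajectory` record.
#' @export
sample_quasicentroid_ensemble <- function(st, params, P, n_steps,
                                          equil_steps = 0,
                                          frame_stride = 10, dt_fs = 0.25,
                                          tau_fs = 50, seed = 1,
                                          rdf_bin = 0.05, r_max = NULL,
                                          intra_args = list()) {
  temperature <- st$spec$temperature
  settings <- integrator_settings(dt_fs, "langevin", tau_fs = tau_fs,
                                  temperature = temperature, seed = seed)
  state <- ring_polymer_state(st$config, P, temperature, st$topo,
                              seed = derive_seed(seed, 13L))
  if (equil_steps > 0) {
    eq <- run_water_pimd(state, st$cell, st$topo, params, settings,
                         n_steps = equil_steps,
                         record_stride = equil_steps)
    state <- eq$final
    settings$seed <- derive_seed(seed, 17L)
  }
  run <- run_water_pimd(state, st$cell, st$topo, params, settings,
                        n_steps = n_steps, record_stride = frame_stride,
                        frame_stride = frame_stride)
  nf <- dim(run$frames)[4]
  if (is.na(nf) || nf < 1) stop("no frames recorded; check frame_stride")
  nat <- st$topo$n_atoms
  qc <- array(NA_real_, dim = c(nat, 3, nf))
  geoms <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- place_quasicentroids(run$frames[, , , f], st$cell, st$topo)
    qc[, , f] <- fr$positions
    geoms[[f]] <- fr$geometry
  }
  dist <- accumulate_distribution_set(qc, st$cell, st$topo, temperature,
                                      rdf_bin = rdf_bin, r_max = r_max,
                                      intra_args = intra_args)
  list(distributions = dist, qc_frames = qc, geometries = geoms,
       record = run)
}
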