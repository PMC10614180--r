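# Quasi-centroid potential of mean force V_qc = V_cl + dV_intra + dV_inter
# and its fit by regularized iterative Boltzmann inversion (IBI).
#
# dV_intra is separable per molecule: a polynomial in (r - r_eq) of the same
# degree as the model's stretch polynomial (4) for each bond, plus a
# quadratic in (theta - theta_eq). dV_inter is a sum of pairwise tabulated
# terms dV_OO, dV_OH, dV_HH on uniform radial grids, switched smoothly to
# zero at the cutoff. The intermolecular update is regularized:
#   dV <- dV + kT * ln[(g_trial + eps*G) / (g_target + eps*G)],
# with G the larger of the two peak heights, which damps noise-driven
# updates where the distributions are small. The intramolecular update is a
# weighted polynomial refit of kT ln(rho_trial/rho_target) over the
# low-noise region (bins above 1% of each density's maximum).

#' Zero-initialized correction potential
#'
#' The IBI initial guess: all polynomial coefficients zero and no pair
#' tables, so that V_qc equals the classical potential.
#'
#' @param params A `water_params` (reference geometry for the polynomials).
#' @return Object of class `correction_potential`.
#' @export
correction_potential <- function(params = qtip4pf_params()) {
  structure(list(dv_r = numeric(5), dv_theta = numeric(3),
                 dv_r_range = c(-1e30, 1e30),
                 dv_theta_range = c(-1e30, 1e30),
                 pair_OO = NULL, pair_OH = NULL, pair_HH = NULL,
                 r_eq = params$r_eq, theta_eq = params$theta_eq,
                 iteration = 0L, epsilon = NA_real_),
            class = "correction_potential")
}

unclass_correction <- function(corr) {
  out <- list(dv_r = corr$dv_r, dv_theta = corr$dv_theta)
  if (!is.null(corr$dv_r_range)) out$dv_r_range <- corr$dv_r_range
  if (!is.null(corr$dv_theta_range)) out$dv_theta_range <- corr$dv_theta_range
  for (p in c("pair_OO", "pair_OH", "pair_HH"))
    if (!is.null(corr[[p]])) out[[p]] <- corr[[p]]
  out
}

#' Energy and forces of the correction terms alone
#'
#' Evaluates dV_intra + dV_inter (and their exact gradients) on a
#' configuration, with the classical terms switched off.
#'
#' @param correction A `correction_potential`.
#' @param config,cell,topo,params As in [water_energy_forces()].
#' @return A `force_energy` containing only the correction contributions.
#' @export
evaluate_correction <- function(correction, config, cell, topo, params) {
  p0 <- params
  p0$D_r <- 1e-300; p0$k_theta <- 1e-300; p0$eps_OO <- 1e-300; p0$q_H <- 0
  # positive-definiteness checks want > 0; vanishing values switch the
  # classical terms off to numerical zero
  check_topology(config, topo)
  p0 <- resolve_cutoff(p0, cell)
  res <- water_energy_forces_cpp(config$positions, cell$edges, unclass(p0),
                                 unclass_correction(correction), TRUE, TRUE)
  res$energy <- res$components[["intra_corr"]] + res$components[["pair_corr"]]
  force_energy(res)
}

# ---- pair-table machinery --------------------------------------------------

# Savitzky-Golay least-squares smoother with asymmetric end windows
savgol <- function(y, window = 9, degree = 3) {
  n <- length(y)
  if (n < window || window < degree + 2) return(y)
  hw <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - hw); hi <- min(n, i + hw)
    xs <- (lo:hi) - i
    A <- outer(xs, 0:degree, "^")
    out[i] <- qr.solve(A, y[lo:hi])[1]
  }
  out
}

# quintic switch: 1 below r0, 0 at r1, C2-continuous in between
quintic_switch <- function(r, r0, r1) {
  t <- pmin(pmax((r - r0) / (r1 - r0), 0), 1)
  1 - t^3 * (10 - 15 * t + 6 * t^2)
}

# build a tabulated pair term: smooth, switch to zero at r_cut, and store
# natural-spline nodal derivatives for the C1 interpolant used in the engine
make_pair_table <- function(r, V, r_cut, switch_width = 1.0,
                            smooth_window = 9) {
  stopifnot(length(r) == length(V), length(r) >= 4)
  dr <- r[2] - r[1]
  if (max(abs(diff(r) - dr)) > 1e-8 * dr) stop("grid must be uniform")
  V <- savgol(V, window = smooth_window)
  V <- V * quintic_switch(r, r_cut - switch_width, r_cut)
  V[r >= r_cut] <- 0
  sf <- stats::splinefun(r, V, method = "natural")
  list(r_min = r[1], dr = dr, V = V, dV = sf(r, deriv = 1))
}

# evaluate a pair table on arbitrary r (same interpolant as the engine)
eval_pair_table <- function(table, r) {
  if (is.null(table)) return(list(V = numeric(length(r)),
                                  dV = numeric(length(r))))
  pair_table_eval_cpp(table, r)
}

#' Regularized intermolecular IBI update
#'
#' Pointwise update of one tabulated pair correction:
#' `dV(r) <- dV(r) + kT ln[(g_trial + eps G)/(g_target + eps G)]` with
#' `G` the larger of the two maximum peak heights. The updated table is
#' re-smoothed and re-switched to zero at the cutoff. With `eps = 0` the
#' update is the basic IBI formula and fails where both distributions
#' vanish.
#'
#' @param table Current pair table (or `NULL` for the zero initial guess).
#' @param g_trial,g_target Distribution values on the common grid `r`.
#' @param r Bin centers (a0), uniform.
#' @param epsilon Regularization parameter (>= 0).
#' @param kT Thermal energy (hartree).
#' @param r_cut Cutoff where the table is switched to zero (a0).
#' @param inner_threshold The table starts at the first r with
#'   `g_target` above this value (default 1e-4).
#' @param smooth_window,switch_width Table post-processing controls.
#' @return Updated pair table (list with `r_min`, `dr`, `V`, `dV`, and the
#'   `epsilon` and `G` actually used).
#' @export
ibi_inter_update <- function(table, g_trial, g_target, r, epsilon, kT,
                             r_cut, inner_threshold = 1e-4,
                             smooth_window = 9, switch_width = 1.0) {
  stopifnot(length(g_trial) == length(r), length(g_target) == length(r))
  if (epsilon < 0) stop("epsilon must be non-negative")
  G <- max(max(g_target), max(g_trial))
  if (!is.finite(G) || G <= 0) stop("empty distributions")
  keep <- r >= r[which(g_target > inner_threshold)[1]] & r <= r_cut
  if (!any(keep)) stop("no usable bins for the pair update")
  rg <- r[keep]
  gt <- g_trial[keep]; gx <- g_target[keep]
  if (epsilon == 0) {
    if (any(gt <= 0 & gx <= 0))
      stop("g_trial and g_target both vanish in some bins; ",
           "the unregularized update is ln(0/0) - use epsilon > 0")
    u <- kT * log(gt / gx)
  } else {
    u <- kT * log((gt + epsilon * G) / (gx + epsilon * G))
  }
  # smooth and switch the increment only, so that a zero update leaves the
  # table exactly unchanged (IBI fixed point) while the accumulated table
  # stays smooth and zero at the cutoff
  u <- savgol(u, window = smooth_window) *
    quintic_switch(rg, r_cut - switch_width, r_cut)
  Vnew <- eval_pair_table(table, rg)$V + u
  Vnew[rg >= r_cut] <- 0
  sf <- stats::splinefun(rg, Vnew, method = "natural")
  dr <- rg[2] - rg[1]
  list(r_min = rg[1], dr = dr, V = Vnew, dV = sf(rg, deriv = 1),
       epsilon = epsilon, G = G, update = u)
}

#' Intramolecular IBI update by polynomial refit
#'
#' Computes the pointwise update `kT ln(rho_trial/rho_target)` on bins where
#' both densities exceed 1% of their maxima, fits a polynomial of the fixed
#' degree (4 for the stretch, 2 for the bend) to it by least squares
#' weighted with the target density, and adds the fitted coefficients to
#' the current ones. Only the low-noise region informs the fit, so no
#' regularization is needed.
#'
#' @param dv_r,dv_theta Current coefficient vectors (powers of `r - r_eq`
#'   and `theta - theta_eq`).
#' @param trial,target `intra_dist` objects on identical grids.
#' @param kT Thermal energy (hartree).
#' @param r_eq,theta_eq Expansion points (a0, rad).
#' @param threshold Usable-bin threshold as a fraction of each maximum.
#' @return List with updated `dv_r`, `dv_theta` and the per-channel number
#'   of bins used.
#' @export
ibi_intra_refit <- function(dv_r, dv_theta, trial, target, kT, r_eq,
                            theta_eq, threshold = 0.01) {
  fit_channel <- function(x0, grid, rho_t, rho_x, degree) {
    if (length(rho_t) != length(rho_x) ||
        max(abs(grid$trial - grid$target)) > 1e-9)
      stop("trial and target intramolecular grids differ")
    mask <- rho_t > threshold * max(rho_t) & rho_x > threshold * max(rho_x)
    if (sum(mask) < degree + 1)
      stop("fewer usable bins (", sum(mask), ") than coefficients (",
           degree + 1, ") in the intramolecular refit")
    x <- grid$trial[mask] - x0
    u <- kT * log(rho_t[mask] / rho_x[mask])
    A <- outer(x, 0:degree, "^")
    fit <- stats::lm.wfit(A, u, w = rho_x[mask])
    list(coef = unname(fit$coefficients), n = sum(mask), mask = mask)
  }
  fr <- fit_channel(r_eq,
                    list(trial = trial$rho_r$r, target = target$rho_r$r),
                    trial$rho_r$density, target$rho_r$density, 4)
  ft <- fit_channel(theta_eq,
                    list(trial = trial$rho_theta$theta,
                         target = target$rho_theta$theta),
                    trial$rho_theta$density, target$rho_theta$density, 2)
  # trust the polynomials 50% beyond the fitted interval on each side: the
  # constant-force continuation then starts where the densities are
  # negligible, so its curvature kink is essentially never crossed
  expand <- function(rg) rg + c(-0.5, 0.5) * diff(rg)
  list(dv_r = dv_r + fr$coef, dv_theta = dv_theta + ft$coef,
       dv_r_range = expand(range(trial$rho_r$r[fr$mask]) - r_eq),
       dv_theta_range = expand(range(trial$rho_theta$theta[ft$mask]) -
                                 theta_eq),
       n_bins_r = fr$n, n_bins_theta = ft$n)
}

# density-weighted sup-norm between two distributions on a common grid,
# with light smoothing of both so statistical bin noise does not dominate
weighted_supnorm <- function(a, b, weight_source, smooth_window = 9) {
  a <- savgol(a, smooth_window)
  b <- savgol(b, smooth_window)
  w <- weight_source / max(weight_source)
  max(abs(a - b) * w)
}

ibi_metric <- function(trial, target, smooth_window = 9) {
  rdf_norm <- function(a, b, w) {
    if (max(w) <= 0) return(0)  # no pairs (single molecule)
    weighted_supnorm(a, b, w, smooth_window)
  }
  m <- c(
    OO = rdf_norm(trial$g_OO$table$g, target$g_OO$table$g,
                  target$g_OO$table$g),
    OH = rdf_norm(trial$g_OH$table$g, target$g_OH$table$g,
                  target$g_OH$table$g),
    HH = rdf_norm(trial$g_HH$table$g, target$g_HH$table$g,
                  target$g_HH$table$g),
    rho_r = weighted_supnorm(
      trial$intra$rho_r$density / max(target$intra$rho_r$density),
      target$intra$rho_r$density / max(target$intra$rho_r$density),
      target$intra$rho_r$density, smooth_window),
    rho_theta = weighted_supnorm(
      trial$intra$rho_theta$density / max(target$intra$rho_theta$density),
      target$intra$rho_theta$density / max(target$intra$rho_theta$density),
      target$intra$rho_theta$density, smooth_window))
  m
}

# ---- the IBI driver --------------------------------------------------------

#' Run regularized iterative Boltzmann inversion
#'
#' Fits the correction potential so that classical NVT sampling on
#' V_cl + correction reproduces the target distribution set. Each iteration
#' runs a classical trial trajectory on the current effective potential,
#' accumulates trial distributions on the target's grids, refits the
#' intramolecular polynomials and applies the regularized update to the
#' three pair tables. Aborts (suggesting a larger `epsilon`) if the
#' convergence metric grows for five consecutive iterations.
#'
#' @param target A `distribution_set` (from PIMD quasi-centroid sampling)
#'   for `system$kind == "water"`, or an `rdf` for the monatomic
#'   Lennard-Jones test system (`system$kind == "lj"`).
#' @param system For water: `list(kind = "water", config, cell, topo,
#'   params)`. For the toy fluid: `list(kind = "lj", config, cell, eps,
#'   sigma, mass, rcut)` (mass in m_e, lengths a0, energies hartree).
#' @param settings An `integrator_settings` (Langevin NVT; its temperature
#'   defines kT in the updates).
#' @param n_iterations Index of the last IBI iteration to run (equals the
#'   number of iterations when starting fresh; with `first_iteration > 1`
#'   the loop continues a checkpointed fit up to this index).
#' @param epsilon Regularization parameter (published protocol: 1 at 300 K,
#'   5 at 150 K).
#' @param md_steps Trial-trajectory production steps per iteration.
#' @param equil_steps Discarded steps at the start of each iteration.
#' @param frame_stride Sampling stride for trial frames.
#' @param seed Master seed; each iteration derives its own stream from the
#'   global iteration index, so resumed fits reproduce uninterrupted ones.
#' @param init_correction,init_config,first_iteration Checkpoint state for
#'   resuming: the correction and configuration reached so far and the next
#'   iteration index.
#' @param smooth_window Savitzky-Golay window for table smoothing and for
#'   the convergence metric.
#' @param verbose Print per-iteration metrics.
#' @return Object of class `ibi_state`: final `correction`, per-iteration
#'   `history` data frame, last trial distributions, the fixed target, and
#'   the final configuration.
#' @export
run_ibi <- function(target, system, settings, n_iterations = 10,
                    epsilon = 1, md_steps = 8000,
                    equil_steps = max(1000, md_steps %/% 5),
                    frame_stride = 4, seed = 1, smooth_window = 9,
                    init_correction = NULL, init_config = NULL,
                    first_iteration = 1L, verbose = FALSE) {
  kind <- system$kind
  kT <- .fq$kB * settings$temperature
  if (kind == "water") {
    corr <- correction_potential(system$params)
    params <- resolve_cutoff(system$params, system$cell)
  } else if (kind == "lj") {
    corr <- structure(list(dv_r = numeric(0), dv_theta = numeric(0),
                           pair_OO = NULL, pair_OH = NULL, pair_HH = NULL,
                           iteration = 0L, epsilon = epsilon),
                      class = "correction_potential")
  } else stop("unknown system kind: ", kind)
  if (!is.null(init_correction)) corr <- init_correction
  corr$epsilon <- epsilon

  config <- if (is.null(init_config)) system$config else init_config
  history <- list()
  n_rise <- 0
  prev_metric <- Inf
  trial <- NULL

  for (it in seq(from = first_iteration,
                 length.out = n_iterations - first_iteration + 1L)) {
    it_seed <- derive_seed(seed, it)
    st <- settings
    st$seed <- it_seed
    if (kind == "water") {
      eq <- run_water_md(config, system$cell, system$topo, params, st,
                         n_steps = equil_steps, correction = corr,
                         record_stride = max(1, equil_steps))
      st$seed <- derive_seed(seed, 1000L + it)
      run <- run_water_md(eq$final, system$cell, system$topo, params, st,
                          n_steps = md_steps, correction = corr,
                          record_stride = max(1, md_steps),
                          frame_stride = frame_stride)
      config <- run$final
      trial <- trial_distributions_water(run$frames, system, target)
      metric <- ibi_metric(trial, target, smooth_window)
      upd <- ibi_intra_refit(corr$dv_r, corr$dv_theta, trial$intra,
                             target$intra, kT, system$params$r_eq,
                             system$params$theta_eq)
      corr$dv_r <- upd$dv_r
      corr$dv_theta <- upd$dv_theta
      corr$dv_r_range <- upd$dv_r_range
      corr$dv_theta_range <- upd$dv_theta_range
      for (p in c("OO", "OH", "HH")) {
        slot <- paste0("pair_", p)
        tr <- trial[[paste0("g_", p)]]$table
        tg <- target[[paste0("g_", p)]]$table
        if (max(tg$g) <= 0) next  # no pairs (single molecule)
        corr[[slot]] <- ibi_inter_update(
          corr[[slot]], tr$g, tg$g, tg$r, epsilon, kT,
          r_cut = params$r_cut, smooth_window = smooth_window)
      }
    } else {
      eq <- run_lj_md_cpp(config$positions, config$velocities,
                          system$cell$edges, system$eps, system$sigma,
                          system$rcut, system$mass, lj_table(corr),
                          fs_to_au(st$dt_fs), equil_steps, kT,
                          1 / fs_to_au(st$tau_fs), 1L, it_seed,
                          equil_steps, 0L)
      run <- run_lj_md_cpp(eq$positions, eq$velocities,
                           system$cell$edges, system$eps, system$sigma,
                           system$rcut, system$mass, lj_table(corr),
                           fs_to_au(st$dt_fs), md_steps, kT,
                           1 / fs_to_au(st$tau_fs), 1L,
                           derive_seed(seed, 1000L + it),
                           md_steps, frame_stride)
      config <- configuration(run$positions, run$velocities)
      trial <- rdf_atoms(run$frames, system$cell, target$bin_width,
                         target$r_max)
      metric <- c(OO = weighted_supnorm(trial$table$g, target$table$g,
                                        target$table$g, smooth_window))
      corr$pair_OO <- ibi_inter_update(
        corr$pair_OO, trial$table$g, target$table$g, target$table$r,
        epsilon, kT, r_cut = system$rcut, smooth_window = smooth_window)
    }

    total <- max(metric)
    history[[it]] <- data.frame(iteration = it, t(metric), total = total)
    if (verbose)
      message(sprintf("IBI iteration %d: metric %.4f", it, total))
    if (total > prev_metric) n_rise <- n_rise + 1 else n_rise <- 0
    if (n_rise >= 5)
      stop("IBI convergence metric grew for 5 consecutive iterations; ",
           "the update is oscillating - increase epsilon")
    prev_metric <- total
    corr$iteration <- it
  }

  structure(list(correction = corr,
                 history = do.call(rbind, history),
                 trial = trial, target = target,
                 final_config = config, epsilon = epsilon,
                 temperature = settings$temperature),
            class = "ibi_state")
}

lj_table <- function(corr) {
  if (is.null(corr$pair_OO)) list() else corr$pair_OO
}

trial_distributions_water <- function(frames, system, target) {
  accumulate_distribution_set(
    frames, system$cell, system$topo, temperature = NA,
    rdf_bin = target$g_OO$bin_width, r_max = target$g_OO$r_max,
    intra_args = list(
      r_range = range(target$intra$rho_r$r) +
        c(-0.5, 0.5) * target$intra$r_bin,
      theta_range = range(target$intra$rho_theta$theta) +
        c(-0.5, 0.5) * target$intra$theta_bin,
      r_bin = target$intra$r_bin, theta_bin = target$intra$theta_bin))
}

# RDF of a monatomic fluid (all atoms one species, no exclusions)
rdf_atoms <- function(frames, cell, bin_width, r_max) {
  frames <- as_frame_array(frames)
  n <- dim(frames)[1]
  nf <- dim(frames)[3]
  nbins <- floor(r_max / bin_width)
  counts <- numeric(nbins)
  for (f in seq_len(nf))
    counts <- counts + pair_hist_cpp(frames[, , f], cell$edges, seq_len(n),
                                     integer(0), seq_len(n), TRUE, 0,
                                     bin_width, nbins)
  V <- prod(cell$edges)
  edges_r <- bin_width * (0:nbins)
  shell <- 4 / 3 * pi * (edges_r[-1]^3 - edges_r[-(nbins + 1)]^3)
  ideal <- n * (n - 1) / 2 * shell / V
  structure(list(
    table = data.frame(r = bin_width * (seq_len(nbins) - 0.5),
                       g = counts / (nf * ideal)),
    pair = "OO", bin_width = bin_width, r_max = r_max, n_frames = nf,
    density = n / V), class = "rdf")
}

derive_seed <- function(master, k) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + k * 7919) %%
               2147483646 + 1)
}

#' Write a correction potential as plain-text tables
#'
#' Polynomial coefficients (with their degrees) and one (r, dV, dV/dr)
#' table per pair channel, under a versioned format header.
#'
#' @param corr A `correction_potential`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_correction <- function(corr, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# fqcmd correction potential format 1", con)
  writeLines(sprintf("iteration = %d", corr$iteration), con)
  writeLines(sprintf("epsilon = %g", corr$epsilon), con)
  writeLines(sprintf("dv_r_degree = %d", length(corr$dv_r) - 1L), con)
  writeLines(paste("dv_r =", paste(format(corr$dv_r, digits = 17),
                                   collapse = " ")), con)
  writeLines(sprintf("dv_theta_degree = %d",
                     length(corr$dv_theta) - 1L), con)
  writeLines(paste("dv_theta =", paste(format(corr$dv_theta, digits = 17),
                                       collapse = " ")), con)
  for (p in c("pair_OO", "pair_OH", "pair_HH")) {
    tab <- corr[[p]]
    if (is.null(tab)) next
    writeLines(sprintf("table %s n = %d r_min = %.17g dr = %.17g", p,
                       length(tab$V), tab$r_min, tab$dr), con)
    r <- tab$r_min + tab$dr * (seq_along(tab$V) - 1)
    writeLines(sprintf("%.17g %.17g %.17g", r, tab$V, tab$dV), con)
  }
  invisible(file)
}

#' Read a correction potential written by [write_correction()]
#'
#' @param file Path.
#' @param params `water_params` for the polynomial reference geometry.
#' @return A `correction_potential`.
#' @export
read_correction <- function(file, params = qtip4pf_params()) {
  lines <- readLines(file)
  if (!grepl("^# fqcmd correction potential format 1", lines[1]))
    stop("unrecognized correction file format")
  corr <- correction_potential(params)
  getval <- function(key) {
    ln <- grep(paste0("^", key, " ="), lines, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  corr$iteration <- as.integer(getval("iteration"))
  corr$epsilon <- as.numeric(getval("epsilon"))
  corr$dv_r <- as.numeric(strsplit(getval("dv_r"), "\\s+")[[1]])
  corr$dv_theta <- as.numeric(strsplit(getval("dv_theta"), "\\s+")[[1]])
  tab_starts <- grep("^table ", lines)
  for (ts in tab_starts) {
    hdr <- lines[ts]
    m <- regmatches(hdr, regexec(
      "^table (pair_\\w+) n = (\\d+) r_min = ([-0-9.eE+]+) dr = ([-0-9.eE+]+)",
      hdr))[[1]]
    n <- as.integer(m[3])
    block <- do.call(rbind,
                     lapply(strsplit(lines[(ts + 1):(ts + n)], "\\s+"),
                            as.numeric))
    corr[[m[2]]] <- list(r_min = as.numeric(m[4]), dr = as.numeric(m[5]),
                         V = block[, 2], dV = block[, 3])
  }
  corr
}
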