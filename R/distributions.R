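# The five target distribution functions: intermolecular radial
# distribution functions g_OO, g_OH, g_HH (intramolecular pairs excluded)
# and the intramolecular densities rho_r (bead-averaged O-H distance, both
# bonds) and rho_theta (bead-averaged H-O-H angle). The same accumulation
# code path serves classical configurations and PIMD quasi-centroid frames.

#' Accumulate a radial distribution function
#'
#' Histograms minimum-image pair distances over a stream of frames and
#' normalizes by frame count, pair multiplicity and the ideal-gas shell
#' count so that g -> 1 at large r in a homogeneous liquid. Intramolecular
#' pairs are excluded (intermolecular definition). Pair multiplicities:
#' OO counts N(N-1)/2 unordered pairs, OH counts 2N(N-1) ordered
#' intermolecular O-H pairs, HH counts 2N(N-1) unordered intermolecular
#' H-H pairs.
#'
#' @param frames (n_atoms, 3, n_frames) array, or a list of n_atoms x 3
#'   matrices, or a single matrix.
#' @param pair One of "OO", "OH", "HH".
#' @param cell A `simulation_cell`.
#' @param topo A `water_topology`.
#' @param bin_width Bin width in a0 (default 0.05).
#' @param r_max Histogram range (default: half the smallest cell edge).
#' @return Object of class `rdf`: data frame `table` with bin centers `r`
#'   and values `g`, plus binning and normalization metadata.
#' @export
accumulate_rdf <- function(frames, pair = c("OO", "OH", "HH"), cell, topo,
                           bin_width = 0.05, r_max = NULL) {
  pair <- match.arg(pair)
  frames <- as_frame_array(frames)
  if (is.null(r_max)) r_max <- half_min_edge(cell)
  if (r_max > half_min_edge(cell) + 1e-9)
    stop("histogram range exceeds half the smallest cell edge")
  nbins <- floor(r_max / bin_width)
  nf <- dim(frames)[3]
  N <- topo$n_mol
  o_idx <- which(topo$species == "O")
  h_idx <- which(topo$species == "H")
  counts <- numeric(nbins)
  for (f in seq_len(nf)) {
    pos <- frames[, , f]
    counts <- counts + switch(pair,
      OO = pair_hist_cpp(pos, cell$edges, o_idx, integer(0), topo$mol_id,
                         TRUE, 0, bin_width, nbins),
      OH = pair_hist_cpp(pos, cell$edges, o_idx, h_idx, topo$mol_id,
                         FALSE, 0, bin_width, nbins),
      HH = pair_hist_cpp(pos, cell$edges, h_idx, integer(0), topo$mol_id,
                         TRUE, 0, bin_width, nbins))
  }
  n_pairs <- switch(pair, OO = N * (N - 1) / 2, OH = 2 * N * (N - 1),
                    HH = 2 * N * (N - 1))
  V <- prod(cell$edges)
  edges_r <- bin_width * (0:nbins)
  shell <- 4 / 3 * pi * (edges_r[-1]^3 - edges_r[-(nbins + 1)]^3)
  ideal <- n_pairs * shell / V
  g <- if (n_pairs > 0) counts / (nf * ideal) else rep(0, nbins)
  structure(list(
    table = data.frame(r = bin_width * (seq_len(nbins) - 0.5), g = g),
    pair = pair, bin_width = bin_width, r_max = r_max,
    n_frames = nf, n_pairs = n_pairs, counts = counts,
    density = N / V
  ), class = "rdf")
}

#' Accumulate intramolecular distributions
#'
#' Histograms of the (bead-averaged) O-H distance (both bonds of every
#' molecule enter rho_r) and H-O-H angle, each normalized to unit integral
#' over its grid. Values outside the grid are counted and reported with a
#' warning, never silently dropped.
#'
#' @param geometries n x 3 matrix of (r1, r2, theta) rows, or a list of
#'   such matrices (one per frame).
#' @param r_range,theta_range Histogram ranges (a0, rad).
#' @param r_bin Bin width for r (a0, default 0.02).
#' @param theta_bin Bin width for theta (rad, default 0.5 degrees).
#' @return Object of class `intra_dist` with data frames `rho_r`
#'   (`r`, `density`) and `rho_theta` (`theta`, `density`), plus counts of
#'   out-of-range values.
#' @export
accumulate_intra <- function(geometries, r_range = c(1.2, 2.6),
                             theta_range = c(1.0, 2.8),
                             r_bin = 0.02, theta_bin = 0.5 * pi / 180) {
  if (is.list(geometries)) geometries <- do.call(rbind, geometries)
  geometries <- as.matrix(geometries)
  if (nrow(geometries) < 1) stop("empty geometry stream")
  rvals <- c(geometries[, 1], geometries[, 2])
  tvals <- geometries[, 3]
  rh <- density_hist(rvals, r_range, r_bin)
  th <- density_hist(tvals, theta_range, theta_bin)
  n_out <- rh$n_out + th$n_out
  if (n_out > 0)
    warning(n_out, " value(s) outside the histogram grids (",
            rh$n_out, " in r, ", th$n_out, " in theta)")
  structure(list(
    rho_r = data.frame(r = rh$mids, density = rh$density),
    rho_theta = data.frame(theta = th$mids, density = th$density),
    r_bin = r_bin, theta_bin = theta_bin,
    n_samples = nrow(geometries), n_out_of_range = n_out
  ), class = "intra_dist")
}

density_hist <- function(x, range, bin) {
  nb <- ceiling(diff(range) / bin - 1e-9)
  edges <- range[1] + bin * (0:nb)
  inside <- x >= range[1] & x < edges[nb + 1]
  idx <- floor((x[inside] - range[1]) / bin) + 1
  counts <- tabulate(idx, nbins = nb)
  total <- length(x)
  list(mids = edges[-(nb + 1)] + bin / 2,
       density = counts / (total * bin),
       n_out = total - sum(inside))
}

#' Bundle the five distribution functions
#'
#' @param g_OO,g_OH,g_HH `rdf` objects.
#' @param intra An `intra_dist`.
#' @param n_frames Number of frames accumulated.
#' @param temperature Temperature tag (K).
#' @return Object of class `distribution_set`.
#' @export
distribution_set <- function(g_OO, g_OH, g_HH, intra, n_frames,
                             temperature) {
  structure(list(g_OO = g_OO, g_OH = g_OH, g_HH = g_HH, intra = intra,
                 n_frames = n_frames, temperature = temperature),
            class = "distribution_set")
}

#' Accumulate the full distribution set from configuration frames
#'
#' Works identically for classical configurations and quasi-centroid
#' frames; the intramolecular coordinates of each frame are its actual
#' internal coordinates (for quasi-centroid frames these equal the
#' curvilinear bead averages by construction).
#'
#' @param frames (n_atoms, 3, n_frames) array (or list of matrices).
#' @param cell,topo Cell and topology.
#' @param temperature Temperature tag (K).
#' @param rdf_bin,r_max RDF binning (a0).
#' @param intra_args List of arguments forwarded to [accumulate_intra()].
#' @return A `distribution_set`.
#' @export
accumulate_distribution_set <- function(frames, cell, topo, temperature,
                                        rdf_bin = 0.05, r_max = NULL,
                                        intra_args = list()) {
  frames <- as_frame_array(frames)
  nf <- dim(frames)[3]
  geoms <- vector("list", nf)
  for (f in seq_len(nf))
    geoms[[f]] <- intra_geometry_cpp(frames[, , f], cell$edges)
  intra <- do.call(accumulate_intra, c(list(geometries = geoms), intra_args))
  distribution_set(
    g_OO = accumulate_rdf(frames, "OO", cell, topo, rdf_bin, r_max),
    g_OH = accumulate_rdf(frames, "OH", cell, topo, rdf_bin, r_max),
    g_HH = accumulate_rdf(frames, "HH", cell, topo, rdf_bin, r_max),
    intra = intra, n_frames = nf, temperature = temperature)
}

as_frame_array <- function(frames) {
  if (is.list(frames)) {
    nat <- nrow(frames[[1]])
    frames <- array(unlist(frames), dim = c(nat, 3, length(frames)))
  } else if (length(dim(frames)) == 2) {
    frames <- array(frames, dim = c(dim(frames), 1))
  }
  frames
}

#' Write a distribution set as CSV tables
#'
#' One file per function: `g_OO.csv`, `g_OH.csv`, `g_HH.csv`, `rho_r.csv`,
#' `rho_theta.csv`.
#'
#' @param dset A `distribution_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_distribution_set <- function(dset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    g_OO = file.path(dir, "g_OO.csv"), g_OH = file.path(dir, "g_OH.csv"),
    g_HH = file.path(dir, "g_HH.csv"), rho_r = file.path(dir, "rho_r.csv"),
    rho_theta = file.path(dir, "rho_theta.csv"))
  utils::write.csv(dset$g_OO$table, paths["g_OO"], row.names = FALSE)
  utils::write.csv(dset$g_OH$table, paths["g_OH"], row.names = FALSE)
  utils::write.csv(dset$g_HH$table, paths["g_HH"], row.names = FALSE)
  utils::write.csv(dset$intra$rho_r, paths["rho_r"], row.names = FALSE)
  utils::write.csv(dset$intra$rho_theta, paths["rho_theta"],
                   row.names = FALSE)
  invisible(paths)
}

#' @export
plot.rdf <- function(x, ...) {
  plot(x$table$r, x$table$g, type = "l", xlab = "r (a0)",
       ylab = sprintf("g_%s(r)", x$pair), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
plot.intra_dist <- function(x, which = c("r", "theta"), ...) {
  which <- match.arg(which)
  if (which == "r")
    plot(x$rho_r$r, x$rho_r$density, type = "l", xlab = "r (a0)",
         ylab = "rho_r", ...)
  else
    plot(x$rho_theta$theta * 180 / pi, x$rho_theta$density, type = "l",
         xlab = "theta (deg)", ylab = "rho_theta", ...)
  invisible(x)
}
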