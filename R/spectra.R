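# Dipole absorption spectra from the dipole-derivative autocorrelation
# function, damped with a Hann window before the cosine transform. Band
# positions are the observable of interest; spectra are reported normalized
# to unit maximum and the constant (temperature/frequency) prefactor of the
# absorption cross-section is omitted, as noted in the output metadata.

#' Dipole-derivative autocorrelation function
#'
#' `C(t) = <mudot(0) . mudot(t)>` averaged over all time origins (unbiased:
#' each lag divided by its number of origins) and summed over the three
#' Cartesian components. Multiple independent segments may be supplied; the
#' correlation is averaged over them.
#'
#' @param mudot n x 3 matrix of dipole-derivative samples on a uniform time
#'   grid, or a list of such matrices (independent segments).
#' @param dt_fs Sampling interval in fs.
#' @param max_lag_fs Maximum lag; must not exceed half the (shortest)
#'   segment length.
#' @return Object of class `autocorrelation`: data frame `table` with
#'   `t_fs`, `C`, plus `dt_fs` and segment metadata.
#' @export
dipole_autocorrelation <- function(mudot, dt_fs, max_lag_fs) {
  segs <- if (is.list(mudot)) mudot else list(mudot)
  segs <- lapply(segs, as.matrix)
  nmin <- min(vapply(segs, nrow, 1L))
  nlag <- floor(max_lag_fs / dt_fs)
  if (nlag > nmin / 2)
    stop("max_lag (", max_lag_fs, " fs) exceeds half the segment length (",
         nmin * dt_fs / 2, " fs)")
  acc <- numeric(nlag + 1)
  for (s in segs) {
    n <- nrow(s)
    m <- 2^ceiling(log2(2 * n))
    cs <- numeric(nlag + 1)
    for (k in 1:ncol(s)) {
      ft <- stats::fft(c(s[, k], numeric(m - n)))
      ac <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / m
      cs <- cs + ac[1:(nlag + 1)]
    }
    acc <- acc + cs / (n - 0:nlag)  # unbiased origin count
  }
  C <- acc / length(segs)
  structure(list(table = data.frame(t_fs = dt_fs * (0:nlag), C = C),
                 dt_fs = dt_fs, n_segments = length(segs)),
            class = "autocorrelation")
}

# direct O(N^2) reference used by tests
autocorrelation_direct <- function(mudot, dt_fs, max_lag_fs) {
  mudot <- as.matrix(mudot)
  n <- nrow(mudot)
  nlag <- floor(max_lag_fs / dt_fs)
  C <- vapply(0:nlag, function(l) {
    i <- 1:(n - l)
    sum(mudot[i, , drop = FALSE] * mudot[i + l, , drop = FALSE]) / (n - l)
  }, numeric(1))
  data.frame(t_fs = dt_fs * (0:nlag), C = C)
}

#' Hann-windowed absorption spectrum
#'
#' Multiplies the correlation function by the Hann taper
#' `cos^2(pi t / (2 tau))` for `t <= tau` (zero beyond), cosine-transforms,
#' and returns the spectrum on a cm^-1 grid normalized to unit maximum.
#' The window time constant `tau` is the time at which the taper reaches
#' zero, which sets the spectral resolution.
#'
#' @param acf An `autocorrelation` (or data frame with `t_fs`, `C`).
#' @param window_tau_fs Hann window time constant in fs (600 was used for
#'   liquid water at 300 K, 800 for ice at 150 K).
#' @param pad_factor Zero-padding factor for the transform grid (frequency
#'   spacing = 1/(padded length x dt)).
#' @return Object of class `absorption_spectrum`: data frame `table` with
#'   `wavenumber` (cm^-1) and `intensity` (unit maximum), plus metadata.
#' @export
windowed_spectrum <- function(acf, window_tau_fs, pad_factor = 8) {
  tab <- if (inherits(acf, "autocorrelation")) acf$table else acf
  dt <- if (inherits(acf, "autocorrelation")) acf$dt_fs else
    tab$t_fs[2] - tab$t_fs[1]
  tmax <- max(tab$t_fs)
  if (window_tau_fs > tmax + 1e-9)
    stop("window time constant (", window_tau_fs,
         " fs) exceeds the correlation length (", tmax, " fs)")
  w <- ifelse(tab$t_fs <= window_tau_fs,
              cos(pi * tab$t_fs / (2 * window_tau_fs))^2, 0)
  y <- tab$C * w
  n <- length(y)
  m <- 2^ceiling(log2(max(2 * n, pad_factor * n)))
  ft <- Re(stats::fft(c(y, numeric(m - n))))
  # cosine transform with trapezoid half-weight at t = 0
  I <- ft - y[1] / 2
  nyq <- floor(m / 2)
  freq_cm1 <- (0:(nyq - 1)) / (m * dt) * .fq$cm1_per_invfs
  I <- I[1:nyq]
  I[I < 0] <- 0  # tiny negative lobes from the finite window
  if (max(I) > 0) I <- I / max(I)
  structure(list(table = data.frame(wavenumber = freq_cm1, intensity = I),
                 window_tau_fs = window_tau_fs, dt_fs = dt,
                 resolution_cm1 = 1 / (m * dt) * .fq$cm1_per_invfs,
                 note = paste("peak-normalized; constant absorption",
                              "prefactor omitted")),
            class = "absorption_spectrum")
}

#' Locate a band maximum
#'
#' Frequency of the maximum intensity within a search range, refined by
#' three-point parabolic interpolation.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param range_cm1 Two-element search interval (cm^-1).
#' @return Peak position in cm^-1.
#' @export
find_band_peak <- function(spectrum, range_cm1) {
  tab <- spectrum$table
  sel <- which(tab$wavenumber >= range_cm1[1] &
               tab$wavenumber <= range_cm1[2])
  if (length(sel) == 0) stop("empty search range")
  i <- sel[which.max(tab$intensity[sel])]
  if (i > 1 && i < nrow(tab)) {
    y1 <- tab$intensity[i - 1]; y2 <- tab$intensity[i]
    y3 <- tab$intensity[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (abs(denom) > .Machine$double.eps) {
      delta <- 0.5 * (y1 - y3) / denom
      if (abs(delta) <= 1)
        return(tab$wavenumber[i] +
               delta * (tab$wavenumber[2] - tab$wavenumber[1]))
    }
  }
  tab$wavenumber[i]
}

#' Compare band positions of two spectra
#'
#' @param spectrum_a,spectrum_b `absorption_spectrum` objects on
#'   overlapping frequency grids.
#' @param bands Data frame with columns `name`, `lo`, `hi` (cm^-1), or a
#'   list of two-element ranges.
#' @return Data frame with per-band peak positions and the signed shift
#'   `peak_a - peak_b` (cm^-1).
#' @export
compare_spectra <- function(spectrum_a, spectrum_b, bands) {
  if (!is.data.frame(bands)) {
    bands <- data.frame(
      name = if (!is.null(names(bands))) names(bands)
             else paste0("band", seq_along(bands)),
      lo = vapply(bands, function(b) b[1], 1),
      hi = vapply(bands, function(b) b[2], 1))
  }
  lo_a <- min(spectrum_a$table$wavenumber)
  hi_a <- max(spectrum_a$table$wavenumber)
  lo_b <- min(spectrum_b$table$wavenumber)
  hi_b <- max(spectrum_b$table$wavenumber)
  if (min(hi_a, hi_b) <= max(lo_a, lo_b))
    stop("spectra have non-overlapping frequency grids")
  pa <- vapply(seq_len(nrow(bands)), function(i)
    find_band_peak(spectrum_a, c(bands$lo[i], bands$hi[i])), 1)
  pb <- vapply(seq_len(nrow(bands)), function(i)
    find_band_peak(spectrum_b, c(bands$lo[i], bands$hi[i])), 1)
  data.frame(band = bands$name, lo = bands$lo, hi = bands$hi,
             peak_a = pa, peak_b = pb, shift = pa - pb)
}

#' Write a spectrum as two-column CSV with a metadata header
#'
#' @param spectrum An `absorption_spectrum`.
#' @param file Output path.
#' @param meta Named character vector of extra metadata lines.
#' @return Invisibly, `file`.
#' @export
write_spectrum <- function(spectrum, file, meta = character()) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_tau_fs = %g", spectrum$window_tau_fs), con)
  writeLines(sprintf("# dt_fs = %g", spectrum$dt_fs), con)
  writeLines(sprintf("# %s", spectrum$note), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s = %s", nm, meta[[nm]]), con)
  writeLines("wavenumber_cm1,intensity", con)
  writeLines(sprintf("%.8g,%.8g", spectrum$table$wavenumber,
                     spectrum$table$intensity), con)
  invisible(file)
}

#' Read a spectrum written by [write_spectrum()]
#' @param file Path.
#' @return An `absorption_spectrum`.
#' @export
read_spectrum <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  tau <- as.numeric(sub(".*= *", "",
                        grep("window_tau_fs", hdr, value = TRUE)[1]))
  dt <- as.numeric(sub(".*= *", "", grep("dt_fs", hdr, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  names(tab) <- c("wavenumber", "intensity")
  structure(list(table = tab, window_tau_fs = tau, dt_fs = dt,
                 note = "read from file"),
            class = "absorption_spectrum")
}

#' @export
plot.absorption_spectrum <- function(x, xlim = c(0, 4500), ...) {
  sel <- x$table$wavenumber >= xlim[1] & x$table$wavenumber <= xlim[2]
  plot(x$table$wavenumber[sel], x$table$intensity[sel], type = "l",
       xlab = expression(tilde(nu) ~ (cm^-1)),
       ylab = "intensity (normalized)", ...)
  invisible(x)
}
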