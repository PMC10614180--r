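# Extended-XYZ trajectory I/O: cell in the Lattice= comment field,
# per-frame time tag. Written by hand since no installed R package handles
# the extended-XYZ comment conventions.

#' Write configurations in extended-XYZ format
#'
#' @param frames A single n x 3 matrix, or an (n, 3, F) array of frames.
#' @param species Character vector of atom species.
#' @param cell A `simulation_cell` or `NULL`.
#' @param file Output path.
#' @param time_fs Optional per-frame times (fs).
#' @param append Append to an existing file.
#' @return Invisibly, `file`.
#' @export
write_xyz <- function(frames, species, file, cell = NULL, time_fs = NULL,
                      append = FALSE) {
  frames <- as_frame_array(frames)
  nat <- dim(frames)[1]
  nf <- dim(frames)[3]
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  lat <- if (!is.null(cell))
    sprintf('Lattice="%g 0 0 0 %g 0 0 0 %g" ', cell$edges[1],
            cell$edges[2], cell$edges[3]) else ""
  for (f in seq_len(nf)) {
    writeLines(as.character(nat), con)
    tcom <- if (!is.null(time_fs)) sprintf("Time=%g ", time_fs[f]) else ""
    writeLines(sprintf('%s%sProperties=species:S:1:pos:R:3', lat, tcom),
               con)
    writeLines(sprintf("%s %.10f %.10f %.10f", species, frames[, 1, f],
                       frames[, 2, f], frames[, 3, f]), con)
  }
  invisible(file)
}

#' Read an extended-XYZ file
#'
#' @param file Path.
#' @return List with `frames` (n, 3, F array), `species`, `cell` (edges or
#'   NULL), `time_fs` (or NULL).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  times <- numeric()
  species <- NULL
  cell <- NULL
  i <- 1
  while (i <= length(lines)) {
    nat <- as.integer(lines[i])
    comment <- lines[i + 1]
    m <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(m) == 2) {
      lat <- as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]])
      cell <- lat[c(1, 5, 9)]
    }
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tm) == 2) times <- c(times, as.numeric(tm[2]))
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + nat)]), "\\s+")
    species <- vapply(rows, `[[`, "", 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nat
  }
  list(frames = as_frame_array(frames), species = species, cell = cell,
       time_fs = if (length(times) > 0) times else NULL)
}
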