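# Physical constants and unit conversions. Everything inside the package is
# in Hartree atomic units (lengths a0, energies hartree, masses m_e,
# hbar = e = 1); fs, K, Angstrom, kcal/mol and cm^-1 appear only at the I/O
# boundaries.

.fq <- list(
  kB            = 3.166811563e-6,     # hartree / K
  autime_fs     = 2.4188843265857e-2, # fs per atomic time unit
  bohr_A        = 0.529177210903,     # Angstrom per a0
  hartree_kcal  = 627.509474,         # kcal/mol per hartree
  amu_me        = 1822.888486209,     # electron masses per unified amu
  hartree_cm1   = 219474.6313632,     # cm^-1 per hartree (angular a.u.)
  cm1_per_invfs = 3.335640951981521e4 # cm^-1 per (cycle/fs)
)

#' Unit conversion constants used by fqcmd
#'
#' Returns the conversion factors between the internal Hartree atomic units
#' and the laboratory units used at the package interfaces (fs, K, Angstrom,
#' kcal/mol, cm^-1).
#'
#' @return Named list of conversion factors.
#' @export
fqcmd_units <- function() .fq

fs_to_au <- function(t_fs) t_fs / .fq$autime_fs
au_to_fs <- function(t_au) t_au * .fq$autime_fs
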