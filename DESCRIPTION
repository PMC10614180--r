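Package: fqcmd
Title: Fast Quasi-Centroid Molecular Dynamics for Water and Ice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates nuclear-quantum-effect-corrected vibrational (dipole
    absorption) spectra of flexible q-TIP4P/f water and hexagonal ice with
    the fast quasi-centroid molecular dynamics (f-QCMD) method. A short
    path-integral molecular dynamics simulation samples quasi-centroid
    distribution functions (three intermolecular radial distribution
    functions plus intramolecular bond-length and bond-angle densities);
    a regularized iterative Boltzmann inversion fits intra- and
    intermolecular corrections to the classical potential so that classical
    dynamics on the corrected potential reproduces those distributions; and
    infrared spectra are computed from the Hann-windowed dipole-derivative
    autocorrelation function of classical trajectories on the fitted
    quasi-centroid potential of mean force. Includes deterministic structure
    generators for liquid water boxes and proton-disordered hexagonal ice,
    compiled molecular dynamics and path-integral engines, and a staged
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
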