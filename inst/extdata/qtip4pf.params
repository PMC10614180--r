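# q-TIP4P/f: flexible four-site point-charge water model.
# Parameter values from the model's defining publication:
#   S. Habershon, T. E. Markland and D. E. Manolopoulos,
#   J. Chem. Phys. 131, 024501 (2009), Table I.
# The O-H stretch is the quartic Taylor expansion of a Morse potential with
# depth D_r and range a_r; the bend is harmonic; the M site carries the
# negative charge, displaced from O toward the H-H midpoint by gamma_M.

r_eq_angstrom     = 0.9419
D_r_kcalmol       = 116.09
a_r_invangstrom   = 2.287
theta_eq_deg      = 107.4
k_theta_kcalmol   = 87.85
sigma_OO_angstrom = 3.1589
eps_OO_kcalmol    = 0.1852
q_H_e             = 0.5564
gamma_M           = 0.73612
m_O_amu           = 15.9994
m_H_amu           = 1.008
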