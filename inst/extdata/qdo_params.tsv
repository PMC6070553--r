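# Illustrative per-element QDO parameter table -- EDIT OR OVERRIDE FOR
# PRODUCTION USE.  Columns:
#   element      chemical symbol
#   alpha1_free  free-atom dipole polarizability, bohr^3
#   alpha2_free  free-atom quadrupole polarizability, bohr^5
#   omega        QDO frequency, atomic units
# Provenance: alpha1_free are standard free-atom reference dipole
# polarizabilities; omega follows the London closure omega = 4 C6 /
# (3 alpha1^2) with homonuclear free-atom C6 values (H 6.5, C 46.6,
# N 24.2, O 15.6 hartree bohr^6).  alpha2_free for H is the exact
# hydrogen-atom value (15 bohr^5); for C, N, O the values are synthetic
# QDO-model estimates alpha2 = (3/4) alpha1 / omega (Drude mass = 1),
# supplied only so the package runs out of the box.  Replace with
# reference free-atom quadrupole polarizabilities for quantitative work.
element	alpha1_free	alpha2_free	omega
H	4.50	15.000	0.42798
C	12.00	20.858	0.43148
N	7.40	9.419	0.58924
O	5.40	5.678	0.71331
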