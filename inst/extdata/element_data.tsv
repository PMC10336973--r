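# Per-element constants and default prediction-error statistics.
#
# Columns:
#   symbol  element symbol
#   Z       atomic number (unitless)
#   chi_S   Sanderson electronegativity, unitless (Sanderson, J. Chem. Educ. 1988, 65, 112)
#   chi_P   Pauling electronegativity, unitless (Allred, J. Inorg. Nucl. Chem. 1961, 17, 215)
#   r_cov   covalent radius, Angstrom (Cordero et al., Dalton Trans. 2008, 2832; C is sp3)
#   mu      mean prediction error of the shipped per-element charge models, electrons
#   sigma   standard deviation of the prediction error, electrons
#
# mu/sigma are the default error-distribution parameters used by the
# error-statistics-weighted equilibration kernels; tailor-made models
# should override them with their own validation statistics.
symbol	Z	chi_S	chi_P	r_cov	mu	sigma
C	6	2.746	2.55	0.76	3.77e-5	1.54e-2
H	1	2.592	2.20	0.31	-2.98e-4	8.98e-3
O	8	3.654	3.44	0.66	-1.97e-4	1.11e-2
N	7	3.194	3.04	0.71	-2.83e-4	2.21e-2
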