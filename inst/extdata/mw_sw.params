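# Stillinger-Weber parameterization of the coarse-grained mW water model
# (monatomic water; tetrahedrality through the three-body term).
# Units: epsilon kJ/mol, sigma Angstrom; remaining constants dimensionless.
# version = 1
epsilon = 25.894776
sigma = 2.3925
a_cut = 1.8
A = 7.049556277
B = 0.6022245584
p = 4
q = 0
lambda3 = 23.15
gamma3 = 1.2
cos_theta0 = -0.333333333333
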