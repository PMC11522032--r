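# Default force-field constants for the coarse-grained collagen fibril model.
# Units: lengths in Angstrom, energies in kcal/mol, stiffness in kcal/mol/A^2
# (bonds) or kcal/mol/rad^2 (angles), mass in amu.
version: 1
mass: 1358.7
angle:
  k_bend: 14.98
  # "double": E = k*(phi - phi_i)^2 (moment 2*k*dphi); "half": E = 0.5*k*dphi^2
  convention: double
pair:
  epsilon: 6.87
  sigma: 14.72
  lambda: 0.9
  # cutoff = cutoff_factor * sigma; energy shifted to zero at the cutoff
  cutoff_factor: 2.5
bonds:
  backbone:
    r0: 14.00
    r1: 18.20
    r_break: 21.00
    k0: 17.13
    k1: 97.66
    z: 0.05
  extension:
    r0: 14.00
    r1: 18.20
    r_break: 70.00
    k0: 17.13
    k1: 97.66
    z: 0.05
  ecl_divalent:
    r0: 18.52
    r1: 20.52
    r_break: 23.20
    k0: 0.20
    k1: 41.84
    z: 0.05
  ecl_trivalent:
    r0: 18.52
    r1: 22.12
    r_break: 24.81
    k0: 0.20
    k1: 54.60
    z: 0.05
  age:
    r0: 18.52
    r1: 22.72
    r_break: 31.72
    k0: 0.10
    k1: 8.00
    z: 0.05
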