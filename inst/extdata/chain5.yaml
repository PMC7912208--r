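# Five-bead chain analogue of a small molecule: reversible gEDMD on the two
# dihedral angles with a tensor periodic-Gaussian dictionary, KM offsets
# spanning one decade. Six metastable states (3 x 2 dihedral wells).
model:
  kind: overdamped
  potential: chain5
  beta: 1.0
  gamma: 1.0
simulation:
  dt: 1.0e-3
  steps: 4000000
  seed: 42
  burn_in_frac: 0.01
rc:
  name: dihedral
basis:
  family: tensor_periodic_gaussian
  centers: linspace(-2.827433388230814, 2.827433388230814, 10)
  bandwidth: 0.05
estimator:
  type: rev
  offsets: [1.0e-3, 2.0e-3, 5.0e-3, 1.0e-2]
  mass_tol: 1.0e-6
  imag_tol: 0.5
analysis:
  n_eigs: 6
  pcca_states: 6
  grid: linspace(-3.06, 3.06, 40)
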