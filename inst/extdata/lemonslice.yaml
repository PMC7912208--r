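# Overdamped dynamics in the lemon-slice potential projected on the polar
# angle: reversible-estimator reference plus a Kramers-Moyal offset scan.
model:
  kind: overdamped
  potential: lemon
  beta: 1.0
  gamma: 1.0
simulation:
  dt: 1.0e-3
  steps: 5000000
  seed: 42
  burn_in_frac: 0.01
rc:
  name: polar-angle
basis:
  family: gaussian
  centers: linspace(-2.8, 2.8, 15)
  bandwidth: 0.1
estimator:
  type: rev
  offsets: [1.0e-3, 5.0e-3, 1.0e-2, 5.0e-2, 1.0e-1]
  mass_tol: 1.0e-6
  imag_tol: 0.1
analysis:
  n_eigs: 4
  pcca_states: 4
  bins: 50
  grid: linspace(-2.9, 2.9, 240)
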