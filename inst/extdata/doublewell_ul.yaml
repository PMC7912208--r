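# Underdamped double-well: KM-gEDMD on the x position across offsets spanning
# the 1/gamma crossover (small offsets yield near-zero effective coefficients).
model:
  kind: underdamped
  potential: doublewell
  beta: 0.4
  gamma: 10.0
simulation:
  dt: 1.0e-3
  steps: 10000000
  seed: 43
  burn_in_frac: 0.01
rc:
  name: x
basis:
  family: gaussian
  centers: linspace(-2.5, 2.5, 15)
  bandwidth: 0.1
estimator:
  type: km
  offsets: [1.0e-3, 1.0e-1, 2.0e-1, 5.0e-1, 1.0]
  mass_tol: 1.0e-6
  imag_tol: 0.5
analysis:
  n_eigs: 3
  pcca_states: 2
  bins: 50
  grid: linspace(-1.8, 1.8, 200)
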