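Package: projgen
Title: Spectral Analysis of Projected Generators for Diffusion Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing spectral properties (eigenvalues, implied
    timescales, metastable decompositions) of effective generators obtained by
    projecting diffusion processes onto reaction coordinates. Provides bundled
    overdamped and underdamped Langevin models with a compiled Euler-Maruyama
    integrator, Galerkin (gEDMD) approximation of the generator from trajectory
    data using exact-parameter and Kramers-Moyal finite-difference estimators,
    binned Kramers-Moyal effective drift/diffusion estimation, PCCA metastable
    membership functions, and a numerical verification suite for an energy-norm
    relative eigenvalue error bound.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
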