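#' Read and validate a run configuration
#'
#' Configurations are YAML documents with blocks `model` (kind, potential,
#' beta, gamma), `simulation` (dt, steps, seed, burn_in_frac), `rc` (name),
#' `basis` (family, centers, bandwidth, or grid for tensor bases),
#' `estimator` (type, offsets, mass_tol, imag_tol), `analysis` (n_eigs,
#' pcca_states, bins, grid) and `output` (dir). Center/grid specifications
#' accept either explicit numeric lists or the string
#' `"linspace(start, stop, n)"` (endpoints included).
#'
#' @param path YAML file path.
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a raw config list.
#' @export
validate_run_config <- function(config) {
  req <- function(block, field, check = NULL) {
    v <- config[[block]][[field]]
    if (is.null(v)) stop(sprintf("config missing %s.%s", block, field))
    if (!is.null(check) && !check(v))
      stop(sprintf("config field %s.%s is invalid", block, field))
    v
  }
  req("model", "kind", function(v) v %in% c("overdamped", "underdamped"))
  req("model", "potential",
      function(v) v %in% c("ou", "lemon", "doublewell", "chain5"))
  req("model", "beta", function(v) is.numeric(v) && v > 0)
  req("model", "gamma", function(v) is.numeric(v) && v > 0)
  req("simulation", "dt", function(v) is.numeric(v) && v > 0)
  req("simulation", "steps", function(v) is.numeric(v) && v >= 1)
  req("simulation", "seed", function(v) is.numeric(v))
  req("rc", "name",
      function(v) v %in% c("x", "polar-angle", "dihedral", "oscillating"))
  req("basis", "family",
      function(v) v %in% c("gaussian", "periodic_gaussian", "hermite",
                           "tensor_gaussian", "tensor_periodic_gaussian"))
  req("estimator", "type", function(v) v %in% c("rev", "nonrev", "km"))
  structure(config, class = "run_config")
}

.parse_linspace <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec(
    "linspace\\(\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+]+)\\s*,\\s*([0-9]+)\\s*\\)", x))[[1]]
  if (length(m) != 4) stop("cannot parse center specification: ", x)
  seq(as.numeric(m[2]), as.numeric(m[3]), length.out = as.integer(m[4]))
}

.config_potential <- function(config) {
  switch(config$model$potential,
         ou = do.call(ou_potential, config$model$parameters %||% list()),
         lemon = lemon_slice_potential(),
         doublewell = double_well_potential(),
         chain5 = do.call(chain5_potential, config$model$parameters %||% list()))
}

.config_rc <- function(config, model) {
  switch(config$rc$name,
         "x" = rc_select(1L, model$dim),
         "polar-angle" = rc_polar_angle(),
         "dihedral" = rc_dihedral(list(1:4, 2:5), n_beads = 5L),
         "oscillating" = rc_oscillating(config$rc$m %||% 0L))
}

.config_basis <- function(config) {
  b <- config$basis
  if (b$family == "hermite") return(hermite_basis(b$n_max %||% 10L))
  if (b$family %in% c("gaussian", "periodic_gaussian")) {
    ctor <- if (b$family == "gaussian") gaussian_basis else
      periodic_gaussian_basis
    return(ctor(.parse_linspace(b$centers), b$bandwidth,
                rho_convention = b$rho_convention %||% "divide"))
  }
  ctor <- if (b$family == "tensor_gaussian") gaussian_basis else
    periodic_gaussian_basis
  cx <- .parse_linspace(b$centers_x %||% b$centers)
  cy <- .parse_linspace(b$centers_y %||% b$centers)
  tensor_grid_basis(ctor(cx, b$bandwidth,
                         rho_convention = b$rho_convention %||% "divide"),
                    ctor(cy, b$bandwidth,
                         rho_convention = b$rho_convention %||% "divide"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment end to end
#'
#' Pipeline: simulate (Euler-Maruyama) -> assemble the reference Galerkin
#' system (exact-parameter estimator, or KM at the smallest offset for
#' `type: km` without model knowledge) -> solve -> optional KM offset scan ->
#' optional binned KM coefficient estimates -> optional PCCA memberships on a
#' grid. Writes JSON (spectrum, provenance), CSV (scan, KM bins, memberships)
#' and the resolved configuration next to the outputs; all randomness derives
#' from the configured seed.
#'
#' @param config a `run_config` (or path to one).
#' @param output_dir overrides `config$output$dir`.
#' @return (invisibly) list with `trajectory`, `system`, `spectral`,
#'   `timescales`, and any of `scan`, `km`, `pcca` that were requested.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  t0 <- Sys.time()
  out_dir <- output_dir %||% config$output$dir %||% tempfile("projgen_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  logf("projgen run started %s", format(t0))
  pot <- stage("model", .config_potential(config))
  model <- stage("model",
                 make_model(ifelse(config$model$kind == "underdamped",
                                   "underdamped", "overdamped"),
                            pot, beta = config$model$beta,
                            gamma = config$model$gamma))
  sim <- config$simulation
  burn <- ceiling((sim$burn_in_frac %||% 0.01) * sim$steps)
  traj <- stage("simulate",
                simulate_em(model, dt = sim$dt, n_steps = sim$steps,
                            seed = as.integer(sim$seed), burn_in = burn))
  logf("simulated %d states (dt=%g, seed=%d)", nrow(traj), sim$dt, sim$seed)
  rc <- stage("rc", .config_rc(config, model))
  basis <- stage("basis", .config_basis(config))
  est <- config$estimator
  n_eigs <- config$analysis$n_eigs %||% min(basis$n_functions, 5L)
  sys <- stage("assemble", switch(
    est$type,
    rev = assemble_reversible(traj, rc, basis, model),
    nonrev = assemble_nonreversible(traj, rc, basis, model),
    km = assemble_km(traj, rc, basis,
                     offset_s = min(unlist(est$offsets %||% sim$dt)))))
  spectral <- stage("solve",
                    solve(sys, n_eigs = n_eigs,
                          mass_tol = est$mass_tol %||% 1e-10,
                          imag_tol = est$imag_tol %||% 0.1))
  ts <- suppressWarnings(implied_timescales(spectral))
  logf("rates: %s", paste(signif(spectral$eigenvalues, 6), collapse = ", "))
  result <- list(trajectory = traj, system = sys, spectral = spectral,
                 timescales = ts)
  spectrum_json <- list(
    eigenvalues = spectral$eigenvalues, timescales = as.numeric(ts),
    estimator = spectral$estimator, offset = spectral$offset,
    discarded_imag = spectral$discarded_imag,
    seed = as.integer(sim$seed), n_samples = sys$n_samples,
    basis = list(family = basis$family, n_functions = basis$n_functions))
  jsonlite::write_json(spectrum_json, file.path(out_dir, "spectrum.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  offsets <- unlist(est$offsets)
  if (length(offsets)) {
    scan <- stage("scan", offset_scan(traj, rc, basis, offsets, spectral,
                                      n_eigs = n_eigs))
    utils::write.csv(scan, file.path(out_dir, "offset_scan.csv"),
                     row.names = FALSE)
    result$scan <- scan
  }
  if (!is.null(config$analysis$bins) && rc$m == 1L && length(offsets)) {
    kms <- lapply(offsets, function(s)
      km_binned(km_differences(traj, rc, s), n_bins = config$analysis$bins))
    km_df <- do.call(rbind, lapply(kms, function(k)
      data.frame(offset = k$offset, bin_center = k$bin_centers,
                 drift = k$drift, diffusion = k$diffusion,
                 count = k$counts)))
    utils::write.csv(km_df, file.path(out_dir, "km_bins.csv"),
                     row.names = FALSE)
    result$km <- kms
  }
  K <- config$analysis$pcca_states
  if (!is.null(K)) {
    grid <- stage("pcca", {
      g <- config$analysis$grid
      if (is.null(g)) stop("analysis.grid required for PCCA")
      if (rc$m == 1L) matrix(.parse_linspace(g), ncol = 1)
      else as.matrix(expand.grid(.parse_linspace(g), .parse_linspace(g)))
    })
    ef <- evaluate_eigenfunctions(spectral, grid, which = seq_len(K))
    pc <- stage("pcca", pcca(ef, K))
    pc_df <- data.frame(grid, pc$memberships, label = pc$crisp_labels,
                        transition = pc$transition_mask)
    utils::write.csv(pc_df, file.path(out_dir, "pcca.csv"), row.names = FALSE)
    result$pcca <- pc
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  logf("finished in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result$output_dir <- out_dir
  invisible(result)
}
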