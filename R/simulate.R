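#' Simulate a model with the Euler-Maruyama scheme
#'
#' Integrates `x[k+1] = x[k] + b(x[k]) dt + sigma(x[k]) sqrt(dt) zeta[k]` with
#' standard normal `zeta[k]`. Bundled potentials use a compiled stepper; other
#' models fall back to an R loop. Trajectories are bit-reproducible given the
#' seed. The integration aborts with the step index if a state becomes
#' non-finite or leaves `|x| > guard` (the lemon-slice potential has a `1/r`
#' singularity, so runaway states are caught early).
#'
#' @param model an [make_model()] model.
#' @param x0 initial state; defaults to the potential minimum (underdamped:
#'   zero momenta).
#' @param dt time step (> 0).
#' @param n_steps number of steps (>= 1).
#' @param seed integer seed recorded on the trajectory.
#' @param burn_in number of initial states to discard (default 1% of steps).
#' @param guard divergence guard on `max |x_i|`.
#' @param noise_factor multiplier on sigma (0 gives the deterministic Euler
#'   scheme, used for integrator checks).
#' @return a `trajectory`: T x d matrix with attributes `dt`, `seed`,
#'   `burn_in_discarded`, `model_name`.
#' @export
simulate_em <- function(model, x0 = NULL, dt, n_steps, seed = 1L,
                        burn_in = ceiling(0.01 * n_steps), guard = 1e6,
                        noise_factor = 1) {
  stopifnot(inherits(model, "sde_model"))
  if (!(dt > 0)) stop("dt must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  burn_in <- as.integer(burn_in)
  if (burn_in > n_steps) stop("burn_in exceeds n_steps")
  if (is.null(x0)) {
    x0 <- model$potential$minimum
    if (is.null(x0)) stop("x0 required: potential has no stored minimum")
    if (model$kind == "underdamped") x0 <- c(x0, numeric(model$dim_position))
  }
  x0 <- as.numeric(x0)
  if (length(x0) != model$dim) stop("x0 has wrong dimension")
  set.seed(seed)
  pot <- model$potential
  if (!is.null(pot$cpp_id) && model$kind %in% c("overdamped", "underdamped")) {
    par <- if (!is.null(pot$cpp_par)) pot$cpp_par else
      as.numeric(unlist(pot$parameters))
    res <- if (model$kind == "overdamped") {
      sim_overdamped_cpp(pot$cpp_id, par, x0, dt, n_steps, model$beta,
                         model$gamma, burn_in, guard, noise_factor)
    } else {
      sim_underdamped_cpp(pot$cpp_id, par, x0, dt, n_steps, model$beta,
                          model$gamma, burn_in, guard, noise_factor)
    }
    states <- res$states
  } else {
    states <- .simulate_em_r(model, x0, dt, n_steps, burn_in, guard,
                             noise_factor)
  }
  trajectory(states, dt = dt, seed = seed, burn_in_discarded = burn_in,
             model_name = pot$name)
}

# plain R fallback stepper (small problems, generic models)
.simulate_em_r <- function(model, x0, dt, n_steps, burn_in, guard,
                           noise_factor) {
  d <- model$dim
  info <- model$a_info
  # constant sigma = sqrt(a) for all supported structures
  sigma <- if (info$type == "iso") {
    diag(sqrt(info$scale), d)
  } else if (info$type == "ul") {
    s <- matrix(0, d, d)
    dp <- info$d_pos
    s[(dp + 1):d, (dp + 1):d] <- diag(sqrt(info$scale), dp)
    s
  } else {
    e <- eigen(info$a, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), d) %*% t(e$vectors)
  }
  sigma <- noise_factor * sigma * sqrt(dt)
  keep <- n_steps + 1 - burn_in
  out <- matrix(NA_real_, keep, d)
  x <- x0
  if (burn_in == 0) out[1, ] <- x
  for (s in seq_len(n_steps)) {
    b <- as.numeric(model$drift(matrix(x, 1)))
    x <- x + b * dt + as.numeric(sigma %*% stats::rnorm(d))
    if (any(!is.finite(x)) || max(abs(x)) > guard)
      stop(sprintf("simulation diverged at step %d", s))
    if (s >= burn_in) out[s - burn_in + 1, ] <- x
  }
  out
}

#' Trajectory container
#'
#' @param states T x d numeric matrix of states (rows = time-ordered samples).
#' @param dt time step between rows.
#' @param seed integer seed used to generate the data (or NA).
#' @param burn_in_discarded number of initial states that were discarded.
#' @param model_name identifier of the generating model.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(states, dt, seed = NA_integer_, burn_in_discarded = 0L,
                       model_name = "unknown") {
  states <- as.matrix(states)
  if (nrow(states) < 2) stop("trajectory needs at least 2 states")
  if (!(dt > 0)) stop("dt must be > 0")
  if (any(!is.finite(states))) stop("trajectory contains non-finite states")
  structure(states, dt = dt, seed = as.integer(seed),
            burn_in_discarded = as.integer(burn_in_discarded),
            model_name = model_name, class = c("trajectory", "matrix"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d states x %d dims, dt = %g, seed = %s, model = %s\n",
              nrow(x), ncol(x), attr(x, "dt"), attr(x, "seed"),
              attr(x, "model_name")))
  invisible(x)
}

#' Write a trajectory to disk
#'
#' `format = "text"`: delimited text with a comment line
#' `# dt=<float> seed=<int> burn_in=<int> model=<name>`, a header row naming
#' columns, and one state per row (17 significant digits, so doubles
#' round-trip exactly). `format = "binary"`: packed little-endian doubles with
#' a small header (magic `PGTB`).
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param format `"text"` or `"binary"`.
#' @export
write_trajectory <- function(traj, path, format = c("text", "binary")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  dt <- attr(traj, "dt"); seed <- attr(traj, "seed")
  burn <- attr(traj, "burn_in_discarded"); name <- attr(traj, "model_name")
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# dt=%.17g seed=%d burn_in=%d model=%s",
                       dt, seed, burn, name), con)
    writeLines(paste(sprintf("x%d", seq_len(ncol(traj))), collapse = "\t"), con)
    utils::write.table(format(unclass(traj), digits = 17, scientific = TRUE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("PGTB", con, 4, eos = NULL)
    writeBin(c(1L, nrow(traj), ncol(traj), seed, burn, nchar(name)), con,
             size = 4L, endian = "little")
    writeChar(name, con, nchar(name), eos = NULL)
    writeBin(dt, con, size = 8L, endian = "little")
    writeBin(as.numeric(traj), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' The format (text or packed binary) is detected from the file's magic bytes.
#'
#' @param path input file.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path) {
  magic <- readBin(path, "raw", 4)
  if (identical(rawToChar(magic), "PGTB")) {
    con <- file(path, "rb")
    on.exit(close(con))
    readChar(con, 4, useBytes = TRUE)
    hd <- readBin(con, "integer", 6, size = 4L, endian = "little")
    name <- readChar(con, hd[6], useBytes = TRUE)
    dt <- readBin(con, "double", 1, size = 8L, endian = "little")
    x <- readBin(con, "double", hd[2] * hd[3], size = 8L, endian = "little")
    return(trajectory(matrix(x, hd[2], hd[3]), dt = dt, seed = hd[4],
                      burn_in_discarded = hd[5], model_name = name))
  }
  lines <- readLines(path, n = 1)
  meta <- regmatches(lines, gregexpr("(\\w+)=([^ ]+)", lines))[[1]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  x <- as.matrix(utils::read.table(path, skip = 1, header = TRUE, sep = "\t"))
  trajectory(x, dt = as.numeric(vals[["dt"]]),
             seed = as.integer(vals[["seed"]]),
             burn_in_discarded = as.integer(vals[["burn_in"]]),
             model_name = vals[["model"]])
}
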