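#' Potential energy specification
#'
#' Bundles an energy function, its analytic gradient and named parameters into
#' a `potential` object usable by [make_model()]. Both `energy` and `gradient`
#' must accept a state matrix (rows = states) and return a vector / matrix.
#'
#' @param name identifier of the potential.
#' @param dim state-space dimension.
#' @param energy function: n x d matrix -> numeric(n), in energy units.
#' @param gradient function: n x d matrix -> n x d matrix.
#' @param parameters named list of scalar parameters.
#' @param cpp_id internal id of a compiled gradient (bundled potentials only).
#' @param minimum a typical minimum of the potential, used as default initial
#'   condition for simulations.
#' @return an object of class `potential`.
#' @export
potential <- function(name, dim, energy, gradient, parameters = list(),
                      cpp_id = NULL, minimum = NULL) {
  stopifnot(is.function(energy), is.function(gradient), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), energy = energy,
                 gradient = gradient, parameters = parameters,
                 cpp_id = cpp_id, minimum = minimum),
            class = "potential")
}

#' @export
print.potential <- function(x, ...) {
  cat("<potential>", x$name, sprintf("(dim = %d)\n", x$dim))
  if (length(x$parameters))
    cat("  parameters:", paste(names(x$parameters), unlist(x$parameters),
                               sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

.as_state_matrix <- function(x, dim) {
  if (is.null(base::dim(x))) x <- matrix(x, ncol = dim, byrow = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Two-dimensional anisotropic quadratic potential
#'
#' `V(x, y) = (alpha_x x^2 + alpha_y y^2) / 2`. Under overdamped Langevin
#' dynamics this is the Ornstein-Uhlenbeck process whose generator spectrum is
#' known in closed form: the rates are `r alpha_x + s alpha_y` for integers
#' `r, s >= 0`, with Hermite-polynomial eigenfunctions.
#'
#' @param alpha_x,alpha_y curvature parameters (> 0).
#' @return a `potential` of dimension 2.
#' @export
ou_potential <- function(alpha_x = 1, alpha_y = 5) {
  a <- c(alpha_x, alpha_y)
  potential(
    name = "quadratic_2d", dim = 2L,
    energy = function(x) {
      x <- .as_state_matrix(x, 2L)
      0.5 * (a[1] * x[, 1]^2 + a[2] * x[, 2]^2)
    },
    gradient = function(x) {
      x <- .as_state_matrix(x, 2L)
      cbind(a[1] * x[, 1], a[2] * x[, 2])
    },
    parameters = list(alpha_x = alpha_x, alpha_y = alpha_y),
    cpp_id = 1L, minimum = c(0, 0))
}

#' Lemon-slice potential
#'
#' A two-dimensional potential written in polar coordinates `(r, phi)`:
#' `V = cos(4 phi) + 1 / cos(phi / 2) + 10 (r - 1)^2 + 1 / r`.
#' The angular part has four minima separated by barriers; the `1/cos(phi/2)`
#' and `1/r` terms impose infinite barriers along the negative x-axis and at
#' the origin, so the slow dynamics are transitions between the four wells in
#' the polar angle.
#'
#' @return a `potential` of dimension 2 (Cartesian state).
#' @export
lemon_slice_potential <- function() {
  potential(
    name = "lemon_slice", dim = 2L,
    energy = function(x) {
      x <- .as_state_matrix(x, 2L)
      r <- sqrt(x[, 1]^2 + x[, 2]^2)
      phi <- atan2(x[, 2], x[, 1])
      cos(4 * phi) + 1 / cos(0.5 * phi) + 10 * (r - 1)^2 + 1 / r
    },
    gradient = function(x) {
      x <- .as_state_matrix(x, 2L)
      potential_grad_cpp(2L, numeric(0), x)
    },
    cpp_id = 2L,
    minimum = c(cos(pi / 4), sin(pi / 4)))
}

#' Two-dimensional quartic double-well potential
#'
#' `V(x, y) = 3 x^4 - 5 x^2 + 1.5 x + 3 y^2`: an asymmetric double well along
#' x (barrier near x = 0) and a harmonic confinement in y. The slow process is
#' barrier crossing along x.
#'
#' @return a `potential` of dimension 2.
#' @export
double_well_potential <- function() {
  potential(
    name = "double_well", dim = 2L,
    energy = function(x) {
      x <- .as_state_matrix(x, 2L)
      3 * x[, 1]^4 - 5 * x[, 1]^2 + 1.5 * x[, 1] + 3 * x[, 2]^2
    },
    gradient = function(x) {
      x <- .as_state_matrix(x, 2L)
      cbind(12 * x[, 1]^3 - 10 * x[, 1] + 1.5, 6 * x[, 2])
    },
    cpp_id = 3L,
    # left minimum of 12 x^3 - 10 x + 1.5 = 0
    minimum = {
      xs <- polyroot(c(1.5, -10, 0, 12))
      xl <- min(Re(xs[abs(Im(xs)) < 1e-8]))
      c(xl, 0)
    })
}

#' Five-bead chain potential (synthetic molecular analogue)
#'
#' A fifteen-dimensional potential for five beads in three-dimensional space,
#' linked as a chain with harmonic bonds, harmonic bond angles, and cosine
#' dihedral terms `c1 (1 + cos(3 phi1)) + c2 (1 + cos(2 phi2))` on the two
#' dihedral angles. The dihedral terms create 3 x 2 = 6 metastable states in
#' the `(phi1, phi2)` plane. Parameters are this package's own choices; the
#' model mimics a small molecule only qualitatively (no solvent, no physical
#' units).
#'
#' @param kb,r0 bond force constant and rest length.
#' @param ka,theta0 angle force constant and rest angle (radians).
#' @param c1,c2 dihedral barrier parameters (barrier heights `2 c`).
#' @return a `potential` of dimension 15.
#' @export
chain5_potential <- function(kb = 50, r0 = 1, ka = 10, theta0 = 1.91,
                             c1 = 2.5, c2 = 2.0) {
  par <- c(kb, r0, ka, theta0, c1, 3, c2, 2)
  energy1 <- function(x) {
    at <- lapply(1:5, function(i) x[(3 * i - 2):(3 * i)])
    e <- 0
    for (i in 1:4) e <- e + kb * (sqrt(sum((at[[i + 1]] - at[[i]])^2)) - r0)^2
    for (i in 1:3) {
      u <- at[[i]] - at[[i + 1]]; w <- at[[i + 2]] - at[[i + 1]]
      ct <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
      e <- e + ka * (acos(pmin(1, pmax(-1, ct))) - theta0)^2
    }
    ns <- c(3, 2); cs <- c(c1, c2)
    for (i in 1:2) {
      phi <- dihedral_batch_cpp(matrix(x, nrow = 1), as.integer(i:(i + 3)))$phi
      e <- e + cs[i] * (1 + cos(ns[i] * phi))
    }
    e
  }
  p <- potential(
    name = "chain5", dim = 15L,
    energy = function(x) {
      x <- .as_state_matrix(x, 15L)
      vapply(seq_len(nrow(x)), function(m) energy1(x[m, ]), numeric(1))
    },
    gradient = function(x) {
      x <- .as_state_matrix(x, 15L)
      potential_grad_cpp(4L, par, x)
    },
    parameters = list(kb = kb, r0 = r0, ka = ka, theta0 = theta0,
                      c1 = c1, c2 = c2),
    cpp_id = 4L,
    minimum = chain5_initial_state())
  p$cpp_par <- par
  p
}

#' Default initial configuration for the five-bead chain
#'
#' A slightly bent, non-collinear zigzag with bond lengths near 1; dihedral
#' angles are away from singular (collinear) configurations. Used as the
#' default simulation start; the burn-in removes the relaxation transient.
#'
#' @return numeric(15) of bead coordinates (x1, y1, z1, x2, ...).
#' @export
chain5_initial_state <- function() {
  c(0, 0, 0,
    1, 0, 0,
    1.35, 0.94, 0,
    2.30, 1.20, 0.55,
    2.60, 2.10, 1.05)
}

#' Check an analytic gradient against central finite differences
#'
#' @param pot a `potential`.
#' @param points matrix of test points (rows).
#' @param h finite-difference step.
#' @return max relative deviation over points and components.
#' @export
gradient_fd_error <- function(pot, points, h = 1e-5) {
  points <- .as_state_matrix(points, pot$dim)
  g <- pot$gradient(points)
  worst <- 0
  for (m in seq_len(nrow(points))) {
    x <- points[m, ]
    fd <- vapply(seq_len(pot$dim), function(k) {
      e <- numeric(pot$dim); e[k] <- h
      (pot$energy(matrix(x + e, 1)) - pot$energy(matrix(x - e, 1))) / (2 * h)
    }, numeric(1))
    scale <- max(1, max(abs(fd)))
    worst <- max(worst, max(abs(fd - g[m, ])) / scale)
  }
  worst
}
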