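#' Reaction coordinates (coarse-graining maps)
#'
#' A `reaction_coordinate` holds a smooth map `xi` from the full state space
#' (dimension `dim`) to a reduced space (dimension `m`), its Jacobian, an
#' optional Hessian (needed only by the non-reversible exact-parameter
#' estimator), and a per-output periodicity flag (angular outputs live in
#' `(-pi, pi]` and their finite differences are wrapped by minimal image).
#'
#' All maps are vectorized over rows: `map(X)` returns n x m, `jacobian(X)`
#' returns an n x d x m array, `hessian(X)` an n x d x d x m array.
#'
#' @param map,jacobian,hessian vectorized functions as described above.
#' @param dim full state dimension d.
#' @param m reduced dimension.
#' @param periodic logical(m): TRUE for angular outputs.
#' @param name identifier.
#' @return an object of class `reaction_coordinate`.
#' @export
reaction_coordinate <- function(map, jacobian, dim, m = 1L, periodic = FALSE,
                                hessian = NULL, name = "custom") {
  structure(list(map = map, jacobian = jacobian, hessian = hessian,
                 dim = as.integer(dim), m = as.integer(m),
                 periodic = rep_len(as.logical(periodic), m), name = name),
            class = "reaction_coordinate")
}

#' @export
print.reaction_coordinate <- function(x, ...) {
  cat(sprintf("<reaction_coordinate> %s: R^%d -> R^%d (periodic: %s)\n",
              x$name, x$dim, x$m, paste(x$periodic, collapse = ",")))
  invisible(x)
}

#' Coordinate-selection reaction coordinate
#'
#' Projects onto a subset of state coordinates, e.g. the x coordinate of a
#' two-dimensional process, or a position coordinate of an underdamped state
#' `(q, p)`.
#'
#' @param indices column indices of the selected coordinates.
#' @param dim full state dimension.
#' @return a `reaction_coordinate` with zero Hessian.
#' @export
rc_select <- function(indices, dim) {
  indices <- as.integer(indices)
  m <- length(indices)
  reaction_coordinate(
    map = function(x) {
      x <- .as_state_matrix(x, dim)
      x[, indices, drop = FALSE]
    },
    jacobian = function(x) {
      x <- .as_state_matrix(x, dim)
      J <- array(0, c(nrow(x), dim, m))
      for (a in seq_len(m)) J[, indices[a], a] <- 1
      J
    },
    hessian = function(x) {
      x <- .as_state_matrix(x, dim)
      array(0, c(nrow(x), dim, dim, m))
    },
    dim = dim, m = m, periodic = FALSE,
    name = paste0("select(", paste(indices, collapse = ","), ")"))
}

#' Polar-angle reaction coordinate
#'
#' `xi(x, y) = atan2(y, x)`, the polar angle of a planar state, with values in
#' `(-pi, pi]`. Singular at the origin: there the Jacobian entries are
#' non-finite and downstream assemblers skip (or refuse) such samples.
#'
#' @return a periodic `reaction_coordinate` on 2-dimensional states.
#' @export
rc_polar_angle <- function() {
  reaction_coordinate(
    map = function(x) {
      x <- .as_state_matrix(x, 2L)
      matrix(atan2(x[, 2], x[, 1]), ncol = 1)
    },
    jacobian = function(x) {
      x <- .as_state_matrix(x, 2L)
      r2 <- x[, 1]^2 + x[, 2]^2
      J <- array(0, c(nrow(x), 2, 1))
      J[, 1, 1] <- -x[, 2] / r2
      J[, 2, 1] <- x[, 1] / r2
      J
    },
    hessian = function(x) {
      x <- .as_state_matrix(x, 2L)
      r4 <- (x[, 1]^2 + x[, 2]^2)^2
      H <- array(0, c(nrow(x), 2, 2, 1))
      H[, 1, 1, 1] <- 2 * x[, 1] * x[, 2] / r4
      H[, 2, 2, 1] <- -2 * x[, 1] * x[, 2] / r4
      H[, 1, 2, 1] <- (x[, 2]^2 - x[, 1]^2) / r4
      H[, 2, 1, 1] <- H[, 1, 2, 1]
      H
    },
    dim = 2L, m = 1L, periodic = TRUE, name = "polar_angle")
}

#' Dihedral-angle reaction coordinates for bead chains
#'
#' Maps a flat chain state `(x1, y1, z1, x2, ...)` to one or more dihedral
#' (torsion) angles, each defined by four bead indices. Angles are in
#' `(-pi, pi]` and periodic. Jacobians are analytic (standard torsion gradient
#' formulas); Hessians are not provided, so use the reversible or
#' Kramers-Moyal estimators with this coordinate.
#'
#' @param quadruples list of integer(4) bead indices, one per dihedral.
#' @param n_beads number of beads in the chain.
#' @return a `reaction_coordinate` with `m = length(quadruples)`.
#' @export
rc_dihedral <- function(quadruples, n_beads = 5L) {
  if (!is.list(quadruples)) quadruples <- list(quadruples)
  m <- length(quadruples)
  d <- 3L * n_beads
  reaction_coordinate(
    map = function(x) {
      x <- .as_state_matrix(x, d)
      vals <- vapply(quadruples,
                     function(q) dihedral_batch_cpp(x, as.integer(q))$phi,
                     numeric(nrow(x)))
      matrix(vals, ncol = m)
    },
    jacobian = function(x) {
      x <- .as_state_matrix(x, d)
      J <- array(0, c(nrow(x), d, m))
      for (a in seq_len(m))
        J[, , a] <- dihedral_batch_cpp(x, as.integer(quadruples[[a]]))$jacobian
      J
    },
    dim = d, m = m, periodic = TRUE,
    name = paste0("dihedral(", m, ")"))
}

#' Oscillating reaction-coordinate family on the plane
#'
#' `xi_m(x, y) = x + 0.1 sin(m y)`: for `m = 0` this is the perfect coordinate
#' for the slowest Ornstein-Uhlenbeck eigenfunction `psi = x`; for larger `m`
#' its level sets oscillate within a strip of width 0.1, leaving the L2
#' projection error of `x` small while the energy-norm (derivative-weighted)
#' error grows. Used to probe the relative eigenvalue error bound.
#'
#' @param m_osc oscillation index (integer >= 0).
#' @return a `reaction_coordinate` on 2-dimensional states.
#' @export
rc_oscillating <- function(m_osc) {
  stopifnot(m_osc >= 0, m_osc == round(m_osc))
  reaction_coordinate(
    map = function(x) {
      x <- .as_state_matrix(x, 2L)
      matrix(x[, 1] + 0.1 * sin(m_osc * x[, 2]), ncol = 1)
    },
    jacobian = function(x) {
      x <- .as_state_matrix(x, 2L)
      J <- array(0, c(nrow(x), 2, 1))
      J[, 1, 1] <- 1
      J[, 2, 1] <- 0.1 * m_osc * cos(m_osc * x[, 2])
      J
    },
    hessian = function(x) {
      x <- .as_state_matrix(x, 2L)
      H <- array(0, c(nrow(x), 2, 2, 1))
      H[, 2, 2, 1] <- -0.1 * m_osc^2 * sin(m_osc * x[, 2])
      H
    },
    dim = 2L, m = 1L, periodic = FALSE,
    name = sprintf("oscillating(m=%d)", m_osc))
}

#' @rdname rc_oscillating
#' @export
oscillating_rc <- rc_oscillating

#' Wrap angles into the interval (-pi, pi]
#'
#' Minimal-image convention for angular differences: a raw difference of about
#' `2 pi` across the branch cut maps to a near-zero net displacement.
#'
#' @param x numeric vector/matrix of angles or angle differences.
#' @return wrapped values in `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Jacobian consistency check by finite differences
#'
#' @param rc a `reaction_coordinate`.
#' @param points matrix of test points.
#' @param h finite-difference step.
#' @return max abs deviation between analytic and finite-difference Jacobian
#'   (angular outputs compared modulo 2*pi).
#' @export
jacobian_fd_error <- function(rc, points, h = 1e-6) {
  points <- .as_state_matrix(points, rc$dim)
  J <- rc$jacobian(points)
  worst <- 0
  for (i in seq_len(nrow(points))) {
    x <- points[i, ]
    for (k in seq_len(rc$dim)) {
      e <- numeric(rc$dim); e[k] <- h
      dv <- (rc$map(matrix(x + e, 1)) - rc$map(matrix(x - e, 1)))
      dv[, rc$periodic] <- wrap_angle(dv[, rc$periodic])
      fd <- dv / (2 * h)
      worst <- max(worst, max(abs(fd - J[i, k, ])))
    }
  }
  worst
}
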