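#' Construct an SDE model from a potential
#'
#' Builds the drift and diffusion of a Langevin model at inverse temperature
#' `beta` and friction `gamma`:
#' * `kind = "overdamped"`: `dX = -(1/gamma) grad V dt + sqrt(2/(beta gamma)) dB`,
#'   with diffusion covariance `a = 2/(beta gamma) I` (uniformly elliptic).
#' * `kind = "underdamped"`: state `(q, p)`, `dq = p dt`,
#'   `dp = (-grad V(q) - gamma p) dt + sqrt(2 gamma / beta) dB`; the diffusion
#'   covariance is zero on the position block and `2 gamma / beta I` on the
#'   momentum block, so the model is not uniformly elliptic and not reversible.
#' * `kind = "generic"`: user-supplied `drift` and constant covariance matrix
#'   `diffusion_cov`.
#'
#' The invariant density is the Boltzmann density `exp(-beta V)` for the
#' overdamped model and `exp(-beta (V(q) + |p|^2 / 2))` (factorized Gaussian
#' momenta) for the underdamped model.
#'
#' @param kind one of `"overdamped"`, `"underdamped"`, `"generic"`.
#' @param potential a [potential()] object.
#' @param beta inverse temperature (> 0).
#' @param gamma friction (> 0).
#' @param drift,diffusion_cov for `kind = "generic"`: drift function
#'   (matrix -> matrix) and constant d x d covariance matrix.
#' @return an object of class `sde_model` with elements `drift` (vectorized),
#'   `diffusion_cov(x)` (d x d matrix at one point), `a_info` (structure
#'   descriptor used by fast code paths), `uniformly_elliptic`,
#'   `invariant_log_density` and `dim` (full state dimension).
#' @export
make_model <- function(kind = c("overdamped", "underdamped", "generic"),
                       potential, beta, gamma = 1,
                       drift = NULL, diffusion_cov = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(potential, "potential"))
  if (!(is.numeric(beta) && beta > 0)) stop("beta must be > 0")
  if (!(is.numeric(gamma) && gamma > 0)) stop("gamma must be > 0")
  d <- potential$dim
  m <- list(kind = kind, potential = potential, beta = beta, gamma = gamma)
  if (kind == "overdamped") {
    scale <- 2 / (beta * gamma)
    m$dim <- d
    m$drift <- function(x) -potential$gradient(x) / gamma
    m$diffusion_cov <- function(x) diag(scale, d)
    m$a_info <- list(type = "iso", scale = scale, dim = d)
    m$uniformly_elliptic <- TRUE
    m$invariant_log_density <- function(x) -beta * potential$energy(x)
  } else if (kind == "underdamped") {
    scale <- 2 * gamma / beta
    m$dim <- 2L * d
    m$dim_position <- d
    m$drift <- function(x) {
      x <- .as_state_matrix(x, 2L * d)
      q <- x[, 1:d, drop = FALSE]
      p <- x[, (d + 1):(2 * d), drop = FALSE]
      cbind(p, -potential$gradient(q) - gamma * p)
    }
    m$diffusion_cov <- function(x) {
      a <- matrix(0, 2 * d, 2 * d)
      a[(d + 1):(2 * d), (d + 1):(2 * d)] <- diag(scale, d)
      a
    }
    m$a_info <- list(type = "ul", scale = scale, dim = 2L * d, d_pos = d)
    m$uniformly_elliptic <- FALSE
    m$invariant_log_density <- function(x) {
      x <- .as_state_matrix(x, 2L * d)
      q <- x[, 1:d, drop = FALSE]
      p <- x[, (d + 1):(2 * d), drop = FALSE]
      -beta * (potential$energy(q) + 0.5 * rowSums(p^2))
    }
  } else {
    if (is.null(drift) || is.null(diffusion_cov))
      stop("generic models need explicit drift and diffusion_cov")
    a <- as.matrix(diffusion_cov)
    if (!isTRUE(all.equal(a, t(a)))) stop("diffusion_cov must be symmetric")
    m$dim <- d
    m$drift <- drift
    m$diffusion_cov <- function(x) a
    m$a_info <- list(type = "const", a = a, dim = d)
    m$uniformly_elliptic <- min(eigen(a, symmetric = TRUE,
                                      only.values = TRUE)$values) > 0
    m$invariant_log_density <- NULL
  }
  class(m) <- "sde_model"
  m
}

#' @export
print.sde_model <- function(x, ...) {
  cat(sprintf("<sde_model> %s Langevin on '%s' (dim %d), beta = %g, gamma = %g\n",
              x$kind, x$potential$name, x$dim, x$beta, x$gamma))
  cat("  uniformly elliptic:", x$uniformly_elliptic, "\n")
  invisible(x)
}

# rows of a(x) %*% t(grad) contracted: returns n-vector of grad_f . a . grad_g
.a_quadratic <- function(model, gf, gg) {
  info <- model$a_info
  if (info$type == "iso") {
    info$scale * rowSums(gf * gg)
  } else if (info$type == "ul") {
    d <- info$d_pos
    info$scale * rowSums(gf[, (d + 1):(2 * d), drop = FALSE] *
                           gg[, (d + 1):(2 * d), drop = FALSE])
  } else {
    rowSums((gf %*% info$a) * gg)
  }
}

#' Apply the infinitesimal generator to an observable pointwise
#'
#' Evaluates `L f(x) = b(x) . grad f(x) + (1/2) a(x) : hess f(x)` at the given
#' points, where `a = sigma sigma^T` and `:` is the Frobenius product.
#'
#' @param model an `sde_model`.
#' @param f_grad function: n x d matrix of points -> n x d gradient matrix.
#' @param f_hess function: single state (numeric(d)) -> d x d Hessian, or NULL.
#'   Required whenever the diffusion is nonzero.
#' @param points n x d matrix of evaluation points.
#' @return numeric(n) of generator values.
#' @export
generator_apply <- function(model, f_grad, f_hess, points) {
  points <- .as_state_matrix(points, model$dim)
  if (is.null(f_hess)) stop("Hessian of f is required since the diffusion is nonzero")
  b <- model$drift(points)
  g <- f_grad(points)
  drift_term <- rowSums(b * g)
  info <- model$a_info
  trace_term <- vapply(seq_len(nrow(points)), function(m) {
    H <- f_hess(points[m, ])
    if (info$type == "iso") {
      0.5 * info$scale * sum(diag(H))
    } else if (info$type == "ul") {
      d <- info$d_pos
      0.5 * info$scale * sum(diag(H)[(d + 1):(2 * d)])
    } else {
      0.5 * sum(info$a * H)
    }
  }, numeric(1))
  drift_term + trace_term
}

#' Quadratic (Dirichlet) form of a reversible model
#'
#' Estimates `Q(f, g) = (1/2) E_mu[ grad f . a . grad g ]` from sample points
#' (Monte Carlo, equal weights) or from quadrature points with weights. For
#' reversible models this equals `< -L f, g >_mu`.
#'
#' @param model an `sde_model`; underdamped models are rejected because the
#'   form is degenerate (zero) on functions of the positions only.
#' @param f_grad,g_grad gradient functions (n x d matrix -> n x d matrix).
#' @param points n x d matrix of sample or quadrature points.
#' @param weights optional quadrature weights summing to 1; default equal.
#' @return scalar estimate of Q(f, g).
#' @export
quadratic_form <- function(model, f_grad, g_grad, points, weights = NULL) {
  if (model$kind == "underdamped")
    stop("quadratic form is degenerate for underdamped models ",
         "(diffusion vanishes on the position block)")
  points <- .as_state_matrix(points, model$dim)
  v <- .a_quadratic(model, f_grad(points), g_grad(points))
  if (is.null(weights)) 0.5 * mean(v) else 0.5 * sum(weights * v) / sum(weights)
}
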