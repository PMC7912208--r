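#' Galerkin systems from trajectory data (gEDMD)
#'
#' The assemblers build the stiffness matrix `S[i,j] ~ < -L phi_i, phi_j >_mu`
#' and mass (Gram) matrix `G[i,j] ~ < phi_i, phi_j >_mu` of the generator
#' restricted to a dictionary of functions of a reaction coordinate, from
#' samples of the full process. Three estimators are available:
#'
#' * [assemble_reversible()]: the quadratic-form estimator
#'   `S[i,j] = (1/2M) sum_m grad phi_i(x_m)^T a(x_m) grad phi_j(x_m)`,
#'   valid for reversible models with known diffusion `a`; symmetric by
#'   construction.
#' * [assemble_nonreversible()]: the direct estimator
#'   `S[i,j] = -(1/M) sum_m [ b . grad phi_i + (1/2) a : hess phi_i ] phi_j`,
#'   needing full model parameters `b`, `a` (and the reaction-coordinate
#'   Hessian for the chain rule); applicable to non-reversible processes.
#' * [assemble_km()]: the Kramers-Moyal estimator that replaces the unknown
#'   effective drift/diffusion by finite differences
#'   `ds xi(x_m) = xi(x_{m + s/dt}) - xi(x_m)` at a positive offset `s`.
#'
#' Gradients of basis functions of `z = xi(x)` are taken with respect to the
#' full state via the chain rule through the Jacobian of `xi`. Samples at
#' which the reaction coordinate or its derivatives are non-finite (e.g. the
#' polar angle at the origin) are skipped and counted, or abort, per
#' `on_singular`.
#'
#' With `n_blocks > 1` the sums are additionally kept as contiguous-block
#' partial sums, enabling the moving-block bootstrap of
#' [bootstrap_timescales()] and block-wise Monte-Carlo standard errors.
#'
#' @param traj a `trajectory` (or plain matrix of states).
#' @param rc a [reaction_coordinate()].
#' @param basis a `basis_set` on the reduced space.
#' @param model an `sde_model` supplying `b` and/or `a`.
#' @param offset_s positive time offset, an integer multiple of the
#'   trajectory's `dt`.
#' @param chunk_size samples per processing chunk (default sized to bound
#'   memory).
#' @param n_blocks number of contiguous blocks to retain for bootstrapping.
#' @param on_singular `"skip"` (drop and count) or `"abort"`.
#' @return a `galerkin_system`: list with `stiffness`, `mass`, `estimator`,
#'   `offset`, `n_samples`, `n_dropped`, `basis`, and (if `n_blocks > 1`)
#'   block partial sums in `blocks`.
#' @name gedmd_assembly
NULL

.default_chunk <- function(N, m) {
  max(1000L, as.integer(2.5e7 / (N * (1 + m + m * m))))
}

# A[a][[b]] entries of the reduced diffusion  (grad xi)^T a (grad xi)
.reduced_diffusion <- function(model, J, m) {
  info <- model$a_info
  A <- vector("list", m * m)
  for (a in seq_len(m)) for (b in seq_len(a)) {
    Ja <- J[, , a, drop = FALSE]; dim(Ja) <- dim(J)[1:2]
    Jb <- J[, , b, drop = FALSE]; dim(Jb) <- dim(J)[1:2]
    v <- if (info$type == "iso") {
      info$scale * rowSums(Ja * Jb)
    } else if (info$type == "ul") {
      dp <- info$d_pos
      info$scale * rowSums(Ja[, (dp + 1):(2 * dp), drop = FALSE] *
                             Jb[, (dp + 1):(2 * dp), drop = FALSE])
    } else {
      rowSums((Ja %*% info$a) * Jb)
    }
    A[[(a - 1) * m + b]] <- v
    A[[(b - 1) * m + a]] <- v
  }
  A
}

# generator applied to each component of xi: L xi_a = b . J_a + 1/2 a : H_a
.generator_of_rc <- function(model, rc, X, J) {
  m <- rc$m
  if (is.null(rc$hessian))
    stop("reaction coordinate provides no Hessian; ",
         "the non-reversible estimator needs it (use reversible or KM)")
  b <- model$drift(X)
  H <- rc$hessian(X)
  info <- model$a_info
  La <- matrix(0, nrow(X), m)
  for (a in seq_len(m)) {
    Ja <- J[, , a, drop = FALSE]; dim(Ja) <- dim(J)[1:2]
    La[, a] <- rowSums(b * Ja)
    if (info$type == "iso") {
      tr <- 0
      for (k in seq_len(info$dim)) tr <- tr + H[, k, k, a]
      La[, a] <- La[, a] + 0.5 * info$scale * tr
    } else if (info$type == "ul") {
      dp <- info$d_pos
      tr <- 0
      for (k in (dp + 1):(2 * dp)) tr <- tr + H[, k, k, a]
      La[, a] <- La[, a] + 0.5 * info$scale * tr
    } else {
      tr <- 0
      for (k in seq_len(info$dim)) for (l in seq_len(info$dim))
        if (info$a[k, l] != 0) tr <- tr + info$a[k, l] * H[, k, l, a]
      La[, a] <- La[, a] + 0.5 * tr
    }
  }
  La
}

.assemble <- function(traj, rc, basis, model = NULL,
                      estimator = c("reversible", "nonreversible", "km"),
                      offset_s = 0, chunk_size = NULL, n_blocks = 1L,
                      on_singular = c("skip", "abort")) {
  estimator <- match.arg(estimator)
  on_singular <- match.arg(on_singular)
  X <- unclass(traj)
  dt <- attr(traj, "dt")
  if (ncol(X) != rc$dim) stop("trajectory dimension does not match rc")
  n_off <- 0L
  if (estimator == "km") {
    if (is.null(dt)) stop("trajectory must carry a dt attribute for KM")
    r <- offset_s / dt
    if (abs(r - round(r)) > 1e-6) stop("offset_s must be a multiple of dt")
    n_off <- as.integer(round(r))
    if (n_off < 1) stop("offset_s must be >= dt")
    if (n_off >= nrow(X)) stop("offset_s exceeds trajectory length")
  }
  M <- nrow(X) - n_off
  N <- basis$n_functions
  m <- rc$m
  if (is.null(chunk_size)) chunk_size <- .default_chunk(N, m)
  n_blocks <- max(1L, as.integer(n_blocks))
  block_of <- if (n_blocks > 1) pmin(n_blocks, 1L + ((seq_len(M) - 1L) * n_blocks) %/% M)
  Sb <- array(0, c(N, N, n_blocks))
  Gb <- array(0, c(N, N, n_blocks))
  nb <- integer(n_blocks)
  dropped <- 0L
  need_hess <- estimator %in% c("nonreversible", "km")
  starts <- seq(1L, M, by = chunk_size)
  for (st in starts) {
    en <- min(st + chunk_size - 1L, M)
    idx <- st:en
    Xc <- X[idx, , drop = FALSE]
    Z <- rc$map(Xc)
    if (estimator == "km") {
      Z2 <- rc$map(X[idx + n_off, , drop = FALSE])
      ds <- Z2 - Z
      if (any(rc$periodic)) ds[, rc$periodic] <- wrap_angle(ds[, rc$periodic])
    }
    keep <- rowSums(!is.finite(Z)) == 0
    if (estimator != "km") {
      J <- rc$jacobian(Xc)
      keep <- keep & (rowSums(!is.finite(matrix(J, nrow(Xc)))) == 0)
    } else {
      keep <- keep & (rowSums(!is.finite(ds)) == 0)
    }
    if (!all(keep)) {
      if (on_singular == "abort")
        stop("non-finite reaction-coordinate value at sample ",
             idx[which(!keep)[1]])
      dropped <- dropped + sum(!keep)
      Xc <- Xc[keep, , drop = FALSE]
      Z <- Z[keep, , drop = FALSE]
      if (estimator == "km") ds <- ds[keep, , drop = FALSE]
      else J <- J[keep, , , drop = FALSE]
    }
    if (nrow(Xc) == 0) next
    eb <- evaluate_basis(basis, Z, hessian = need_hess)
    if (estimator == "reversible") {
      A <- .reduced_diffusion(model, J, m)
      Sc <- matrix(0, N, N)
      for (a in seq_len(m)) for (b in seq_len(m)) {
        Ga <- eb$grad[, , a, drop = FALSE]; dim(Ga) <- c(nrow(Z), N)
        Gb2 <- eb$grad[, , b, drop = FALSE]; dim(Gb2) <- c(nrow(Z), N)
        Sc <- Sc + crossprod(Ga * A[[(a - 1) * m + b]], Gb2)
      }
      Sc <- 0.5 * Sc
    } else {
      if (estimator == "nonreversible") {
        La <- .generator_of_rc(model, rc, Xc, J)
        A <- .reduced_diffusion(model, J, m)
      } else {
        La <- ds / offset_s
        A <- vector("list", m * m)
        for (a in seq_len(m)) for (b in seq_len(m))
          A[[(a - 1) * m + b]] <- ds[, a] * ds[, b] / offset_s
      }
      Lphi <- matrix(0, nrow(Z), N)
      for (a in seq_len(m)) {
        Ga <- eb$grad[, , a, drop = FALSE]; dim(Ga) <- c(nrow(Z), N)
        Lphi <- Lphi + La[, a] * Ga
      }
      for (a in seq_len(m)) for (b in seq_len(m)) {
        Ha <- eb$hess[, , a, b, drop = FALSE]; dim(Ha) <- c(nrow(Z), N)
        Lphi <- Lphi + 0.5 * A[[(a - 1) * m + b]] * Ha
      }
      Sc <- -crossprod(Lphi, eb$val)
    }
    Gc <- crossprod(eb$val)
    if (n_blocks == 1) {
      Sb[, , 1] <- Sb[, , 1] + Sc
      Gb[, , 1] <- Gb[, , 1] + Gc
      nb[1] <- nb[1] + nrow(Z)
    } else {
      # chunk may straddle block boundaries: split by block id
      bl <- block_of[idx][keep]
      for (b in unique(bl)) {
        sub <- bl == b
        if (all(sub)) {
          Sb[, , b] <- Sb[, , b] + Sc
          Gb[, , b] <- Gb[, , b] + Gc
          nb[b] <- nb[b] + nrow(Z)
        } else {
          # recompute partial sums for the straddling part (rare, cheap)
          Zs <- Z[sub, , drop = FALSE]
          eb2 <- evaluate_basis(basis, Zs, hessian = need_hess)
          if (estimator == "reversible") {
            Js <- J[sub, , , drop = FALSE]
            A2 <- .reduced_diffusion(model, Js, m)
            S2 <- matrix(0, N, N)
            for (a in seq_len(m)) for (b2 in seq_len(m)) {
              Ga <- eb2$grad[, , a, drop = FALSE]; dim(Ga) <- c(nrow(Zs), N)
              Gb3 <- eb2$grad[, , b2, drop = FALSE]; dim(Gb3) <- c(nrow(Zs), N)
              S2 <- S2 + crossprod(Ga * A2[[(a - 1) * m + b2]], Gb3)
            }
            S2 <- 0.5 * S2
          } else {
            Ls <- La[sub, , drop = FALSE]
            Lphi2 <- matrix(0, nrow(Zs), N)
            for (a in seq_len(m)) {
              Ga <- eb2$grad[, , a, drop = FALSE]; dim(Ga) <- c(nrow(Zs), N)
              Lphi2 <- Lphi2 + Ls[, a] * Ga
            }
            for (a in seq_len(m)) for (b2 in seq_len(m)) {
              Av <- A[[(a - 1) * m + b2]][sub]
              Ha <- eb2$hess[, , a, b2, drop = FALSE]; dim(Ha) <- c(nrow(Zs), N)
              Lphi2 <- Lphi2 + 0.5 * Av * Ha
            }
            S2 <- -crossprod(Lphi2, eb2$val)
          }
          Sb[, , b] <- Sb[, , b] + S2
          Gb[, , b] <- Gb[, , b] + crossprod(eb2$val)
          nb[b] <- nb[b] + nrow(Zs)
        }
      }
    }
  }
  n_used <- sum(nb)
  if (n_used == 0) stop("no usable samples after singularity filtering")
  S <- apply(Sb, c(1, 2), sum) / n_used
  G <- apply(Gb, c(1, 2), sum) / n_used
  if (estimator == "reversible") S <- (S + t(S)) / 2
  if (any(!is.finite(S)) || any(!is.finite(G)))
    stop("non-finite entries in assembled matrices")
  out <- list(stiffness = S, mass = G, estimator = estimator,
              offset = if (estimator == "km") offset_s else 0,
              n_samples = n_used, n_dropped = dropped, basis = basis,
              rc_name = rc$name, dt = dt)
  if (n_blocks > 1) out$blocks <- list(S = Sb, G = Gb, n = nb)
  class(out) <- "galerkin_system"
  out
}

#' @rdname gedmd_assembly
#' @export
assemble_reversible <- function(traj, rc, basis, model, chunk_size = NULL,
                                n_blocks = 1L, on_singular = "skip") {
  .assemble(traj, rc, basis, model, "reversible", chunk_size = chunk_size,
            n_blocks = n_blocks, on_singular = on_singular)
}

#' @rdname gedmd_assembly
#' @export
assemble_nonreversible <- function(traj, rc, basis, model, chunk_size = NULL,
                                   n_blocks = 1L, on_singular = "skip") {
  .assemble(traj, rc, basis, model, "nonreversible", chunk_size = chunk_size,
            n_blocks = n_blocks, on_singular = on_singular)
}

#' @rdname gedmd_assembly
#' @export
assemble_km <- function(traj, rc, basis, offset_s, chunk_size = NULL,
                        n_blocks = 1L, on_singular = "skip") {
  .assemble(traj, rc, basis, NULL, "km", offset_s = offset_s,
            chunk_size = chunk_size, n_blocks = n_blocks,
            on_singular = on_singular)
}

#' @export
print.galerkin_system <- function(x, ...) {
  cat(sprintf("<galerkin_system> %s estimator, N = %d, offset = %g, M = %g",
              x$estimator, nrow(x$stiffness), x$offset, x$n_samples))
  if (x$n_dropped > 0) cat(sprintf(" (%d samples skipped)", x$n_dropped))
  cat("\n")
  invisible(x)
}

# core generalized symmetric/nonsymmetric eigensolve with mass whitening
.solve_gev <- function(S, G, estimator, n_eigs = NULL, mass_tol = 1e-10,
                       imag_tol = 0.1) {
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- eg$values > mass_tol * max(eg$values)
  rank <- sum(keep)
  if (is.null(n_eigs)) n_eigs <- min(rank, nrow(S))
  if (n_eigs > rank)
    stop(sprintf("mass matrix rank (%d at tolerance %g) below n_eigs = %d",
                 rank, mass_tol, n_eigs))
  B <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), rank)
  discarded_imag <- 0
  if (estimator %in% c("reversible", "quadrature")) {
    R <- t(B) %*% ((S + t(S)) / 2) %*% B
    ee <- eigen((R + t(R)) / 2, symmetric = TRUE)
    ord <- order(ee$values)
    vals <- ee$values[ord]
    vecs <- ee$vectors[, ord, drop = FALSE]
  } else {
    # rows of S index the differentiated function: the weak form uses S^T
    R <- t(B) %*% t(S) %*% B
    ee <- eigen(R)
    ord <- order(Re(ee$values))
    vals_c <- ee$values[ord]
    vecs_c <- ee$vectors[, ord, drop = FALSE]
    sel <- seq_len(n_eigs)
    discarded_imag <- max(abs(Im(vals_c[sel])))
    rel <- abs(Im(vals_c[sel])) / pmax(abs(Re(vals_c[sel])), 1e-12)
    # the stationary eigenvalue is ~0; judge only genuinely nonzero ones
    nonzero <- abs(Re(vals_c[sel])) > 1e-8 * max(abs(Re(vals_c)))
    if (any(rel[nonzero] > imag_tol))
      stop(sprintf(paste0("dominant eigenvalue has imaginary part beyond ",
                          "imag_tol (max |Im|/|Re| = %.3g)"),
                   max(rel[nonzero])))
    vals <- Re(vals_c)
    vecs <- Re(vecs_c)
  }
  vals <- vals[seq_len(n_eigs)]
  vecs <- vecs[, seq_len(n_eigs), drop = FALSE]
  coef <- B %*% vecs
  # normalize to unit mass norm
  nrm <- sqrt(pmax(colSums(coef * (G %*% coef)), 1e-300))
  coef <- sweep(coef, 2, nrm, "/")
  list(values = vals, coefficients = coef, mass_rank = rank,
       discarded_imag = discarded_imag)
}

#' Solve the generalized eigenproblem of a Galerkin system
#'
#' Whitens by the mass matrix (symmetric eigendecomposition, truncating
#' directions whose mass eigenvalue is below `mass_tol` times the largest),
#' solves the reduced eigenproblem (symmetric-definite for the reversible
#' estimator; general otherwise, sorted by real part with the largest
#' imaginary part recorded), and back-transforms the eigenvector coefficients.
#'
#' @param a a `galerkin_system`.
#' @param b unused (generic signature).
#' @param n_eigs number of eigenpairs to retain (default: mass rank).
#' @param mass_tol relative mass-eigenvalue truncation threshold.
#' @param imag_tol maximal tolerated `|Im|/|Re|` of retained nonzero
#'   eigenvalues for the non-symmetric estimators; larger values abort.
#' @param ... unused.
#' @return a `spectral_model`: eigenvalues (ascending rates, real parts),
#'   coefficient vectors in the basis (mass-normalized), implied timescales
#'   (stationary eigenvalue excluded), `discarded_imag`, and provenance.
#' @export
solve.galerkin_system <- function(a, b, n_eigs = NULL, mass_tol = 1e-10,
                                  imag_tol = 0.1, ...) {
  sol <- .solve_gev(a$stiffness, a$mass, a$estimator, n_eigs, mass_tol,
                    imag_tol)
  spectral_model(sol$values, sol$coefficients, basis = a$basis,
                 estimator = a$estimator, offset = a$offset,
                 discarded_imag = sol$discarded_imag,
                 mass_rank = sol$mass_rank)
}

#' Spectral model of a projected generator
#'
#' @param eigenvalues rates (ascending; the pair with smallest `|omega|` is
#'   treated as the stationary one).
#' @param coefficients N x K matrix of eigenfunction coefficients.
#' @param basis the `basis_set` the coefficients refer to.
#' @param estimator,offset,discarded_imag,mass_rank provenance.
#' @return object of class `spectral_model`.
#' @export
spectral_model <- function(eigenvalues, coefficients, basis,
                           estimator = "unknown", offset = 0,
                           discarded_imag = 0, mass_rank = NA_integer_) {
  stopifnot(!is.unsorted(eigenvalues))
  structure(list(eigenvalues = eigenvalues, coefficients = coefficients,
                 basis = basis, estimator = estimator, offset = offset,
                 discarded_imag = discarded_imag, mass_rank = mass_rank),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("<spectral_model> %s estimator (offset %g): %d eigenvalues\n",
              x$estimator, x$offset, length(x$eigenvalues)))
  cat("  rates:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  ts <- implied_timescales(x)
  if (length(ts)) cat("  timescales:", paste(signif(ts, 4), collapse = ", "), "\n")
  invisible(x)
}

# index of the stationary eigenpair (smallest |omega|)
.stationary_index <- function(spectral) which.min(abs(spectral$eigenvalues))

#' Nontrivial rates of a spectral model
#'
#' Eigenvalues with the stationary pair (smallest `|omega|`) removed,
#' ascending.
#'
#' @param spectral a `spectral_model`.
#' @return numeric vector of rates.
#' @export
nontrivial_rates <- function(spectral) {
  spectral$eigenvalues[-.stationary_index(spectral)]
}

#' Implied timescales
#'
#' Reciprocals `t_i = 1 / omega_i` of the nontrivial rates. Nonpositive rates
#' past the stationary one are spurious (sampling artifacts); they yield `NA`
#' timescales and are flagged in the `"spurious"` attribute.
#'
#' @param spectral a `spectral_model`.
#' @param n number of timescales (default all available).
#' @return numeric vector of timescales, attribute `spurious` holding indices
#'   of nonpositive rates.
#' @export
implied_timescales <- function(spectral, n = NULL) {
  om <- nontrivial_rates(spectral)
  if (!is.null(n)) om <- om[seq_len(min(n, length(om)))]
  ts <- ifelse(om > 0, 1 / om, NA_real_)
  spurious <- which(om <= 0)
  if (length(spurious))
    warning("nonpositive eigenvalue(s) past the stationary one: spurious")
  attr(ts, "spurious") <- spurious
  ts
}

#' Evaluate estimated eigenfunctions on reduced-space points
#'
#' @param spectral a `spectral_model`.
#' @param z evaluation points (vector or n x m matrix).
#' @param which column indices of eigenfunctions (default all).
#' @return n x length(which) matrix of eigenfunction values.
#' @export
evaluate_eigenfunctions <- function(spectral, z, which = NULL) {
  if (is.null(which)) which <- seq_len(ncol(spectral$coefficients))
  v <- evaluate_basis(spectral$basis, z)$val
  v %*% spectral$coefficients[, which, drop = FALSE]
}

#' Offset scan of the Kramers-Moyal gEDMD spectrum
#'
#' Re-assembles and solves the KM-gEDMD problem for a series of offsets `s`
#' and tracks, per nontrivial eigenvalue, the relative error
#' `E_i(s) = |omega_i(s) - omega_i(0)| / omega_i(s)` against a reference
#' spectral model (typically from an exact-parameter estimator). Assembly or
#' solve failures at an offset are recorded as `NA` rows without aborting the
#' scan.
#'
#' @param traj,rc,basis as in [assemble_km()].
#' @param offsets numeric vector of offsets (multiples of `dt`).
#' @param reference a `spectral_model` providing the reference rates.
#' @param n_eigs eigenpairs per offset (default: as in the reference).
#' @param mass_tol,imag_tol passed to the solver.
#' @return data.frame with columns `offset`, `i`, `rate`, `timescale`,
#'   `rel_error`, `error_message`.
#' @export
offset_scan <- function(traj, rc, basis, offsets, reference, n_eigs = NULL,
                        mass_tol = 1e-10, imag_tol = 0.1) {
  if (is.null(n_eigs)) n_eigs <- length(reference$eigenvalues)
  ref_rates <- nontrivial_rates(reference)
  ni <- min(n_eigs - 1, length(ref_rates))
  rows <- list()
  for (s in offsets) {
    rates <- rep(NA_real_, ni)
    msg <- NA_character_
    res <- tryCatch({
      sys <- assemble_km(traj, rc, basis, offset_s = s)
      solve(sys, n_eigs = n_eigs, mass_tol = mass_tol, imag_tol = imag_tol)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
    } else {
      rates <- nontrivial_rates(res)[seq_len(ni)]
    }
    rows[[length(rows) + 1]] <- data.frame(
      offset = s, i = seq_len(ni), rate = rates,
      timescale = ifelse(rates > 0, 1 / rates, NA_real_),
      rel_error = abs(rates - ref_rates[seq_len(ni)]) / abs(rates),
      error_message = msg, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Moving-block bootstrap of implied timescales
#'
#' Resamples the contiguous-block partial sums stored by an assembler called
#' with `n_blocks > 1`, re-solves the eigenproblem per resample, and returns
#' the bootstrap distribution of the implied timescales.
#'
#' @param system a `galerkin_system` assembled with `n_blocks > 1`.
#' @param n_resamples number of bootstrap resamples.
#' @param n_eigs,mass_tol,imag_tol passed to the solver.
#' @param seed RNG seed for the resampling.
#' @return matrix (n_resamples x timescales) with attribute `se` (bootstrap
#'   standard errors).
#' @export
bootstrap_timescales <- function(system, n_resamples = 100, n_eigs = NULL,
                                 mass_tol = 1e-10, imag_tol = 0.1, seed = 1L) {
  if (is.null(system$blocks))
    stop("system was assembled without blocks (use n_blocks > 1)")
  bl <- system$blocks
  B <- length(bl$n)
  set.seed(seed)
  out <- NULL
  for (r in seq_len(n_resamples)) {
    pick <- sample.int(B, B, replace = TRUE)
    n_tot <- sum(bl$n[pick])
    S <- apply(bl$S[, , pick, drop = FALSE], c(1, 2), sum) / n_tot
    G <- apply(bl$G[, , pick, drop = FALSE], c(1, 2), sum) / n_tot
    ts <- tryCatch({
      sol <- .solve_gev(S, G, system$estimator, n_eigs, mass_tol, imag_tol)
      sm <- spectral_model(sol$values, sol$coefficients, system$basis,
                           system$estimator, system$offset)
      suppressWarnings(implied_timescales(sm))
    }, error = function(e) NULL)
    if (is.null(ts)) next
    if (is.null(out)) out <- matrix(NA_real_, n_resamples, length(ts))
    out[r, seq_along(ts)] <- ts
  }
  if (is.null(out)) stop("all bootstrap resamples failed")
  attr(out, "se") <- apply(out, 2, stats::sd, na.rm = TRUE)
  out
}
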