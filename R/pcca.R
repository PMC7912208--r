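#' PCCA metastable membership functions
#'
#' Converts the `K` dominant generator eigenfunctions (evaluated on a set of
#' points, typically a regular grid over the reduced domain) into `K` fuzzy
#' membership functions that sum to one at every point. The construction is
#' the inner-simplex (vertex-seeking) PCCA scheme: the rows of the
#' eigenfunction matrix, whose first column is the (near-)constant stationary
#' eigenfunction, span a simplex in K-dimensional space whose vertices
#' correspond to the metastable states; memberships are the barycentric
#' coordinates with respect to those vertices. No subsequent optimization
#' pass is applied, which keeps the result deterministic.
#'
#' Small negative memberships caused by sampling noise are clipped to
#' `[0, 1]` and rows renormalized; the largest pre-clip violation is reported
#' in the result.
#'
#' @param eigfun_values n x K matrix of dominant eigenfunction values; the
#'   first column must be the (near-)constant stationary eigenfunction.
#' @param K number of metastable states (`K >= 1`, at most `ncol`).
#' @param transition_threshold points whose largest membership is below this
#'   are marked as transition states (default 0.6).
#' @return object of class `pcca_result`: `memberships` (n x K,
#'   row-stochastic in `[0,1]`), `crisp_labels` (argmax), `transition_mask`,
#'   `K`, `violation` (largest pre-clip constraint violation), `vertices`
#'   (row indices of the simplex vertices).
#' @export
pcca <- function(eigfun_values, K, transition_threshold = 0.6) {
  X <- as.matrix(eigfun_values)
  if (K < 1) stop("K must be >= 1")
  if (K > ncol(X)) stop("K exceeds the number of available eigenfunctions")
  X <- X[, seq_len(K), drop = FALSE]
  n <- nrow(X)
  if (K == 1) {
    return(structure(list(memberships = matrix(1, n, 1),
                          crisp_labels = rep(1L, n),
                          transition_mask = rep(FALSE, n), K = 1L,
                          violation = 0, vertices = which.max(abs(X[, 1]))[1]),
                     class = "pcca_result"))
  }
  if (stats::sd(X[, 1]) > 0.1 * max(abs(X[, 1])))
    warning("first eigenfunction is far from constant; PCCA assumes the ",
            "stationary eigenfunction comes first")
  X[, 1] <- 1 # exact constant in the affine coordinates
  # inner-simplex vertex search (pivoted orthogonalization of centered rows)
  idx <- integer(K)
  idx[1] <- which.max(rowSums(X^2))
  Y <- sweep(X, 2, X[idx[1], ])
  for (k in 2:K) {
    nr <- sqrt(rowSums(Y^2))
    idx[k] <- which.max(nr)
    if (nr[idx[k]] < 1e-12)
      stop(sprintf(paste0("degenerate simplex: eigenfunction set has ",
                          "collinear vertices at state %d"), k))
    v <- Y[idx[k], ] / nr[idx[k]]
    Y <- Y - outer(as.numeric(Y %*% v), v)
  }
  V <- X[idx, , drop = FALSE]
  chi <- X %*% solve(V)
  violation <- max(0, max(-chi), max(chi - 1))
  chi[chi < 0] <- 0
  chi[chi > 1] <- 1
  chi <- chi / rowSums(chi)
  structure(list(memberships = chi,
                 crisp_labels = max.col(chi, ties.method = "first"),
                 transition_mask = apply(chi, 1, max) < transition_threshold,
                 K = as.integer(K), violation = violation, vertices = idx),
            class = "pcca_result")
}

#' @export
print.pcca_result <- function(x, ...) {
  cat(sprintf("<pcca_result> K = %d states over %d points; %d transition points",
              x$K, nrow(x$memberships), sum(x$transition_mask)))
  cat(sprintf("; max pre-clip violation %.3g\n", x$violation))
  tab <- table(factor(x$crisp_labels, levels = seq_len(x$K)))
  cat("  crisp state sizes:", paste(as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}
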