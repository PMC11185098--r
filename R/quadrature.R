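#' Gauss-Hermite quadrature rule for standard-normal expectations
#'
#' Computes nodes and weights such that `sum(w * f(x))` approximates
#' `E[f(Z)]` for `Z ~ N(0, 1)`. Nodes are obtained by the Golub-Welsch
#' algorithm (eigendecomposition of the Jacobi matrix of the physicists'
#' Hermite polynomials) and rescaled to the probabilists' convention.
#'
#' @param n number of nodes (>= 1).
#' @return list with `nodes` and `weights`; weights sum to 1.
#' @examples
#' gh <- gauss_hermite_normal(15)
#' sum(gh$weights * gh$nodes^2)  # ~ Var(Z) = 1
#' @export
gauss_hermite_normal <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1L)] <- off
  Jm[cbind(i + 1L, i)] <- off
  ev <- eigen(Jm, symmetric = TRUE)
  ord <- order(ev$values)
  nodes <- ev$values[ord] * sqrt(2)         # physicists' -> N(0,1) scale
  weights <- ev$vectors[1L, ord]^2          # already sum to 1
  weights <- weights / sum(weights)
  list(nodes = nodes, weights = weights)
}

#' Quadrature grid over the latent space
#'
#' Builds the standard-normal Gauss-Hermite grid used by [marginal_loglik()]
#' and [fit_dlc()]: one dimension for ability theta, and a second for the
#' engagement threshold psi in the two-level family. Nodes are on the
#' *standard* scale; the model's (theta, psi) covariance is applied later
#' through its Cholesky factor.
#'
#' @param n_nodes nodes per dimension (>= 5).
#' @param dim 1 (theta only) or 2 (theta and psi).
#' @return object of class `dlc_grid` with elements `u1`, `w1` and, when
#'   `dim == 2`, `u2`, `w2`.
#' @export
quad_grid <- function(n_nodes = 15, dim = 1) {
  stopifnot(n_nodes >= 5, dim %in% c(1, 2))
  gh <- gauss_hermite_normal(n_nodes)
  g <- list(n_nodes = as.integer(n_nodes), dim = as.integer(dim),
            u1 = gh$nodes, w1 = gh$weights)
  if (dim == 2) { g$u2 <- gh$nodes; g$w2 <- gh$weights }
  class(g) <- "dlc_grid"
  g
}

# Cholesky factor of the 2x2 covariance of (theta, psi); tolerates the
# boundary sigma2_psi = 0 (degenerate psi) which chol() would reject.
latent_chol <- function(var_theta, sigma2_psi, cov_psi_theta) {
  if (var_theta <= 0) stop("var_theta must be > 0", call. = FALSE)
  L11 <- sqrt(var_theta)
  L21 <- cov_psi_theta / L11
  d <- sigma2_psi - L21^2
  if (d < -1e-8 * max(1, sigma2_psi)) {
    stop("implied (theta, psi) covariance is not positive semidefinite",
         call. = FALSE)
  }
  L22 <- sqrt(max(d, 0))
  matrix(c(L11, L21, 0, L22), 2, 2)
}
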