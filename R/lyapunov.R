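#' Forward solve of the stationary Lyapunov equation
#'
#' Solves `J C + C t(J) = -2 F` for the stationary covariance C of a linear
#' (Ornstein-Uhlenbeck) fluctuation system with Hurwitz-stable Jacobian J
#' and fluctuation (diffusion) matrix F. The solver diagonalizes J (complex
#' eigen-decomposition), solves the transformed equation entrywise, and
#' transforms back; cost O(n^3), no vectorized n^2 x n^2 system is formed.
#'
#' @param jac square numeric matrix; all eigenvalues must have negative
#'   real part.
#' @param flu symmetric positive-semidefinite matrix of the same size.
#' @return a [CovarianceMatrix-class] (with `nSamples` set to the formal
#'   minimum 2, since it is analytic, not estimated); residual Frobenius
#'   norm is checked against `1e-10 * (1 + ||C||)`.
#' @export
solveLyapunov <- function(jac, flu) {
  jac <- as.matrix(jac); flu <- as.matrix(flu)
  n <- nrow(jac)
  stopifnot(ncol(jac) == n)
  if (!identical(dim(flu), dim(jac)))
    stop("jac and flu dimensions differ")
  if (max(abs(flu - t(flu))) > 1e-8 * (1 + max(abs(flu))))
    stop("fluctuation matrix must be symmetric")
  eg <- eigen(jac)
  if (max(Re(eg$values)) >= 0)
    stop("non-stable Jacobian: max eigenvalue real part = ",
         signif(max(Re(eg$values)), 4))
  V <- eg$vectors
  Vinv <- solve(V)
  D <- outer(eg$values, eg$values, `+`)        # d_i + d_j, all nonzero (stable)
  solveRHS <- function(Q) {                    # solves J X + X J' = Q
    W <- (Vinv %*% Q %*% t(Vinv)) / D
    X <- Re(V %*% W %*% t(V))
    (X + t(X)) / 2
  }
  fro <- function(m) sqrt(sum(m^2))
  C <- solveRHS(-2 * flu)
  # a couple of iterative-refinement sweeps absorb eigenbasis conditioning
  for (it in 1:3) {
    resid <- jac %*% C + C %*% t(jac) + 2 * flu
    if (fro(resid) <= 1e-11 * (1 + fro(C))) break
    C <- C - solveRHS(resid)
  }
  resid <- jac %*% C + C %*% t(jac) + 2 * flu
  if (fro(resid) > 1e-10 * (1 + fro(C)))
    stop("Lyapunov solve did not converge: residual ", signif(fro(resid), 4),
         " (ill-conditioned eigenbasis?)")
  if (is.null(rownames(jac))) dimnames(C) <- list(paste0("M", 1:n), paste0("M", 1:n))
  else dimnames(C) <- dimnames(jac)
  new("CovarianceMatrix", values = C, nSamples = 2L)
}

#' Eigenvalue stability diagnostics for a Jacobian
#'
#' The stationary-fluctuation premise requires the reconstructed Jacobian
#' to be Hurwitz-stable (all eigenvalue real parts negative); this reports
#' the spectrum and the flag.
#'
#' @param j square numeric matrix.
#' @return list with `eigenvalues` (complex vector) and `stable` (logical).
#' @export
stabilityReport <- function(j) {
  j <- as.matrix(j)
  stopifnot(nrow(j) == ncol(j))
  ev <- eigen(j, only.values = TRUE)$values
  list(eigenvalues = ev, stable = all(Re(ev) < 0))
}
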