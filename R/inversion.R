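#' Fluctuation model constructor
#'
#' @param baseIntensity positive numeric vector (recycled to the metabolite
#'   count at draw time): base diagonal of the fluctuation matrix.
#' @param spread non-negative log-scale dispersion of Monte-Carlo draws
#'   (`0` = deterministic fluctuation).
#' @param seed integer seed addressing the draw streams.
#' @return a [FluctuationModel-class].
#' @export
FluctuationModel <- function(baseIntensity, spread = 0.2, seed = 1L) {
  new("FluctuationModel", baseIntensity = as.numeric(baseIntensity),
      spread = as.numeric(spread), seed = as.integer(seed))
}

#' Data-driven default fluctuation model
#'
#' In the absence of knowledge about the fluctuation magnitude, the base
#' diagonal is taken proportional to the observed metabolite variances
#' (default 10 percent), which makes the reconstruction scale-consistent
#' with the data.
#'
#' @param covm a [CovarianceMatrix-class].
#' @param rel proportionality constant applied to `diag(cov)`.
#' @param spread,seed passed to [FluctuationModel()].
#' @return a [FluctuationModel-class].
#' @export
defaultFluctuation <- function(covm, rel = 0.1, spread = 0.2, seed = 1L) {
  d <- rel * diag(as.matrix(covm))
  d[d <= 0] <- max(d[d > 0], 1) * 1e-6
  FluctuationModel(d, spread = spread, seed = seed)
}

#' Draw one fluctuation matrix
#'
#' Entry i of the diagonal is `base_i * exp(spread * z_i)` with independent
#' standard normal `z_i`; the stream is fully determined by the model seed
#' and the draw index, so draws are reproducible and parallel-addressable.
#' `spread = 0` returns exactly `diag(baseIntensity)`.
#'
#' @param model a [FluctuationModel-class].
#' @param nMetabolites matrix size.
#' @param drawIndex positive integer identifying the draw.
#' @return diagonal positive-definite matrix.
#' @export
sampleFluctuation <- function(model, nMetabolites, drawIndex = 1L) {
  base <- rep_len(model@baseIntensity, nMetabolites)
  if (model@spread == 0) return(diag(base, nMetabolites))
  z <- .withSeed(.substreamSeed(model@seed, drawIndex),
                 stats::rnorm(nMetabolites))
  diag(base * exp(model@spread * z), nMetabolites)
}

# Linear system in the free parameters: each column of X is the
# upper-triangle vectorization of (A_p C + C t(A_p)), where A_p is the
# Jacobian derivative with respect to free parameter p. In elasticity mode
# p indexes allowed entries (k, j) of E (J = N E, A_p = N[, k] e_j');
# in direct mode p indexes allowed Jacobian entries directly.
.buildDesign <- function(C, net, mode = c("elasticity", "direct")) {
  mode <- match.arg(mode)
  S <- net@stoichiometry
  n <- nrow(S)
  ut <- .upperTriIdx(n)
  if (mode == "elasticity") {
    idx <- which(net@elasticityPattern, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("elasticity pattern is empty")
    X <- matrix(0, length(ut), nrow(idx))
    for (p in seq_len(nrow(idx))) {
      k <- idx[p, 1]; j <- idx[p, 2]
      AC <- tcrossprod(S[, k], C[j, ])        # outer(S[,k], C[j,])
      M <- AC + t(AC)
      X[, p] <- M[ut]
    }
    pidx <- data.frame(reaction = rownames(net@elasticityPattern)[idx[, 1]],
                       metabolite = colnames(net@elasticityPattern)[idx[, 2]],
                       k = idx[, 1], j = idx[, 2], stringsAsFactors = FALSE)
  } else {
    mask <- suppressWarnings(jacobianSparsity(net))
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0L) stop("Jacobian sparsity mask is empty")
    X <- matrix(0, length(ut), nrow(idx))
    for (p in seq_len(nrow(idx))) {
      i <- idx[p, 1]; j <- idx[p, 2]
      M <- matrix(0, n, n)
      M[i, ] <- M[i, ] + C[j, ]
      M[, i] <- M[, i] + C[j, ]
      X[, p] <- M[ut]
    }
    pidx <- data.frame(reaction = NA_character_,
                       metabolite = colnames(mask)[idx[, 2]],
                       k = idx[, 1], j = idx[, 2], stringsAsFactors = FALSE)
  }
  list(X = X, paramIndex = pidx, ut = ut, n = n, mode = mode)
}

# Factor the least-squares problem once; returns solve(b) closure.
# ridge > 0: Cholesky of the ridge-regularized normal equations.
# ridge = 0: SVD minimum-norm solution; warns if rank-deficient.
.factorDesign <- function(X, ridge, warnUnderdetermined = TRUE) {
  P <- ncol(X)
  if (ridge > 0) {
    Rc <- chol(crossprod(X) + diag(ridge, P))
    function(b) backsolve(Rc, forwardsolve(t(Rc), crossprod(X, b)))
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
    rank <- sum(sv$d > tol)
    if (rank < P && warnUnderdetermined)
      warning("under-determined inverse problem (rank ", rank, " < ", P,
              " unknowns); returning the minimum-norm solution")
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    function(b) sv$v %*% (dinv * crossprod(sv$u, b))
  }
}

.assembleJacobian <- function(e, design, net) {
  n <- design$n
  if (design$mode == "elasticity") {
    E <- matrix(0, nrow(net@elasticityPattern), ncol(net@elasticityPattern))
    E[cbind(design$paramIndex$k, design$paramIndex$j)] <- e
    J <- net@stoichiometry %*% E
  } else {
    J <- matrix(0, n, n)
    J[cbind(design$paramIndex$k, design$paramIndex$j)] <- e
  }
  dimnames(J) <- list(net@metabolites$id, net@metabolites$id)
  J
}

#' Single Jacobian reconstruction from a covariance and one fluctuation
#'
#' Solves the stationary Lyapunov equation `J C + C t(J) = -2 F` for the
#' Jacobian, restricted to the network parameterization `J = N E` with the
#' elasticity matrix E free only on the network's sparsity pattern
#' (`mode = "elasticity"`, the default), or with the Jacobian entries free
#' on the structural mask (`mode = "direct"`). Only the n(n+1)/2 upper
#' triangle equations of the symmetric residual are used, and the system is
#' solved by ridge-regularized least squares (minimum-norm when
#' `ridge = 0`).
#'
#' @param covm [CovarianceMatrix-class] or plain symmetric matrix.
#' @param flu fluctuation matrix (symmetric PSD) of matching size.
#' @param net a [MetabolicNetwork-class] whose metabolite order matches
#'   the covariance.
#' @param ridge non-negative ridge penalty (default `1e-8`, for numerical
#'   conditioning of near-collinear designs).
#' @param mode `"elasticity"` or `"direct"`.
#' @return Jacobian matrix with exact zeros off the structural mask and
#'   attributes `elasticities` (free-parameter solution) and
#'   `parameterIndex`.
#' @export
invertOnce <- function(covm, flu, net, ridge = 1e-8,
                       mode = c("elasticity", "direct")) {
  C <- if (is(covm, "CovarianceMatrix")) covm@values else as.matrix(covm)
  flu <- as.matrix(flu)
  n <- nrow(net@stoichiometry)
  if (!identical(dim(C), c(n, n)) || !identical(dim(flu), c(n, n)))
    stop("dimension mismatch between covariance/fluctuation and network")
  if (!is.null(rownames(C)) && !identical(rownames(C), net@metabolites$id))
    stop("covariance metabolite order does not match the network")
  design <- .buildDesign(C, net, mode)
  solveFn <- .factorDesign(design$X, ridge)
  b <- (-2 * flu)[design$ut]
  e <- as.numeric(solveFn(b))
  J <- .assembleJacobian(e, design, net)
  attr(J, "elasticities") <- stats::setNames(
    e, paste(design$paramIndex$reaction, design$paramIndex$metabolite, sep = ":"))
  attr(J, "parameterIndex") <- design$paramIndex
  J
}

#' Bundle the inputs of the Monte-Carlo inversion
#'
#' @param covm [CovarianceMatrix-class].
#' @param network [MetabolicNetwork-class] in the same metabolite order.
#' @param fluctuation a [FluctuationModel-class]; default
#'   [defaultFluctuation()] of the covariance.
#' @param nDraws number of Monte-Carlo fluctuation draws (default 1000).
#' @param ridge ridge penalty for each solve.
#' @param mode `"elasticity"` or `"direct"` (see [invertOnce()]).
#' @param bootstrapProfiles optional [MetaboliteProfiles-class]; when given,
#'   each draw also recomputes the covariance from a bootstrap resample of
#'   its replicates (slower: the design is refactored per draw).
#' @return an `InverseProblem` list consumed by [ensembleInvert()].
#' @export
inverseProblem <- function(covm, network, fluctuation = NULL, nDraws = 1000L,
                           ridge = 1e-8, mode = c("elasticity", "direct"),
                           bootstrapProfiles = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(covm, "CovarianceMatrix"), is(network, "MetabolicNetwork"),
            nDraws >= 1L, ridge >= 0)
  if (!identical(metaboliteIds(covm), metaboliteIds(network)))
    stop("covariance metabolite order must equal network metabolite order")
  if (is.null(fluctuation)) fluctuation <- defaultFluctuation(covm)
  structure(list(cov = covm, network = network, fluctuation = fluctuation,
                 nDraws = as.integer(nDraws), ridge = ridge, mode = mode,
                 bootstrapProfiles = bootstrapProfiles),
            class = "InverseProblem")
}

#' Monte-Carlo ensemble inversion
#'
#' Runs [invertOnce()] once per fluctuation draw and summarizes the stack
#' of Jacobians by entrywise median and interquartile range — the ensemble
#' summary subsequently compared between conditions. With a fixed seed the
#' result is bit-reproducible. Draws whose linear solve fails are skipped;
#' at least 90 percent of draws must succeed.
#'
#' @param problem an [inverseProblem()] bundle.
#' @param conditionLabel label stored on the resulting ensemble.
#' @return a [JacobianEnsemble-class].
#' @export
ensembleInvert <- function(problem, conditionLabel = "") {
  stopifnot(inherits(problem, "InverseProblem"))
  net <- problem$network
  n <- nrow(net@stoichiometry)
  C <- problem$cov@values
  design <- .buildDesign(C, net, problem$mode)
  P <- ncol(design$X)
  boot <- !is.null(problem$bootstrapProfiles)
  solveFn <- if (!boot) .factorDesign(design$X, problem$ridge) else NULL
  k <- problem$nDraws
  draws <- array(0, dim = c(n, n, k),
                 dimnames = list(net@metabolites$id, net@metabolites$id, NULL))
  edraws <- matrix(NA_real_, P, k)
  ok <- logical(k)
  for (d in seq_len(k)) {
    flu <- sampleFluctuation(problem$fluctuation, n, d)
    des <- design
    sfn <- solveFn
    if (boot) {
      Xb <- profileValues(problem$bootstrapProfiles)
      ridx <- .withSeed(.substreamSeed(problem$fluctuation@seed, 500000L + d),
                        sample.int(nrow(Xb), replace = TRUE))
      Cb <- stats::cov(Xb[ridx, , drop = FALSE])
      des <- .buildDesign((Cb + t(Cb)) / 2, net, problem$mode)
      sfn <- tryCatch(.factorDesign(des$X, problem$ridge, warnUnderdetermined = FALSE),
                      error = function(e) NULL)
      if (is.null(sfn)) next
    }
    b <- (-2 * flu)[des$ut]
    e <- tryCatch(as.numeric(sfn(b)), error = function(err) NULL)
    if (is.null(e) || any(!is.finite(e))) next
    edraws[, d] <- e
    draws[, , d] <- .assembleJacobian(e, des, net)
    ok[d] <- TRUE
  }
  if (mean(ok) < 0.9)
    stop(sprintf("only %d/%d inversion draws succeeded (< 90%%)", sum(ok), k))
  if (!all(ok)) {
    draws <- draws[, , ok, drop = FALSE]
    edraws <- edraws[, ok, drop = FALSE]
    message(sum(!ok), " failed draw(s) skipped")
  }
  med <- apply(draws, c(1, 2), stats::median)
  q <- apply(draws, c(1, 2), stats::quantile, probs = c(0.25, 0.75))
  iqr <- q[2, , ] - q[1, , ]
  dimnames(med) <- dimnames(iqr) <- dimnames(draws)[1:2]
  mask <- suppressWarnings(jacobianSparsity(net))
  new("JacobianEnsemble", draws = draws, median = med, iqr = iqr, mask = mask,
      elasticityDraws = edraws,
      elasticityMedian = apply(edraws, 1, stats::median),
      parameterIndex = design$paramIndex,
      conditionLabel = conditionLabel, network = net,
      successRate = mean(ok))
}

#' @rdname JacobianEnsemble-class
#' @export
setMethod("medianJacobian", "JacobianEnsemble", function(x) x@median)

#' @rdname JacobianEnsemble-class
#' @export
setMethod("iqrJacobian", "JacobianEnsemble", function(x) x@iqr)

#' @rdname JacobianEnsemble-class
#' @export
setMethod("sparsityMask", "JacobianEnsemble", function(x) x@mask)

#' @rdname JacobianEnsemble-class
#' @export
setMethod("metaboliteIds", "JacobianEnsemble", function(x) rownames(x@median))

#' Export ensemble summaries as labeled TSV
#'
#' @param ens a [JacobianEnsemble-class].
#' @param medianPath,iqrPath output paths (either may be NULL).
#' @param header optional `#` comment line.
#' @return invisibly, the paths written.
#' @export
writeEnsemble <- function(ens, medianPath = NULL, iqrPath = NULL, header = NULL) {
  written <- character()
  if (!is.null(medianPath)) {
    .writeLabeledTSV(ens@median, medianPath, header = header)
    written <- c(written, medianPath)
  }
  if (!is.null(iqrPath)) {
    .writeLabeledTSV(ens@iqr, iqrPath, header = header)
    written <- c(written, iqrPath)
  }
  invisible(written)
}

setMethod("show", "JacobianEnsemble", function(object) {
  cat(sprintf("JacobianEnsemble '%s': %d x %d Jacobian, %d draws (%.0f%% success)\n",
              object@conditionLabel, nrow(object@median), ncol(object@median),
              dim(object@draws)[3], 100 * object@successRate))
})
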