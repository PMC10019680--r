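# PCA / PLS-DA / OPLS-DA on Pareto-scaled intensities, NIPALS-style.

.codeLabels <- function(labels) {
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L)
    stop("exactly two classes required (got ", length(lv), ")")
  if (any(table(labels) < 2L)) stop("both classes need >= 2 samples")
  list(y = ifelse(as.character(labels) == lv[2], 1, -1), levels = lv)
}

# center + pareto scale with stored parameters, so held-out samples can be
# preprocessed with training-fold statistics during cross-validation
.scaleTrain <- function(X, scaling = c("pareto", "none")) {
  scaling <- match.arg(scaling)
  ctr <- colMeans(X)
  if (scaling == "pareto") {
    s <- apply(X, 2, stats::sd)
    if (any(s == 0))
      stop("zero-variance metabolite(s) in multivariate fit: ",
           paste(colnames(X)[s == 0], collapse = ", "))
    sc <- sqrt(s)
  } else sc <- rep(1, ncol(X))
  list(X = sweep(sweep(X, 2, ctr), 2, sc, "/"), center = ctr, scale = sc)
}

.scaleApply <- function(X, prep) sweep(sweep(X, 2, prep$center), 2, prep$scale, "/")

# PLS1 NIPALS on preprocessed X and centered y; returns weights/loadings in
# the deflated coordinate systems plus fit statistics.
.pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); Pl <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp); ssy <- numeric(ncomp)
  ssx0 <- sum(X^2); ssy0 <- sum(y^2)
  r2x <- numeric(ncomp); r2y <- numeric(ncomp)
  Xd <- X; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    pl <- crossprod(Xd, t_) / tt
    qa <- sum(yd * t_) / tt
    Xd <- Xd - tcrossprod(t_, pl)
    yd <- yd - qa * t_
    W[, a] <- w; Pl[, a] <- pl; Tm[, a] <- t_; q[a] <- qa
    ssy[a] <- qa^2 * tt
    r2x[a] <- 1 - sum(Xd^2) / ssx0
    r2y[a] <- 1 - sum(yd^2) / ssy0
  }
  if (ncomp == 0L) stop("no usable PLS component (response uncorrelated with data)")
  keep <- seq_len(ncomp)
  list(W = W[, keep, drop = FALSE], P = Pl[, keep, drop = FALSE],
       T = Tm[, keep, drop = FALSE], q = q[keep], ssy = ssy[keep],
       r2xCum = r2x[keep], r2yCum = r2y[keep], ncomp = ncomp)
}

# regression coefficients of a PLS1 fit in the preprocessed X space
.plsCoef <- function(fit, ncomp = fit$ncomp) {
  a <- seq_len(ncomp)
  W <- fit$W[, a, drop = FALSE]; P <- fit$P[, a, drop = FALSE]
  W %*% solve(crossprod(P, W), fit$q[a])
}

.stratifiedFolds <- function(labels, k) {
  n <- length(labels)
  fold <- integer(n)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
  }
  fold
}

# cross-validated Q2 per cumulative component count; fitFun(Xraw, y) must
# return a function(XrawNew) -> matrix of predictions (one column per a)
.q2cv <- function(Xraw, y, labels, ncomp, folds, fitPredict) {
  n <- length(y)
  k <- min(folds, min(table(labels)))
  if (k < 2) k <- n                      # leave-one-out fallback
  k <- min(k, n)
  fold <- if (k == n) seq_len(n) else .stratifiedFolds(labels, k)
  press <- matrix(0, 1, ncomp)
  for (f in unique(fold)) {
    test <- fold == f
    pred <- fitPredict(Xraw[!test, , drop = FALSE], y[!test],
                       Xraw[test, , drop = FALSE], ncomp)
    press <- press + colSums((y[test] - pred)^2)
  }
  tss <- sum((y - mean(y))^2)
  as.numeric(1 - press / tss)
}

#' Principal component analysis of metabolite profiles
#'
#' Pareto-scales the data (the convention for metabolomics intensity
#' tables) and extracts components by singular value decomposition,
#' ordered by decreasing explained variance.
#'
#' @param p a [MetaboliteProfiles-class].
#' @param nComponents number of components (at most
#'   `min(samples - 1, metabolites)`).
#' @param scaling `"pareto"` (default) or `"none"` (mean-centering only).
#' @return a [LatentModel-class] of kind `"pca"` with `r2xCum` the
#'   cumulative explained-variance fraction.
#' @export
fitPCA <- function(p, nComponents = 2L, scaling = c("pareto", "none")) {
  X0 <- profileValues(p)
  nmax <- min(nrow(X0) - 1L, ncol(X0))
  if (nComponents > nmax)
    stop("nComponents must be <= min(samples - 1, metabolites) = ", nmax)
  if (all(apply(X0, 2, stats::sd) == 0))
    stop("degenerate profiles: all replicates identical")
  prep <- .scaleTrain(X0, match.arg(scaling))
  sv <- svd(prep$X, nu = nComponents, nv = nComponents)
  scores <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  expl <- sv$d^2 / sum(sv$d^2)
  rownames(scores) <- colnames(p)
  rownames(sv$v) <- colnames(X0)
  new("LatentModel", kind = "pca", scores = scores,
      xLoadings = sv$v, xWeights = sv$v, yLoadings = numeric(0),
      orthoScores = matrix(0, nrow(X0), 0), orthoLoadings = matrix(0, ncol(X0), 0),
      orthoWeights = matrix(0, ncol(X0), 0),
      r2xCum = cumsum(expl)[seq_len(nComponents)],
      r2yCum = numeric(0), q2Cum = numeric(0), ssy = numeric(0),
      center = prep$center, scaleFactor = prep$scale,
      yMean = NA_real_, classLevels = character(0))
}

.plsdaFitPredict <- function(scaling) function(Xtr, ytr, Xte, ncomp) {
  prep <- .scaleTrain(Xtr, scaling)
  yc <- ytr - mean(ytr)
  fit <- .pls1(prep$X, yc, ncomp)
  Xs <- .scaleApply(Xte, prep)
  sapply(seq_len(ncomp), function(a)
    if (a <= fit$ncomp) Xs %*% .plsCoef(fit, a) + mean(ytr)
    else Xs %*% .plsCoef(fit, fit$ncomp) + mean(ytr)) |>
    matrix(nrow = nrow(Xte))
}

#' Two-class partial least squares discriminant analysis
#'
#' Codes the two condition labels as a -1/+1 response, Pareto-scales the
#' metabolite intensities, and extracts sequential NIPALS components.
#' `r2yCum` is the cumulative fraction of response variance fitted;
#' `q2Cum` the cross-validated analogue (stratified `cvFolds`-fold,
#' falling back to leave-one-out when a class is smaller than the fold
#' count).
#'
#' @param p a [MetaboliteProfiles-class].
#' @param labels two-class labels (default: the profiles' conditions).
#' @param nComponents number of predictive components.
#' @param cvFolds cross-validation folds for Q2 (default 7).
#' @param scaling `"pareto"` or `"none"`.
#' @param cvSeed seed fixing the fold assignment.
#' @return a [LatentModel-class] of kind `"plsda"`.
#' @export
fitPLSDA <- function(p, labels = NULL, nComponents = 2L, cvFolds = 7L,
                     scaling = c("pareto", "none"), cvSeed = 1L) {
  scaling <- match.arg(scaling)
  X0 <- profileValues(p)
  if (is.null(labels)) labels <- sampleConditions(p)
  cl <- .codeLabels(labels)
  prep <- .scaleTrain(X0, scaling)
  yc <- cl$y - mean(cl$y)
  fit <- .pls1(prep$X, yc, nComponents)
  q2 <- .withSeed(cvSeed,
    .q2cv(X0, cl$y, labels, fit$ncomp, cvFolds, .plsdaFitPredict(scaling)))
  rownames(fit$T) <- colnames(p)
  rownames(fit$W) <- rownames(fit$P) <- colnames(X0)
  new("LatentModel", kind = "plsda", scores = fit$T,
      xLoadings = fit$P, xWeights = fit$W, yLoadings = fit$q,
      orthoScores = matrix(0, nrow(X0), 0),
      orthoLoadings = matrix(0, ncol(X0), 0),
      orthoWeights = matrix(0, ncol(X0), 0),
      r2xCum = fit$r2xCum, r2yCum = fit$r2yCum, q2Cum = q2, ssy = fit$ssy,
      center = prep$center, scaleFactor = prep$scale,
      yMean = mean(cl$y), classLevels = cl$levels)
}

# orthogonal signal correction: strips components of X that are orthogonal
# to y; returns filtered X and the removed score/loading/weight sets
.oscFilter <- function(X, y, nOrthogonal) {
  p <- ncol(X)
  To <- matrix(0, nrow(X), nOrthogonal)
  Po <- matrix(0, p, nOrthogonal); Wo <- matrix(0, p, nOrthogonal)
  w <- crossprod(X, y); w <- w / sqrt(sum(w^2))
  for (a in seq_len(nOrthogonal)) {
    t_ <- X %*% w
    pl <- crossprod(X, t_) / sum(t_^2)
    wo <- pl - as.numeric(crossprod(w, pl)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) { nOrthogonal <- a - 1L; break }
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to) / sum(to^2)
    X <- X - tcrossprod(to, po)
    To[, a] <- to; Po[, a] <- po; Wo[, a] <- wo
  }
  keep <- seq_len(nOrthogonal)
  list(X = X, To = To[, keep, drop = FALSE], Po = Po[, keep, drop = FALSE],
       Wo = Wo[, keep, drop = FALSE], n = nOrthogonal)
}

.oplsdaFitPredict <- function(scaling, nOrthogonal) function(Xtr, ytr, Xte, ncomp) {
  prep <- .scaleTrain(Xtr, scaling)
  yc <- ytr - mean(ytr)
  osc <- if (nOrthogonal > 0) .oscFilter(prep$X, yc, nOrthogonal)
         else list(X = prep$X, Wo = NULL, Po = NULL, n = 0L)
  fit <- .pls1(osc$X, yc, 1L)
  Xs <- .scaleApply(Xte, prep)
  if (osc$n > 0)
    for (a in seq_len(osc$n)) {
      to <- Xs %*% osc$Wo[, a]
      Xs <- Xs - tcrossprod(to, osc$Po[, a])
    }
  matrix(Xs %*% .plsCoef(fit, 1L) + mean(ytr), nrow = nrow(Xte))
}

#' Orthogonal PLS discriminant analysis
#'
#' Removes `nOrthogonal` components of the (scaled) data that are
#' orthogonal to the class response, then fits a single predictive PLS
#' component on the filtered data. With `nOrthogonal = 0` this is exactly
#' a 1-component PLS-DA. Useful when structured variation unrelated to
#' the class labels dominates the data.
#'
#' @inheritParams fitPLSDA
#' @param nOrthogonal number of label-orthogonal components to remove.
#' @return a [LatentModel-class] of kind `"oplsda"`; `scores` holds the
#'   predictive component, `orthoScores` the removed ones.
#' @export
fitOPLSDA <- function(p, labels = NULL, nOrthogonal = 1L, cvFolds = 7L,
                      scaling = c("pareto", "none"), cvSeed = 1L) {
  scaling <- match.arg(scaling)
  X0 <- profileValues(p)
  if (is.null(labels)) labels <- sampleConditions(p)
  cl <- .codeLabels(labels)
  prep <- .scaleTrain(X0, scaling)
  yc <- cl$y - mean(cl$y)
  ssx0 <- sum(prep$X^2)
  osc <- if (nOrthogonal > 0) .oscFilter(prep$X, yc, nOrthogonal)
         else list(X = prep$X, To = matrix(0, nrow(X0), 0),
                   Po = matrix(0, ncol(X0), 0), Wo = matrix(0, ncol(X0), 0), n = 0L)
  fit <- .pls1(osc$X, yc, 1L)
  q2 <- .withSeed(cvSeed,
    .q2cv(X0, cl$y, labels, 1L, cvFolds, .oplsdaFitPredict(scaling, nOrthogonal)))
  r2x <- 1 - sum((osc$X - tcrossprod(fit$T, fit$P))^2) / ssx0
  rownames(fit$T) <- colnames(p)
  rownames(fit$W) <- rownames(fit$P) <- colnames(X0)
  new("LatentModel", kind = "oplsda", scores = fit$T,
      xLoadings = fit$P, xWeights = fit$W, yLoadings = fit$q,
      orthoScores = osc$To, orthoLoadings = osc$Po, orthoWeights = osc$Wo,
      r2xCum = r2x, r2yCum = fit$r2yCum, q2Cum = q2, ssy = fit$ssy,
      center = prep$center, scaleFactor = prep$scale,
      yMean = mean(cl$y), classLevels = cl$levels)
}

#' @rdname vipScores
#' @export
setMethod("vipScores", "LatentModel", function(model) {
  if (model@kind == "pca") stop("VIP undefined for PCA")
  W <- model@xWeights
  ssy <- model@ssy
  p <- nrow(W)
  num <- (W^2) %*% ssy
  v <- sqrt(p * num / sum(ssy))
  stats::setNames(as.numeric(v), rownames(W))
})

setMethod("show", "LatentModel", function(object) {
  cat(sprintf("LatentModel (%s): %d component(s)\n", object@kind,
              ncol(object@scores)))
  if (length(object@r2xCum))
    cat("  R2X(cum):", paste(signif(object@r2xCum, 3), collapse = " "), "\n")
  if (length(object@r2yCum))
    cat("  R2Y(cum):", paste(signif(object@r2yCum, 3), collapse = " "), "\n")
  if (length(object@q2Cum))
    cat("  Q2(cum): ", paste(signif(object@q2Cum, 3), collapse = " "), "\n")
  if (object@kind == "oplsda")
    cat("  orthogonal components removed:", ncol(object@orthoScores), "\n")
})
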