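#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats median quantile sd var cov rnorm runif t.test prcomp setNames cor lm coef p.adjust
#' @importFrom utils read.csv read.delim write.table head
NULL

.tol <- 1e-8

#' MetabolicNetwork: reactions, stoichiometry and elasticity sparsity
#'
#' Holds an ordered metabolite table, a reaction list, the metabolite x
#' reaction stoichiometric matrix N (the "interaction" or RENEW matrix), and
#' the reaction x metabolite elasticity sparsity pattern: `TRUE` where the
#' rate of a reaction is allowed to depend on a metabolite concentration.
#' The Jacobian of the network is parameterized as J = N %*% E with the
#' elasticity matrix E nonzero only on the pattern.
#'
#' @slot metabolites data.frame with columns `id`, `name`, `is_cofactor`,
#'   in first-appearance order; all matrices are indexed by this order.
#' @slot reactions list of reaction records (`id`, `substrates`, `products`
#'   as named integer vectors of stoichiometric coefficients, `modifiers`
#'   as a character vector of metabolite ids).
#' @slot stoichiometry integer matrix, metabolites x reactions; entry =
#'   product coefficient minus substrate coefficient.
#' @slot elasticityPattern logical matrix, reactions x metabolites.
#' @export
setClass("MetabolicNetwork",
  slots = c(
    metabolites = "data.frame",
    reactions = "list",
    stoichiometry = "matrix",
    elasticityPattern = "matrix"
  )
)

setValidity("MetabolicNetwork", function(object) {
  msg <- character()
  ids <- object@metabolites$id
  if (length(ids) == 0L) msg <- c(msg, "network has no metabolites")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate metabolite ids")
  if (any(!nzchar(ids))) msg <- c(msg, "empty metabolite id")
  rids <- vapply(object@reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) msg <- c(msg, "duplicate reaction ids")
  S <- object@stoichiometry
  P <- object@elasticityPattern
  if (!identical(dim(S), c(length(ids), length(rids))))
    msg <- c(msg, "stoichiometry dimensions inconsistent with lists")
  if (!identical(dim(P), c(length(rids), length(ids))))
    msg <- c(msg, "elasticityPattern dimensions inconsistent with lists")
  if (!is.logical(P)) msg <- c(msg, "elasticityPattern must be logical")
  for (k in seq_along(object@reactions)) {
    rx <- object@reactions[[k]]
    both <- intersect(names(rx$substrates), names(rx$products))
    if (length(both))
      msg <- c(msg, sprintf("reaction '%s': metabolite on both sides (%s)",
                            rx$id, paste(both, collapse = ", ")))
    if (length(rx$substrates) == 0L && length(rx$products) == 0L)
      msg <- c(msg, sprintf("reaction '%s' has neither substrates nor products", rx$id))
    unknown <- setdiff(c(names(rx$substrates), names(rx$products), rx$modifiers), ids)
    if (length(unknown))
      msg <- c(msg, sprintf("reaction '%s' references unknown metabolite(s): %s",
                            rx$id, paste(unknown, collapse = ", ")))
    # substrate/modifier elasticities must be allowed by the pattern
    need <- c(names(rx$substrates), rx$modifiers)
    if (length(need) && !all(P[k, match(need, ids)]))
      msg <- c(msg, sprintf("reaction '%s': pattern misses a substrate/modifier", rx$id))
  }
  if (length(msg)) msg else TRUE
})

#' MetaboliteProfiles: replicate metabolite intensity profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `intensity`
#' assay (metabolites as rows, biological replicates as columns) and a
#' required `condition` column in `colData()`. Constructed by
#' [MetaboliteProfiles()] or [readProfiles()].
#'
#' @export
setClass("MetaboliteProfiles", contains = "SummarizedExperiment")

setValidity("MetaboliteProfiles", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else if (!is.numeric(SummarizedExperiment::assay(object, "intensity")))
    msg <- c(msg, "assay 'intensity' must be numeric")
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'condition' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "metabolite ids (rownames) must exist and be unique")
  if (length(msg)) msg else TRUE
})

#' CovarianceMatrix: metabolite covariance with sample-size provenance
#'
#' @slot values symmetric numeric matrix (metabolites x metabolites).
#' @slot nSamples number of replicates the estimate is based on.
#' @export
setClass("CovarianceMatrix",
  slots = c(values = "matrix", nSamples = "integer"))

setValidity("CovarianceMatrix", function(object) {
  V <- object@values
  msg <- character()
  if (nrow(V) != ncol(V)) msg <- c(msg, "covariance must be square")
  if (is.null(rownames(V)) || !identical(rownames(V), colnames(V)))
    msg <- c(msg, "covariance must carry identical row/column metabolite ids")
  sc <- max(1, max(abs(V)))
  if (max(abs(V - t(V))) > 1e-8 * sc) msg <- c(msg, "covariance not symmetric")
  if (any(diag(V) < -1e-10 * sc)) msg <- c(msg, "negative variance on diagonal")
  ev <- tryCatch(eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (!is.null(ev) && min(ev) < -1e-6 * sc)
    msg <- c(msg, "covariance not positive semidefinite")
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (length(msg)) msg else TRUE
})

#' FluctuationModel: diagonal metabolic fluctuation (diffusion) model
#'
#' The fluctuation matrix FLU of the Lyapunov equation is modelled as
#' diagonal and positive. Monte-Carlo draws jitter each diagonal entry
#' multiplicatively: `base * exp(spread * z)`, `z ~ N(0, 1)`, which keeps
#' FLU positive definite and has median equal to `base`.
#'
#' @slot baseIntensity positive base diagonal, one value per metabolite.
#' @slot spread non-negative log-scale dispersion of the draws.
#' @slot seed integer seed; together with a draw index it fixes the draw.
#' @export
setClass("FluctuationModel",
  slots = c(baseIntensity = "numeric", spread = "numeric", seed = "integer"))

setValidity("FluctuationModel", function(object) {
  msg <- character()
  if (any(object@baseIntensity <= 0)) msg <- c(msg, "baseIntensity must be > 0")
  if (length(object@spread) != 1L || object@spread < 0)
    msg <- c(msg, "spread must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' JacobianEnsemble: Monte-Carlo stack of reconstructed Jacobians
#'
#' One Jacobian per fluctuation draw, with entrywise median and
#' interquartile range, the structural sparsity mask, and the free
#' elasticity draws the Jacobians were assembled from.
#'
#' @slot draws numeric array, metabolites x metabolites x draws.
#' @slot median,iqr entrywise summaries over draws.
#' @slot mask logical matrix of structurally allowed Jacobian entries.
#' @slot elasticityDraws matrix, free parameters x draws (elasticity mode)
#'   or masked Jacobian entries x draws (direct mode).
#' @slot elasticityMedian per-parameter median of `elasticityDraws`.
#' @slot parameterIndex data.frame locating each free parameter
#'   (`reaction`, `metabolite` in elasticity mode; `row`, `col` labels
#'   in direct mode).
#' @slot conditionLabel condition the input covariance came from.
#' @slot network the MetabolicNetwork used for the reconstruction.
#' @slot successRate fraction of draws that solved.
#' @export
setClass("JacobianEnsemble",
  slots = c(
    draws = "array", median = "matrix", iqr = "matrix", mask = "matrix",
    elasticityDraws = "matrix", elasticityMedian = "numeric",
    parameterIndex = "data.frame", conditionLabel = "character",
    network = "MetabolicNetwork", successRate = "numeric"
  )
)

setValidity("JacobianEnsemble", function(object) {
  msg <- character()
  d <- dim(object@draws)
  if (length(d) != 3L || d[1] != d[2]) msg <- c(msg, "draws must be an m x m x k array")
  if (!identical(dim(object@median), d[1:2]) || !identical(dim(object@iqr), d[1:2]))
    msg <- c(msg, "median/iqr dimensions must match draws")
  if (any(object@iqr < 0)) msg <- c(msg, "iqr must be non-negative")
  off <- !object@mask
  if (any(object@draws[array(off, dim = d)] != 0))
    msg <- c(msg, "entries outside the sparsity mask must be exactly zero")
  if (length(msg)) msg else TRUE
})

#' DifferentialJacobian: normalized entrywise comparison of two ensembles
#'
#' @slot delta non-negative score matrix: |median difference| divided by the
#'   squared pooled interquartile range (floored at `epsilon`).
#' @slot signedDelta signed median differences (condition B minus A).
#' @slot ranking data.frame of masked entries sorted by decreasing score.
#' @slot labels the two condition names (A, B).
#' @slot epsilon floor applied to the squared pooled IQR.
#' @slot mask common sparsity mask.
#' @export
setClass("DifferentialJacobian",
  slots = c(delta = "matrix", signedDelta = "matrix", ranking = "data.frame",
            labels = "character", epsilon = "numeric", mask = "matrix"))

setValidity("DifferentialJacobian", function(object) {
  msg <- character()
  if (any(object@delta[!object@mask] != 0))
    msg <- c(msg, "delta must be exactly zero outside the mask")
  if (any(object@delta < 0)) msg <- c(msg, "delta scores must be non-negative")
  if (is.unsorted(rev(object@ranking$score)))
    msg <- c(msg, "ranking must be sorted by non-increasing score")
  if (nrow(object@ranking) != sum(object@mask))
    msg <- c(msg, "ranking must cover exactly the masked-in entries")
  if (length(object@labels) != 2L) msg <- c(msg, "labels must name two conditions")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' LatentModel: PCA / PLS-DA / OPLS-DA fit
#'
#' @slot kind one of `"pca"`, `"plsda"`, `"oplsda"`.
#' @slot scores sample scores (samples x components; predictive component
#'   only for OPLS-DA).
#' @slot xLoadings,xWeights per-component loadings/weights (variables x
#'   components); weights are unit-norm.
#' @slot yLoadings inner-relation coefficient per component (empty for PCA).
#' @slot orthoScores,orthoLoadings,orthoWeights label-orthogonal components
#'   removed by OPLS-DA (zero-column matrices otherwise).
#' @slot r2xCum,r2yCum,q2Cum cumulative model statistics per component.
#' @slot ssy explained response sum-of-squares per component (PLS kinds).
#' @slot center,scaleFactor column preprocessing applied before the fit.
#' @slot yMean mean of the coded class response; `classLevels` the two
#'   class labels coded as -1/+1.
#' @export
setClass("LatentModel",
  slots = c(kind = "character", scores = "matrix", xLoadings = "matrix",
            xWeights = "matrix", yLoadings = "numeric",
            orthoScores = "matrix", orthoLoadings = "matrix", orthoWeights = "matrix",
            r2xCum = "numeric", r2yCum = "numeric", q2Cum = "numeric",
            ssy = "numeric", center = "numeric", scaleFactor = "numeric",
            yMean = "numeric", classLevels = "character"))

setValidity("LatentModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("pca", "plsda", "oplsda"))
    msg <- c(msg, "kind must be pca, plsda or oplsda")
  if (ncol(object@scores) > 1L) {
    G <- crossprod(object@scores)
    offd <- abs(G[upper.tri(G)])
    if (max(offd) > 1e-6 * max(diag(G)))
      msg <- c(msg, "component scores must be mutually orthogonal")
  }
  if (length(object@r2xCum) && (is.unsorted(object@r2xCum - 1e-12) ||
                                max(object@r2xCum) > 1 + 1e-8))
    msg <- c(msg, "r2xCum must be non-decreasing and <= 1")
  if (length(msg)) msg else TRUE
})

#' KineticGroundTruth: simulated network with known Jacobian
#'
#' @slot network the MetabolicNetwork.
#' @slot trueElasticities reactions x metabolites elasticity matrix,
#'   nonzero only on the network's pattern.
#' @slot trueJacobian stoichiometry %*% trueElasticities (Hurwitz-stable).
#' @slot trueFluctuation diagonal positive fluctuation matrix.
#' @slot analyticCovariance stationary covariance solving the Lyapunov
#'   equation for (trueJacobian, trueFluctuation).
#' @export
setClass("KineticGroundTruth",
  slots = c(network = "MetabolicNetwork", trueElasticities = "matrix",
            trueJacobian = "matrix", trueFluctuation = "matrix",
            analyticCovariance = "CovarianceMatrix"))

setValidity("KineticGroundTruth", function(object) {
  msg <- character()
  J <- object@trueJacobian
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0)
    msg <- c(msg, "trueJacobian must be Hurwitz-stable")
  C <- object@analyticCovariance@values
  R <- J %*% C + C %*% t(J) + 2 * object@trueFluctuation
  if (max(abs(R)) > 1e-8 * (1 + max(abs(C))))
    msg <- c(msg, "analyticCovariance does not satisfy the Lyapunov equation")
  if (length(msg)) msg else TRUE
})
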