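#' Unbiased sample covariance of metabolite profiles
#'
#' Estimates the metabolite x metabolite covariance of the biological
#' replicate-to-replicate variation — the quantity that, together with an
#' assumed fluctuation matrix, determines the Jacobian through the
#' stationary Lyapunov equation. The unbiased (n - 1) estimator is used
#' because replicate groups are typically small.
#'
#' @param p a [MetaboliteProfiles-class]; if `condition` is given, only the
#'   matching replicates are used.
#' @param condition optional condition label to subset to first.
#' @return a [CovarianceMatrix-class].
#' @export
sampleCovariance <- function(p, condition = NULL) {
  if (!is.null(condition)) p <- subsetCondition(p, condition)
  X <- profileValues(p)
  if (nrow(X) < 2L)
    stop("covariance needs >= 2 replicates (got ", nrow(X), ")")
  V <- stats::cov(X)              # n - 1 denominator
  V <- (V + t(V)) / 2             # exact symmetry
  new("CovarianceMatrix", values = V, nSamples = nrow(X))
}

#' @param values symmetric numeric matrix with metabolite dimnames.
#' @param nSamples replicate count behind the estimate.
#' @rdname CovarianceMatrix-class
#' @export
CovarianceMatrix <- function(values, nSamples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("M", seq_len(nrow(values))),
                             paste0("M", seq_len(ncol(values))))
  new("CovarianceMatrix", values = (values + t(values)) / 2,
      nSamples = as.integer(nSamples))
}

#' @rdname CovarianceMatrix-class
#' @param x a CovarianceMatrix
#' @param ... ignored
#' @export
setMethod("as.matrix", "CovarianceMatrix", function(x, ...) x@values)

#' @rdname CovarianceMatrix-class
#' @export
setMethod("metaboliteIds", "CovarianceMatrix", function(x) rownames(x@values))

#' Export a covariance matrix as labeled TSV
#'
#' @param covm a [CovarianceMatrix-class].
#' @param path output path.
#' @param header optional `#` comment line.
#' @return `path`, invisibly.
#' @export
writeCovariance <- function(covm, path, header = NULL) {
  .writeLabeledTSV(covm@values, path,
                   header = c(header, sprintf("n_samples: %d", covm@nSamples)))
}

setMethod("show", "CovarianceMatrix", function(object) {
  cat(sprintf("CovarianceMatrix: %d metabolites, n = %d replicates\n",
              nrow(object@values), object@nSamples))
})
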