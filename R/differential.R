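#' Differential Jacobian between two conditions
#'
#' For every structurally allowed Jacobian entry, scores the difference of
#' the two conditions' ensemble medians normalized to the square of the
#' interquartile distance of the ensembles: by default
#' `|median_B - median_A| / max(meanIQR^2, epsilon)` with
#' `meanIQR = (iqr_A + iqr_B) / 2` (the pooled reading is symmetric in the
#' two conditions; per-condition normalization before differencing is
#' available via `normalization`). Large scores flag reaction elasticities
#' whose inferred value shifted between conditions by much more than the
#' Monte-Carlo reconstruction uncertainty.
#'
#' @param a,b [JacobianEnsemble-class] objects with identical metabolite
#'   order and sparsity mask (conditions A and B).
#' @param epsilon positive floor applied to the squared IQR; default
#'   `1e-6 *` the largest pooled IQR over masked entries (guards the
#'   `spread = 0` degenerate case).
#' @param normalization `"pooled"` (default) or `"per-condition"`
#'   (`|median_B/iqr_B^2 - median_A/iqr_A^2|`).
#' @return a [DifferentialJacobian-class].
#' @export
differentialJacobian <- function(a, b, epsilon = NULL,
                                 normalization = c("pooled", "per-condition")) {
  normalization <- match.arg(normalization)
  stopifnot(is(a, "JacobianEnsemble"), is(b, "JacobianEnsemble"))
  if (!identical(rownames(a@median), rownames(b@median)))
    stop("ensembles have different metabolite order")
  if (!identical(a@mask, b@mask))
    stop("ensembles have different sparsity masks")
  mask <- a@mask
  pooled <- (a@iqr + b@iqr) / 2
  if (is.null(epsilon)) {
    top <- if (any(mask)) max(pooled[mask]) else 0
    epsilon <- max(1e-6 * top, .Machine$double.eps)
  }
  stopifnot(epsilon > 0)
  signed <- b@median - a@median
  if (normalization == "pooled") {
    delta <- abs(signed) / pmax(pooled^2, epsilon)
  } else {
    delta <- abs(b@median / pmax(b@iqr^2, epsilon) -
                 a@median / pmax(a@iqr^2, epsilon))
  }
  delta[!mask] <- 0
  signed[!mask] <- 0
  idx <- which(mask, arr.ind = TRUE)
  rk <- data.frame(row = rownames(mask)[idx[, 1]],
                   col = colnames(mask)[idx[, 2]],
                   score = delta[idx],
                   signedDifference = signed[idx],
                   medianA = a@median[idx], medianB = b@median[idx],
                   iqrA = a@iqr[idx], iqrB = b@iqr[idx],
                   stringsAsFactors = FALSE)
  # descending score; deterministic tie-break by (row index, column index)
  ord <- order(-rk$score, idx[, 1], idx[, 2])
  rk <- rk[ord, , drop = FALSE]
  rownames(rk) <- NULL
  new("DifferentialJacobian", delta = delta, signedDelta = signed,
      ranking = rk,
      labels = c(a@conditionLabel, b@conditionLabel),
      epsilon = epsilon, mask = mask)
}

#' Top perturbed Jacobian entries
#'
#' @param d a [DifferentialJacobian-class].
#' @param topK number of entries to report; truncated with a warning when
#'   it exceeds the number of masked entries.
#' @return data.frame with `rank`, `entry` (label
#'   `"df_ROW/df_COL"`), the two metabolites, the score and the signed
#'   median difference.
#' @export
rankPerturbations <- function(d, topK = 10L) {
  stopifnot(is(d, "DifferentialJacobian"))
  n <- nrow(d@ranking)
  if (topK > n) {
    warning("topK = ", topK, " exceeds the ", n, " masked entries; truncating")
    topK <- n
  }
  rk <- d@ranking[seq_len(topK), , drop = FALSE]
  data.frame(rank = seq_len(topK),
             entry = sprintf("df_%s/df_%s", rk$row, rk$col),
             row = rk$row, col = rk$col,
             score = rk$score, signedDifference = rk$signedDifference,
             stringsAsFactors = FALSE)
}

#' @rdname DifferentialJacobian-class
#' @export
setMethod("ranking", "DifferentialJacobian", function(x) x@ranking)

#' Export the full differential ranking as TSV
#'
#' @param d a [DifferentialJacobian-class].
#' @param path output path.
#' @param header optional `#` comment line(s).
#' @return `path`, invisibly.
#' @export
writeDifferential <- function(d, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# conditions: ", d@labels[1], " vs ", d@labels[2]),
               if (!is.null(header)) paste0("# ", header)), con)
  df <- cbind(rank = seq_len(nrow(d@ranking)), d@ranking)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "DifferentialJacobian", function(object) {
  cat(sprintf("DifferentialJacobian: %s vs %s, %d masked entries\n",
              object@labels[1], object@labels[2], nrow(object@ranking)))
  top <- head(object@ranking, 3)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %d. df_%s/df_%s  score %.4g\n", i, top$row[i], top$col[i],
                top$score[i]))
})
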