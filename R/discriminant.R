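#' Label-permutation validation of a discriminant model
#'
#' Refits the discriminant model on class labels permuted at random
#' `nPermutations` times (default 200) and compares the original R2Y and
#' Q2 against the permuted distributions. Overfitting is flagged by the
#' intercept criterion: the least-squares regressions of permuted R2Y and
#' Q2 on the absolute correlation between permuted and original labels
#' must both intercept (at correlation 0) below the original statistics.
#' A one-sided permutation p-value for Q2 uses the add-one convention.
#'
#' @param p a [MetaboliteProfiles-class].
#' @param labels two-class labels (default: the profiles' conditions).
#' @param nPermutations number of label permutations.
#' @param seed RNG seed (permutation stream and CV folds).
#' @param model `"plsda"` (default) or `"oplsda"`.
#' @param nComponents components for PLS-DA (OPLS-DA always has 1
#'   predictive component).
#' @param nOrthogonal orthogonal components for OPLS-DA.
#' @param cvFolds folds for the Q2 of every fit.
#' @return list of class `"permutationResult"` with the original and
#'   permuted statistics, the intercepts, `intercept_ok` and `p_value`.
#' @export
permutationValidate <- function(p, labels = NULL, nPermutations = 200L,
                                seed = 1L, model = c("plsda", "oplsda"),
                                nComponents = 2L, nOrthogonal = 1L,
                                cvFolds = 7L) {
  model <- match.arg(model)
  if (is.null(labels)) labels <- sampleConditions(p)
  cl <- .codeLabels(labels)
  fitOne <- function(lab, cvSeed) {
    if (model == "plsda")
      fitPLSDA(p, lab, nComponents = nComponents, cvFolds = cvFolds,
               cvSeed = cvSeed)
    else
      fitOPLSDA(p, lab, nOrthogonal = nOrthogonal, cvFolds = cvFolds,
                cvSeed = cvSeed)
  }
  orig <- fitOne(labels, .substreamSeed(seed, 0L))
  r2o <- tail1(orig@r2yCum); q2o <- tail1(orig@q2Cum)
  permR2 <- numeric(nPermutations); permQ2 <- numeric(nPermutations)
  permCor <- numeric(nPermutations)
  for (i in seq_len(nPermutations)) {
    perm <- .withSeed(.substreamSeed(seed, i), sample(labels))
    permCor[i] <- abs(stats::cor(ifelse(perm == cl$levels[2], 1, -1), cl$y))
    f <- tryCatch(fitOne(perm, .substreamSeed(seed, 100000L + i)),
                  error = function(e) NULL)
    if (is.null(f)) { permR2[i] <- NA; permQ2[i] <- NA; next }
    permR2[i] <- tail1(f@r2yCum); permQ2[i] <- tail1(f@q2Cum)
  }
  okp <- is.finite(permR2) & is.finite(permQ2)
  interceptAt0 <- function(stat) {
    if (stats::sd(permCor[okp]) < 1e-12) return(mean(stat[okp]))
    unname(stats::coef(stats::lm(stat[okp] ~ permCor[okp]))[1])
  }
  r2int <- interceptAt0(permR2); q2int <- interceptAt0(permQ2)
  res <- list(nPermutations = nPermutations,
              original_r2 = r2o, original_q2 = q2o,
              permuted_r2 = permR2, permuted_q2 = permQ2,
              permuted_cor = permCor,
              r2_intercept = r2int, q2_intercept = q2int,
              intercept_ok = (r2int < r2o) && (q2int < q2o),
              p_value = (1 + sum(permQ2[okp] >= q2o)) / (sum(okp) + 1),
              model = model, seed = seed)
  class(res) <- "permutationResult"
  res
}

tail1 <- function(x) if (length(x)) x[length(x)] else NA_real_

#' @export
print.permutationResult <- function(x, ...) {
  cat(sprintf("Permutation validation (%s, n = %d)\n", x$model, x$nPermutations))
  cat(sprintf("  original R2Y = %.3f, Q2 = %.3f\n", x$original_r2, x$original_q2))
  cat(sprintf("  intercepts: R2 %.3f, Q2 %.3f -> %s\n", x$r2_intercept,
              x$q2_intercept, if (x$intercept_ok) "valid" else "overfit"))
  cat(sprintf("  permutation p-value (Q2) = %.4g\n", x$p_value))
  invisible(x)
}

#' Per-metabolite log fold change between two classes
#'
#' The logarithm (default base 2) of the ratio of class-mean intensities
#' (second class level over first, levels sorted alphabetically, or as
#' given in `classOrder`).
#'
#' @param p a [MetaboliteProfiles-class].
#' @param labels two-class labels (default: the profiles' conditions).
#' @param base logarithm base.
#' @param classOrder optional length-2 character giving (reference,
#'   comparison) class.
#' @return named numeric vector of log fold changes.
#' @export
foldChange <- function(p, labels = NULL, base = 2, classOrder = NULL) {
  X <- profileValues(p)
  if (is.null(labels)) labels <- sampleConditions(p)
  lv <- classOrder %||% sort(unique(as.character(labels)))
  stopifnot(length(lv) == 2L, all(labels %in% lv))
  m1 <- colMeans(X[labels == lv[1], , drop = FALSE])
  m2 <- colMeans(X[labels == lv[2], , drop = FALSE])
  bad <- m1 <= 0 | m2 <= 0
  if (any(bad))
    stop("non-positive class mean for metabolite(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  log(m2 / m1, base = base)
}

#' Two-tailed two-sample t-test p-values per metabolite
#'
#' @param p a [MetaboliteProfiles-class].
#' @param labels two-class labels (default: the profiles' conditions).
#' @param welch use the Welch unequal-variance test (default; safer for
#'   the small replicate groups typical of targeted metabolomics) or the
#'   classic pooled-variance test.
#' @return named numeric vector of p-values.
#' @export
tTestPValues <- function(p, labels = NULL, welch = TRUE) {
  X <- profileValues(p)
  if (is.null(labels)) labels <- sampleConditions(p)
  cl <- .codeLabels(labels)
  g1 <- labels == cl$levels[1]
  apply(X, 2, function(v)
    stats::t.test(v[g1], v[!g1], var.equal = !welch)$p.value)
}

#' Discriminant-metabolite selection rule
#'
#' A metabolite is selected iff its VIP score strictly exceeds
#' `vipThreshold` (default 1.0) and its p-value is strictly below `alpha`
#' (default 0.05). No multiple-testing correction is applied in the rule
#' itself; a Benjamini-Hochberg adjusted column is reported alongside.
#'
#' @param vip named non-negative VIP scores.
#' @param pValues p-values of the same length/order.
#' @param vipThreshold,alpha strict selection thresholds.
#' @param logFoldChange optional log fold changes to carry along.
#' @return data.frame with `metabolite`, `vip`, `p_value`, `p_adj_bh`,
#'   optional `log_fold_change`, and logical `selected`.
#' @export
selectDiscriminant <- function(vip, pValues, vipThreshold = 1.0, alpha = 0.05,
                               logFoldChange = NULL) {
  if (length(vip) != length(pValues))
    stop("vip and pValues lengths differ")
  if (!is.null(logFoldChange) && length(logFoldChange) != length(vip))
    stop("logFoldChange length differs")
  out <- data.frame(metabolite = names(vip) %||% seq_along(vip),
                    vip = as.numeric(vip), p_value = as.numeric(pValues),
                    p_adj_bh = stats::p.adjust(pValues, "BH"),
                    stringsAsFactors = FALSE)
  if (!is.null(logFoldChange)) out$log_fold_change <- as.numeric(logFoldChange)
  out$selected <- out$vip > vipThreshold & out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' One-call discriminant-metabolite table
#'
#' Fits an OPLS-DA model (the convention for VIP-based biomarker
#' screening), computes VIP scores, per-metabolite two-tailed t-test
#' p-values on the raw intensities, log fold changes, and applies the
#' VIP > 1 and p < 0.05 selection rule.
#'
#' @param p a [MetaboliteProfiles-class].
#' @param labels two-class labels (default: the profiles' conditions).
#' @param nOrthogonal orthogonal components of the OPLS-DA fit.
#' @param vipThreshold,alpha selection thresholds.
#' @param foldChangeBase base of the log fold change.
#' @param welch Welch t-test toggle.
#' @param cvSeed seed for the Q2 folds.
#' @return list with `table` (the selection data.frame), `model`
#'   (the fitted [LatentModel-class]).
#' @export
discriminantStats <- function(p, labels = NULL, nOrthogonal = 1L,
                              vipThreshold = 1.0, alpha = 0.05,
                              foldChangeBase = 2, welch = TRUE, cvSeed = 1L) {
  if (is.null(labels)) labels <- sampleConditions(p)
  model <- fitOPLSDA(p, labels, nOrthogonal = nOrthogonal, cvSeed = cvSeed)
  vip <- vipScores(model)
  pv <- tTestPValues(p, labels, welch = welch)
  lfc <- foldChange(p, labels, base = foldChangeBase)
  list(table = selectDiscriminant(vip, pv, vipThreshold, alpha,
                                  logFoldChange = lfc),
       model = model)
}
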