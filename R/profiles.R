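#' Construct MetaboliteProfiles from a replicate x metabolite table
#'
#' @param values numeric matrix or data.frame, rows = biological replicates,
#'   columns = metabolites (non-negative raw intensities).
#' @param condition character/factor of length `nrow(values)` labelling each
#'   replicate's biological condition.
#' @param sampleIds optional replicate ids (default: rownames or S1, S2, ...).
#' @return a [MetaboliteProfiles-class] (metabolites as rows internally,
#'   following the assay convention).
#' @export
MetaboliteProfiles <- function(values, condition, sampleIds = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("profile values must be numeric")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at sample %s, metabolite %s (imputation is not supported)",
                 bad[1], bad[2]))
  }
  if (length(condition) != nrow(values))
    stop("condition must have one label per replicate (row)")
  if (is.null(colnames(values))) stop("metabolite ids (column names) required")
  if (is.null(sampleIds))
    sampleIds <- rownames(values) %||% paste0("S", seq_len(nrow(values)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = t(values)),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = sampleIds))
  new("MetaboliteProfiles", se)
}

#' Read replicate metabolite profiles from a CSV/TSV table
#'
#' Wide rectangular table: one row per biological replicate, one numeric
#' column per metabolite, plus a condition-label column. The delimiter is
#' chosen by file extension (`.csv` vs anything else = tab).
#'
#' @param path input file path.
#' @param conditionColumn name of the condition-label column.
#' @param sampleColumn optional name of a sample-id column; a column
#'   literally named `sample` is used automatically when present.
#' @return a [MetaboliteProfiles-class] preserving metabolite column order.
#' @export
readProfiles <- function(path, conditionColumn = "condition", sampleColumn = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) utils::read.csv
            else utils::read.delim
  df <- reader(path, check.names = FALSE, stringsAsFactors = FALSE,
               comment.char = "#")
  if (!conditionColumn %in% names(df))
    stop("condition column '", conditionColumn, "' not found in ", path)
  condition <- as.character(df[[conditionColumn]])
  df[[conditionColumn]] <- NULL
  sampleIds <- NULL
  if (is.null(sampleColumn) && "sample" %in% names(df)) sampleColumn <- "sample"
  if (!is.null(sampleColumn)) {
    if (!sampleColumn %in% names(df))
      stop("sample column '", sampleColumn, "' not found in ", path)
    sampleIds <- as.character(df[[sampleColumn]])
    df[[sampleColumn]] <- NULL
  }
  for (j in names(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   j, if (is.na(bad)) 1L else bad, path))
    }
    if (anyNA(v))
      stop(sprintf("missing value in column '%s', row %d of %s",
                   j, which(is.na(v))[1], path))
  }
  MetaboliteProfiles(as.matrix(df), condition, sampleIds = sampleIds)
}

#' Write profiles to a CSV/TSV table readable by [readProfiles()]
#'
#' @param p a [MetaboliteProfiles-class].
#' @param path output path (`.csv` for comma-separated, else tab).
#' @param header optional `#` comment lines written before the table.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(p, path, header = NULL) {
  df <- data.frame(sample = colnames(p),
                   condition = sampleConditions(p),
                   profileValues(p), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname MetaboliteProfiles-class
#' @export
setMethod("profileValues", "MetaboliteProfiles", function(x)
  t(SummarizedExperiment::assay(x, "intensity")))

#' @rdname MetaboliteProfiles-class
#' @export
setMethod("sampleConditions", "MetaboliteProfiles", function(x)
  as.character(SummarizedExperiment::colData(x)$condition))

#' @rdname MetaboliteProfiles-class
#' @export
setMethod("metaboliteIds", "MetaboliteProfiles", function(x) rownames(x))

#' Subset profiles to one condition
#'
#' @param p a [MetaboliteProfiles-class].
#' @param condition condition label to keep.
#' @return a [MetaboliteProfiles-class] with only the matching replicates.
#' @export
subsetCondition <- function(p, condition) {
  keep <- sampleConditions(p) == condition
  if (!any(keep)) stop("condition '", condition, "' not present in profiles")
  p[, keep]
}

#' Pareto scaling
#'
#' Mean-centers each metabolite and divides by the square root of its
#' standard deviation, the scaling conventionally applied to metabolomics
#' intensity data before multivariate modelling: it shrinks the dominance
#' of high-abundance metabolites while inflating noise less than unit
#' scaling does.
#'
#' @param p a [MetaboliteProfiles-class].
#' @param allowConstant if `TRUE`, a zero-variance metabolite becomes an
#'   all-zero column with a warning instead of an error.
#' @return a [MetaboliteProfiles-class] of scaled values (no longer
#'   non-negative).
#' @export
paretoScale <- function(p, allowConstant = FALSE) {
  X <- profileValues(p)
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0
  if (any(zero) && !allowConstant)
    stop("zero-variance metabolite(s): ", paste(colnames(X)[zero], collapse = ", "),
         " (set allowConstant = TRUE to zero them out)")
  if (any(zero))
    warning("zero-variance metabolite(s) set to zero: ",
            paste(colnames(X)[zero], collapse = ", "))
  Xs <- sweep(X, 2, colMeans(X))
  Xs[, !zero] <- sweep(Xs[, !zero, drop = FALSE], 2, sqrt(sds[!zero]), "/")
  Xs[, zero] <- 0
  out <- MetaboliteProfiles(Xs, sampleConditions(p), sampleIds = colnames(p))
  S4Vectors::metadata(out)$scaling <- "pareto"
  out
}

#' Elementwise log transform
#'
#' @param p a [MetaboliteProfiles-class].
#' @param base logarithm base (> 1).
#' @param pseudocount non-negative constant added before taking logs.
#' @return a [MetaboliteProfiles-class] of transformed values.
#' @export
logTransform <- function(p, base = exp(1), pseudocount = 0) {
  stopifnot(base > 1, pseudocount >= 0)
  X <- profileValues(p) + pseudocount
  if (any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive value at sample %d, metabolite '%s' after pseudocount %g",
                 bad[1], colnames(X)[bad[2]], pseudocount))
  }
  out <- MetaboliteProfiles(log(X, base = base), sampleConditions(p),
                            sampleIds = colnames(p))
  S4Vectors::metadata(out)$scaling <- sprintf("log base %g", base)
  out
}

setMethod("show", "MetaboliteProfiles", function(object) {
  tab <- table(sampleConditions(object))
  cat(sprintf("MetaboliteProfiles: %d metabolites x %d replicates\n",
              nrow(object), ncol(object)))
  cat("  conditions:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "), "\n")
})
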