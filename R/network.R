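#' Build a MetabolicNetwork from reaction records
#'
#' @param reactions list of reaction records; each a list with `id`
#'   (character), `substrates` and `products` (named numeric vectors of
#'   positive integer stoichiometric coefficients, names = metabolite ids),
#'   and optional `modifiers` (character vector of metabolite ids that
#'   affect the rate without mass change).
#' @param cofactors character vector of metabolite ids flagged as cofactors
#'   (reporting only; cofactors are ordinary Jacobian coordinates).
#' @param productElasticities if `TRUE`, reaction rates are also allowed to
#'   depend on their products (reversible kinetics); the default keeps the
#'   irreversible assumption, which leaves the inverse problem better
#'   determined.
#' @param names optional named character vector mapping metabolite ids to
#'   free-text names.
#' @return a validated [MetabolicNetwork-class]; metabolite order is
#'   first-appearance order over the reaction list.
#' @export
MetabolicNetwork <- function(reactions, cofactors = character(),
                             productElasticities = FALSE, names = NULL) {
  if (length(reactions) == 0L) stop("no reactions")
  ids <- character()
  for (rx in reactions) {
    for (m in c(names(rx$substrates), names(rx$products), rx$modifiers))
      if (!m %in% ids) ids <- c(ids, m)
  }
  rids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ", rids[duplicated(rids)][1])
  m <- length(ids); R <- length(reactions)
  S <- matrix(0L, m, R, dimnames = list(ids, rids))
  P <- matrix(FALSE, R, m, dimnames = list(rids, ids))
  for (k in seq_len(R)) {
    rx <- reactions[[k]]
    rx$modifiers <- as.character(rx$modifiers %||% character())
    for (s in names(rx$substrates)) S[s, k] <- S[s, k] - as.integer(rx$substrates[[s]])
    for (p in names(rx$products)) S[p, k] <- S[p, k] + as.integer(rx$products[[p]])
    dep <- c(names(rx$substrates), rx$modifiers)
    if (productElasticities) dep <- c(dep, names(rx$products))
    P[k, match(unique(dep), ids)] <- TRUE
    reactions[[k]] <- rx
  }
  meta <- data.frame(id = ids,
                     name = if (is.null(names)) ids else
                       ifelse(ids %in% base::names(names), names[ids], ids),
                     is_cofactor = ids %in% cofactors,
                     stringsAsFactors = FALSE)
  new("MetabolicNetwork", metabolites = meta, reactions = reactions,
      stoichiometry = S, elasticityPattern = P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parseSide <- function(txt, line, path) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(stats::setNames(numeric(0), character(0)))
  out <- numeric(0)
  for (term in strsplit(txt, "+", fixed = TRUE)[[1]]) {
    term <- trimws(term)
    if (!nzchar(term)) next
    toks <- strsplit(term, "[[:space:]]+")[[1]]
    if (length(toks) == 1L) {
      coef <- 1; id <- toks
    } else if (length(toks) == 2L && grepl("^[0-9]+$", toks[1])) {
      coef <- as.numeric(toks[1]); id <- toks[2]
    } else {
      stop(sprintf("%s: parse error at line %d: cannot read term '%s'",
                   path, line, term))
    }
    out[id] <- (if (id %in% names(out)) out[[id]] else 0) + coef
  }
  out
}

#' Read a metabolic network from a reaction-list text file
#'
#' One reaction per line in the form
#' `id : a A + b B -> c C | modifiers: M1, M2`, with optional coefficients
#' (default 1), `#` comments, blank lines ignored, and an optional
#' `cofactors: NAD, NADH` directive line flagging cofactor metabolites.
#' Either side of `->` may be empty (exchange reactions).
#'
#' @param path path to the reaction-list file.
#' @param productElasticities passed to [MetabolicNetwork()].
#' @return a validated [MetabolicNetwork-class].
#' @export
readNetwork <- function(path, productElasticities = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  reactions <- list()
  cofactors <- character()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^cofactors[[:space:]]*:", ln)) {
      cf <- sub("^cofactors[[:space:]]*:", "", ln)
      cofactors <- c(cofactors, trimws(strsplit(cf, ",")[[1]]))
      next
    }
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop(sprintf("%s: parse error at line %d: expected 'id : reaction'", path, i))
    id <- trimws(parts[1])
    body <- trimws(paste(parts[-1], collapse = ":"))
    mods <- character()
    if (grepl("|", body, fixed = TRUE)) {
      bp <- strsplit(body, "|", fixed = TRUE)[[1]]
      body <- trimws(bp[1])
      modtxt <- trimws(paste(bp[-1], collapse = "|"))
      if (!grepl("^modifiers[[:space:]]*:", modtxt))
        stop(sprintf("%s: parse error at line %d: expected 'modifiers:' clause", path, i))
      modtxt <- sub("^modifiers[[:space:]]*:", "", modtxt)
      mods <- trimws(strsplit(modtxt, ",")[[1]])
      mods <- mods[nzchar(mods)]
    }
    if (!grepl("->", body, fixed = TRUE))
      stop(sprintf("%s: parse error at line %d: missing '->'", path, i))
    sides <- strsplit(body, "->", fixed = TRUE)[[1]]
    if (length(sides) > 2L)
      stop(sprintf("%s: parse error at line %d: more than one '->'", path, i))
    subs <- .parseSide(sides[1], i, path)
    prods <- .parseSide(if (length(sides) > 1L) sides[2] else "", i, path)
    reactions[[length(reactions) + 1L]] <-
      list(id = id, substrates = subs, products = prods, modifiers = mods)
  }
  if (length(reactions) == 0L) stop(path, ": no reactions")
  MetabolicNetwork(reactions, cofactors = cofactors,
                   productElasticities = productElasticities)
}

#' Write a network back to the reaction-list text format
#'
#' Inverse of [readNetwork()]: reloading the written file yields an
#' identical network.
#'
#' @param net a [MetabolicNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(net, path) {
  fmt <- function(v) paste(ifelse(v > 1, paste(v, names(v)), names(v)),
                           collapse = " + ")
  lines <- character()
  cf <- net@metabolites$id[net@metabolites$is_cofactor]
  if (length(cf)) lines <- c(lines, paste0("cofactors: ", paste(cf, collapse = ", ")))
  for (rx in net@reactions) {
    ln <- paste0(rx$id, " : ", fmt(rx$substrates), " -> ", fmt(rx$products))
    if (length(rx$modifiers))
      ln <- paste0(ln, " | modifiers: ", paste(rx$modifiers, collapse = ", "))
    lines <- c(lines, ln)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Structural sparsity of the Jacobian
#'
#' Entry (i, j) of the Jacobian J = N %*% E can be nonzero only if some
#' reaction k both changes metabolite i (nonzero stoichiometry) and is
#' allowed to depend on metabolite j (elasticity pattern). The returned
#' mask is that allowed-nonzero set.
#'
#' @param net a [MetabolicNetwork-class].
#' @return logical metabolites x metabolites matrix.
#' @export
jacobianSparsity <- function(net) {
  mask <- (net@stoichiometry != 0) %*% (net@elasticityPattern * 1) > 0
  dimnames(mask) <- list(net@metabolites$id, net@metabolites$id)
  if (any(rowSums(mask) == 0))
    warning("metabolite(s) with an all-false Jacobian row: ",
            paste(rownames(mask)[rowSums(mask) == 0], collapse = ", "),
            " (no stable dynamics possible for them)")
  mask
}

#' Count free elasticity parameters against available equations
#'
#' The symmetric Lyapunov equation supplies n(n+1)/2 independent scalar
#' equations for n metabolites; the free unknowns are the allowed
#' elasticity entries. Reports both counts and the determinacy of the
#' inverse problem.
#'
#' @param net a [MetabolicNetwork-class].
#' @return list with `free`, `equations`, `determinacy` (one of
#'   "over-determined", "exactly-determined", "under-determined").
#' @export
countFreeParameters <- function(net) {
  n <- nrow(net@stoichiometry)
  free <- sum(net@elasticityPattern)
  eqs <- n * (n + 1L) / 2L
  list(free = free, equations = eqs,
       determinacy = if (free < eqs) "over-determined"
                     else if (free == eqs) "exactly-determined"
                     else "under-determined")
}

#' Export stoichiometry and Jacobian sparsity as labeled TSV
#'
#' @param net a [MetabolicNetwork-class].
#' @param stoichiometryPath,sparsityPath output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
exportNetworkMatrices <- function(net, stoichiometryPath = NULL, sparsityPath = NULL) {
  written <- character()
  if (!is.null(stoichiometryPath)) {
    .writeLabeledTSV(net@stoichiometry, stoichiometryPath)
    written <- c(written, stoichiometryPath)
  }
  if (!is.null(sparsityPath)) {
    .writeLabeledTSV(jacobianSparsity(net) * 1L, sparsityPath)
    written <- c(written, sparsityPath)
  }
  invisible(written)
}

#' @rdname MetabolicNetwork-class
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites$id)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("reactionIds", "MetabolicNetwork",
          function(x) vapply(x@reactions, `[[`, character(1), "id"))

#' @rdname MetabolicNetwork-class
#' @export
setMethod("stoichiometry", "MetabolicNetwork", function(x) x@stoichiometry)

#' @rdname MetabolicNetwork-class
#' @export
setMethod("elasticityPattern", "MetabolicNetwork", function(x) x@elasticityPattern)

setMethod("show", "MetabolicNetwork", function(object) {
  cp <- countFreeParameters(object)
  cat(sprintf("MetabolicNetwork: %d metabolites, %d reactions\n",
              nrow(object@metabolites), length(object@reactions)))
  cat(sprintf("  free elasticities: %d | Lyapunov equations: %d (%s)\n",
              cp$free, cp$equations, cp$determinacy))
  cat("  metabolites:", paste(head(object@metabolites$id, 12), collapse = ", "),
      if (nrow(object@metabolites) > 12) "..." else "", "\n")
})
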