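# End-to-end orchestration: profiles + network -> covariances -> ensembles
# -> differential ranking; profiles + labels -> discriminant table.

.configHash <- function(config) {
  flat <- vapply(names(config), function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1))
  .fnv1a(paste(sort(flat), collapse = ";"))
}

.writeManifest <- function(path, config, extra = list()) {
  manifest <- c(list(config = config, config_hash = .configHash(config),
                     package_version = as.character(utils::packageVersion("metarecon")),
                     r_version = R.version.string),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the covariance-to-differential-Jacobian pipeline
#'
#' Full reconstruction workflow for one condition pair: per-condition
#' sample covariance, Monte-Carlo ensemble inversion against the network
#' sparsity, and the differential-Jacobian ranking, all written as labeled
#' TSV files plus a machine-readable JSON manifest (configuration, its
#' hash, seed, per-condition draw success rates). Every output file
#' carries a `#` header with the configuration hash and seed, and reruns
#' with the same configuration are numerically identical.
#'
#' @param profiles a [MetaboliteProfiles-class] or a path readable by
#'   [readProfiles()].
#' @param network a [MetabolicNetwork-class] or a path readable by
#'   [readNetwork()].
#' @param conditions length-2 character: (reference, comparison) condition
#'   labels.
#' @param outDir output directory (created if needed).
#' @param nDraws Monte-Carlo draws per condition.
#' @param fluRel,fluSpread fluctuation model: base = `fluRel * diag(cov)`,
#'   log-scale draw dispersion `fluSpread`.
#' @param fluBase optional explicit fluctuation base diagonal (overrides
#'   `fluRel`).
#' @param ridge ridge penalty of each inversion.
#' @param mode `"elasticity"` or `"direct"` (see [invertOnce()]).
#' @param epsilon IQR floor of [differentialJacobian()] (NULL = default).
#' @param topK entries in the printed top ranking.
#' @param seed master seed; per-condition substreams are derived from it.
#' @return invisibly, a list with the two [JacobianEnsemble-class]s, the
#'   [DifferentialJacobian-class], the top-`topK` table and `outDir`.
#' @export
runMetarecon <- function(profiles, network, conditions, outDir,
                         nDraws = 1000L, fluRel = 0.1, fluSpread = 0.2,
                         fluBase = NULL, ridge = 1e-8,
                         mode = c("elasticity", "direct"),
                         epsilon = NULL, topK = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(profiles)) profiles <- readProfiles(profiles)
  if (is.character(network)) network <- readNetwork(network)
  stopifnot(length(conditions) == 2L)
  missing <- setdiff(conditions, unique(sampleConditions(profiles)))
  if (length(missing))
    stop("stage profiles: condition(s) not present in data: ",
         paste(missing, collapse = ", "))
  ids <- metaboliteIds(network)
  if (!all(ids %in% metaboliteIds(profiles)))
    stop("stage profiles: network metabolite(s) missing from profiles: ",
         paste(setdiff(ids, metaboliteIds(profiles)), collapse = ", "))
  profiles <- profiles[ids, ]            # network order
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- list(conditions = conditions, nDraws = nDraws, fluRel = fluRel,
                 fluSpread = fluSpread, fluBase = fluBase %||% "data-driven",
                 ridge = ridge, mode = mode,
                 epsilon = epsilon %||% "auto", topK = topK, seed = seed)
  hdr <- sprintf("config_hash: %s | seed: %d", .configHash(config), seed)

  ensembles <- list()
  for (i in 1:2) {
    cond <- conditions[i]
    covm <- sampleCovariance(profiles, condition = cond)
    writeCovariance(covm, file.path(outDir, paste0("covariance_", cond, ".tsv")),
                    header = hdr)
    flu <- if (is.null(fluBase))
      defaultFluctuation(covm, rel = fluRel, spread = fluSpread,
                         seed = .substreamSeed(seed, i))
    else FluctuationModel(fluBase, spread = fluSpread,
                          seed = .substreamSeed(seed, i))
    prob <- inverseProblem(covm, network, fluctuation = flu, nDraws = nDraws,
                           ridge = ridge, mode = mode)
    ens <- ensembleInvert(prob, conditionLabel = cond)
    writeEnsemble(ens,
                  medianPath = file.path(outDir, paste0("jacobian_median_", cond, ".tsv")),
                  iqrPath = file.path(outDir, paste0("jacobian_iqr_", cond, ".tsv")),
                  header = hdr)
    ensembles[[cond]] <- ens
  }
  dj <- differentialJacobian(ensembles[[1]], ensembles[[2]], epsilon = epsilon)
  writeDifferential(dj, file.path(outDir, "differential_ranking.tsv"), header = hdr)
  top <- rankPerturbations(dj, topK = min(topK, nrow(dj@ranking)))
  .writeManifest(file.path(outDir, "manifest.json"), config,
                 extra = list(success_rates = lapply(ensembles, function(e) e@successRate),
                              n_samples = lapply(conditions, function(cond)
                                sum(sampleConditions(profiles) == cond)),
                              top_entry = top$entry[1]))
  invisible(list(ensembles = ensembles, differential = dj, top = top,
                 outDir = outDir))
}

#' Run the discriminant-metabolite pipeline
#'
#' OPLS-DA (with VIP scores), per-metabolite two-tailed t-tests and log
#' fold changes, the VIP > 1 and p < 0.05 selection rule, and a
#' label-permutation validation of the model, written as TSV/JSON outputs
#' with a configuration-hash header.
#'
#' @param profiles a [MetaboliteProfiles-class] or a path readable by
#'   [readProfiles()].
#' @param conditions length-2 condition labels to compare.
#' @param outDir output directory.
#' @param nOrthogonal orthogonal OPLS-DA components.
#' @param vipThreshold,alpha selection thresholds.
#' @param nPermutations label permutations for the validation step.
#' @param seed master seed.
#' @return invisibly, a list with the selection `table`, the fitted
#'   `model`, the `permutation` result, and `outDir`.
#' @export
runDiscriminant <- function(profiles, conditions, outDir, nOrthogonal = 1L,
                            vipThreshold = 1.0, alpha = 0.05,
                            nPermutations = 200L, seed = 1L) {
  if (is.character(profiles)) profiles <- readProfiles(profiles)
  stopifnot(length(conditions) == 2L)
  missing <- setdiff(conditions, unique(sampleConditions(profiles)))
  if (length(missing))
    stop("stage profiles: condition(s) not present in data: ",
         paste(missing, collapse = ", "))
  keep <- sampleConditions(profiles) %in% conditions
  profiles <- profiles[, keep]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- list(conditions = conditions, nOrthogonal = nOrthogonal,
                 vipThreshold = vipThreshold, alpha = alpha,
                 nPermutations = nPermutations, seed = seed)
  hdr <- sprintf("config_hash: %s | seed: %d", .configHash(config), seed)

  ds <- discriminantStats(profiles, nOrthogonal = nOrthogonal,
                          vipThreshold = vipThreshold, alpha = alpha,
                          cvSeed = .substreamSeed(seed, 0L))
  con <- file(file.path(outDir, "discriminant_table.tsv"), "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(ds$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  pv <- permutationValidate(profiles, nPermutations = nPermutations,
                            seed = seed, model = "oplsda",
                            nOrthogonal = nOrthogonal)
  .writeManifest(file.path(outDir, "manifest.json"), config,
                 extra = list(
                   model = list(r2x = tail1(ds$model@r2xCum),
                                r2y = tail1(ds$model@r2yCum),
                                q2 = tail1(ds$model@q2Cum)),
                   permutation = list(p_value = pv$p_value,
                                      intercept_ok = pv$intercept_ok,
                                      r2_intercept = pv$r2_intercept,
                                      q2_intercept = pv$q2_intercept),
                   n_selected = sum(ds$table$selected)))
  invisible(list(table = ds$table, model = ds$model, permutation = pv,
                 outDir = outDir))
}
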