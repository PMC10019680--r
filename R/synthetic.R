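# Synthetic ground-truth module: stable metabolic Jacobians driving an
# Ornstein-Uhlenbeck fluctuation process around steady state, built around
# the D-serine synthesis pathway.

#' Built-in D-serine synthesis pathway network
#'
#' The de novo D-serine route 3-phosphoglycerate -> 3-phosphohydroxypyruvate
#' (PHGDH, NAD+ -> NADH) -> phosphoserine (PSAT1, Glu -> KGA) -> L-serine
#' (PSPH) -> D-serine (SRR), closed into a stable system by a glutamate-
#' dehydrogenase-like cofactor recycling reaction GDH
#' (KGA + NADH -> Glu + NAD), D-serine degradation (DAAO), first-order
#' NAD/Glu consumption by the rest of metabolism, and exchange inflows.
#' The GDH recycling step couples the NADH and alpha-ketoglutarate (KGA,
#' also written KEG) coordinates, so the NADH-KGA Jacobian entry is
#' structurally allowed — the coupling through which a serine-pathway
#' perturbation is expected to surface in a differential Jacobian.
#'
#' @return a [MetabolicNetwork-class] with 9 metabolites and 13 reactions;
#'   NAD/NADH are flagged as cofactors.
#' @export
serineNetwork <- function() {
  rx <- list(
    list(id = "PGin",   substrates = c(),            products = c(`3PG` = 1)),
    list(id = "PHGDH",  substrates = c(`3PG` = 1, NAD = 1),
         products = c(`3PHP` = 1, NADH = 1)),
    list(id = "PSAT1",  substrates = c(`3PHP` = 1, Glu = 1),
         products = c(PSer = 1, KGA = 1)),
    list(id = "PSPH",   substrates = c(PSer = 1),    products = c(LSer = 1)),
    list(id = "SRR",    substrates = c(LSer = 1),    products = c(DSer = 1)),
    list(id = "DAAO",   substrates = c(DSer = 1),    products = c()),
    list(id = "GDH",    substrates = c(KGA = 1, NADH = 1),
         products = c(Glu = 1, NAD = 1)),
    list(id = "NADin",  substrates = c(),            products = c(NAD = 1)),
    list(id = "NADuse", substrates = c(NAD = 1),     products = c()),
    list(id = "NADHox", substrates = c(NADH = 1),    products = c()),
    list(id = "Gluin",  substrates = c(),            products = c(Glu = 1)),
    list(id = "Gluout", substrates = c(Glu = 1),     products = c()),
    list(id = "KGAdh",  substrates = c(KGA = 1),     products = c())
  )
  MetabolicNetwork(rx, cofactors = c("NAD", "NADH"))
}

#' 40-metabolite screening-panel network
#'
#' Pads the D-serine pathway network with independent bystander
#' metabolites (each with its own inflow and first-order degradation) up
#' to a targeted-panel size, emulating a metabolomics screen in which only
#' a small sub-network is biologically coupled. The bystanders are an
#' explicit synthetic stand-in, not a curated network.
#'
#' @param nMetabolites total panel size (default 40; at least 10).
#' @return a [MetabolicNetwork-class].
#' @export
panelNetwork <- function(nMetabolites = 40L) {
  base <- serineNetwork()
  nby <- nMetabolites - nrow(base@metabolites)
  if (nby < 1L) stop("nMetabolites must exceed the 9 pathway metabolites")
  rx <- base@reactions
  for (i in seq_len(nby)) {
    id <- sprintf("B%02d", i)
    rx[[length(rx) + 1L]] <- list(id = paste0(id, "in"), substrates = c(),
                                  products = stats::setNames(1, id))
    rx[[length(rx) + 1L]] <- list(id = paste0(id, "dg"),
                                  substrates = stats::setNames(1, id),
                                  products = c())
  }
  MetabolicNetwork(rx, cofactors = c("NAD", "NADH"))
}

#' Sample a ground-truth kinetic parameterization
#'
#' Draws elasticities on the network's sparsity pattern — positive for
#' substrates (rates increase with substrate availability), negative by
#' default for modifiers — and a positive diagonal fluctuation matrix,
#' retrying (with progressively damped modifier strength) until the
#' implied Jacobian `N E` is Hurwitz-stable. The stationary covariance is
#' computed analytically by [solveLyapunov()].
#'
#' @param net a [MetabolicNetwork-class].
#' @param elasticityScale overall elasticity magnitude (1/time units).
#' @param fluctScale magnitude of the fluctuation diagonal.
#' @param seed RNG seed; identical seeds give identical truths.
#' @param modifierSign +1 or -1 sign given to modifier elasticities.
#' @param maxRetries bound on stability resampling attempts.
#' @return a [KineticGroundTruth-class].
#' @export
makeGroundTruth <- function(net, elasticityScale = 1, fluctScale = 0.1,
                            seed = 1L, modifierSign = -1, maxRetries = 50L) {
  ids <- net@metabolites$id
  R <- length(net@reactions); m <- length(ids)
  isSub <- matrix(FALSE, R, m)
  for (k in seq_len(R))
    isSub[k, match(names(net@reactions[[k]]$substrates), ids)] <- TRUE
  pat <- net@elasticityPattern
  if (!any(pat)) stop("elasticity pattern is empty")
  .withSeed(seed, {
    damp <- 1
    for (try in seq_len(maxRetries)) {
      E <- matrix(0, R, m, dimnames = dimnames(pat))
      nsub <- sum(pat & isSub); nmod <- sum(pat & !isSub)
      E[pat & isSub] <- elasticityScale * stats::runif(nsub, 0.5, 1.5)
      E[pat & !isSub] <- modifierSign * damp * elasticityScale *
        stats::runif(nmod, 0.25, 0.75)
      J <- net@stoichiometry %*% E
      if (max(Re(eigen(J, only.values = TRUE)$values)) < -1e-8) {
        FLU <- diag(fluctScale * stats::runif(m, 0.5, 1.5), m)
        dimnames(J) <- list(ids, ids)
        C <- solveLyapunov(J, FLU)
        return(new("KineticGroundTruth", network = net, trueElasticities = E,
                   trueJacobian = J, trueFluctuation = FLU,
                   analyticCovariance = C))
      }
      if (try %% 10L == 0L) damp <- damp / 2
    }
    stop("no Hurwitz-stable parameterization found in ", maxRetries, " attempts")
  })
}

#' True free-elasticity vector of a ground truth
#'
#' The pattern entries of the true elasticity matrix in the order used by
#' [ensembleInvert()]'s `parameterIndex`, for direct comparison with
#' recovered values.
#'
#' @param truth a [KineticGroundTruth-class].
#' @return named numeric vector (names `"reaction:metabolite"`).
#' @export
trueFreeElasticities <- function(truth) {
  idx <- which(truth@network@elasticityPattern, arr.ind = TRUE)
  stats::setNames(truth@trueElasticities[idx],
                  paste(rownames(truth@trueElasticities)[idx[, 1]],
                        colnames(truth@trueElasticities)[idx[, 2]], sep = ":"))
}

#' Simulate replicate profiles from a stationary OU process
#'
#' Euler-Maruyama integration of `dx = J x dt + sqrt(2 FLU) dW` — the
#' linear fluctuation model whose stationary covariance solves the
#' Lyapunov equation `J C + C t(J) = -2 FLU`. Samples are taken after a
#' burn-in, at `thinning`-step intervals, and shifted by per-metabolite
#' steady-state offsets (`offsetFactor` times the stationary standard
#' deviation) so that emitted intensities are positive; optional i.i.d.
#' measurement noise can be added.
#'
#' @param truth a [KineticGroundTruth-class].
#' @param nSamples replicates to emit.
#' @param dt integration step; must satisfy `dt * max|eigenvalue(J)| < 0.1`
#'   (default `NULL`: `0.08 / max|eigenvalue|`, safely inside the guard).
#' @param burnIn integration steps discarded before sampling.
#' @param thinning steps between successive samples (default `NULL`: the
#'   number of steps spanning two relaxation times of the slowest network
#'   mode, `2 / (dt * min|Re eigenvalue|)`, so successive replicates are
#'   nearly independent draws of the stationary distribution — the
#'   independent-replicate design the covariance estimator assumes).
#' @param measurementNoiseSd standard deviation of additive measurement
#'   noise (0 = pure process fluctuation).
#' @param offsetFactor steady-state mean in units of stationary SD.
#' @param seed RNG seed.
#' @param condition condition label attached to the replicates.
#' @return a [MetaboliteProfiles-class].
#' @export
simulateOU <- function(truth, nSamples = 1000L, dt = NULL, burnIn = 2000L,
                       thinning = NULL, measurementNoiseSd = 0,
                       offsetFactor = 10, seed = 1L, condition = "control") {
  stopifnot(nSamples >= 1L, burnIn >= 0L, measurementNoiseSd >= 0)
  J <- truth@trueJacobian
  m <- nrow(J)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= 0) stop("unstable ground-truth Jacobian")
  if (is.null(dt)) dt <- 0.08 / max(Mod(ev))
  stopifnot(dt > 0)
  if (is.null(thinning)) thinning <- ceiling(2 / (dt * min(abs(Re(ev)))))
  stopifnot(thinning >= 1L)
  if (dt * max(Mod(ev)) >= 0.1)
    stop(sprintf("dt too large for stability: dt * max|eig| = %.3f >= 0.1",
                 dt * max(Mod(ev))))
  sdNoise <- sqrt(2 * diag(truth@trueFluctuation) * dt)
  offs <- offsetFactor * sqrt(diag(truth@analyticCovariance@values))
  X <- .withSeed(seed, {
    x <- numeric(m)
    out <- matrix(0, nSamples, m)
    steps <- burnIn + nSamples * thinning
    kept <- 0L
    for (s in seq_len(steps)) {
      x <- x + dt * as.numeric(J %*% x) + sdNoise * stats::rnorm(m)
      if (s > burnIn && (s - burnIn) %% thinning == 0L) {
        kept <- kept + 1L
        out[kept, ] <- x
      }
    }
    out <- sweep(out, 2, offs, "+")
    if (measurementNoiseSd > 0)
      out <- out + matrix(stats::rnorm(length(out), sd = measurementNoiseSd),
                          nrow(out), ncol(out))
    out
  })
  colnames(X) <- rownames(J)
  if (any(X <= 0))
    stop("non-positive simulated intensities; increase offsetFactor")
  MetaboliteProfiles(X, rep(condition, nSamples))
}

#' Perturb one elasticity of a ground truth
#'
#' Emulates a knockout-like condition: one allowed elasticity is
#' multiplied by `factor`, and the Jacobian and analytic covariance are
#' recomputed (the fluctuation matrix is kept).
#'
#' @param truth a [KineticGroundTruth-class].
#' @param reaction,metabolite coordinates of the elasticity (must be on
#'   the pattern).
#' @param factor multiplicative perturbation (e.g. 0.3 for a strong
#'   knockdown of that coupling).
#' @return a [KineticGroundTruth-class] for the perturbed condition.
#' @export
perturbCondition <- function(truth, reaction, metabolite, factor) {
  net <- truth@network
  k <- match(reaction, reactionIds(net))
  j <- match(metabolite, metaboliteIds(net))
  if (is.na(k)) stop("unknown reaction: ", reaction)
  if (is.na(j)) stop("unknown metabolite: ", metabolite)
  if (!net@elasticityPattern[k, j])
    stop(sprintf("elasticity (%s, %s) is not on the pattern", reaction, metabolite))
  E <- truth@trueElasticities
  E[k, j] <- E[k, j] * factor
  J <- net@stoichiometry %*% E
  dimnames(J) <- dimnames(truth@trueJacobian)
  if (max(Re(eigen(J, only.values = TRUE)$values)) >= 0)
    stop("perturbed system is not Hurwitz-stable")
  new("KineticGroundTruth", network = net, trueElasticities = E,
      trueJacobian = J, trueFluctuation = truth@trueFluctuation,
      analyticCovariance = solveLyapunov(J, truth@trueFluctuation))
}

#' Generate a two-condition dataset with known truth
#'
#' Control and perturbed conditions are simulated independently (disjoint
#' seed substreams) from the same ground truth except for one perturbed
#' elasticity, mirroring a control-vs-knockout design.
#'
#' @param truth control-condition [KineticGroundTruth-class].
#' @param reaction,metabolite,factor the perturbation
#'   (see [perturbCondition()]); `factor = 1` yields two identical-truth
#'   conditions.
#' @param nSamples replicates per condition.
#' @param conditionLabels length-2 labels (control, perturbed).
#' @param seed RNG seed (substreams derived per condition).
#' @param ... further arguments to [simulateOU()].
#' @return list with `profiles` (combined [MetaboliteProfiles-class]),
#'   `truthControl`, `truthPerturbed`.
#' @export
generateTwoConditionDataset <- function(truth, reaction, metabolite, factor,
                                        nSamples = 1000L,
                                        conditionLabels = c("control", "perturbed"),
                                        seed = 1L, ...) {
  stopifnot(length(conditionLabels) == 2L)
  truthP <- if (factor == 1) truth
            else perturbCondition(truth, reaction, metabolite, factor)
  pc <- simulateOU(truth, nSamples = nSamples, seed = .substreamSeed(seed, 1L),
                   condition = conditionLabels[1], ...)
  pp <- simulateOU(truthP, nSamples = nSamples, seed = .substreamSeed(seed, 2L),
                   condition = conditionLabels[2], ...)
  X <- rbind(profileValues(pc), profileValues(pp))
  rownames(X) <- paste0(rep(conditionLabels, each = nSamples), "_",
                        rep(seq_len(nSamples), 2))
  list(profiles = MetaboliteProfiles(
         X, rep(conditionLabels, each = nSamples)),
       truthControl = truth, truthPerturbed = truthP)
}

#' Simulate a simple two-class intensity panel
#'
#' A direct generator for discriminant-statistics testing: independent
#' metabolites with log-uniform baseline abundances and proportional
#' within-class variation; a chosen number of "effect" metabolites is
#' shifted by `effectSize` within-class standard deviations in the second
#' class. Replicate counts default to the small groups typical of targeted
#' metabolomics.
#'
#' @param nMetabolites panel size.
#' @param nPerClass replicates per class.
#' @param nEffects number of truly shifted metabolites.
#' @param effectSize shift in units of within-class SD.
#' @param cv within-class coefficient of variation.
#' @param classLabels length-2 class labels.
#' @param seed RNG seed.
#' @return a [MetaboliteProfiles-class]; the shifted metabolite ids are in
#'   `S4Vectors::metadata()$trueEffects`.
#' @export
simulateIntensityPanel <- function(nMetabolites = 40L, nPerClass = 6L,
                                   nEffects = 3L, effectSize = 2,
                                   cv = 0.15, classLabels = c("control", "case"),
                                   seed = 1L) {
  stopifnot(nEffects <= nMetabolites, nPerClass >= 2L)
  .withSeed(seed, {
    ids <- sprintf("M%02d", seq_len(nMetabolites))
    # one decade of baseline abundance: targeted panels are per-metabolite
    # calibrated, so response areas are far more homogeneous than full-scan
    mu <- 10^stats::runif(nMetabolites, 4.5, 5.5)
    sdv <- cv * mu
    effects <- sort(sample.int(nMetabolites, nEffects))
    mu2 <- mu
    mu2[effects] <- mu[effects] + effectSize * sdv[effects] *
      sample(c(-1, 1), nEffects, replace = TRUE)
    n <- nPerClass
    X <- rbind(
      matrix(stats::rnorm(n * nMetabolites, rep(mu, each = n),
                          rep(sdv, each = n)), n, nMetabolites),
      matrix(stats::rnorm(n * nMetabolites, rep(mu2, each = n),
                          rep(sdv, each = n)), n, nMetabolites))
    X <- pmax(X, 1)                      # intensities stay positive
    colnames(X) <- ids
    out <- MetaboliteProfiles(X, rep(classLabels, each = n))
    S4Vectors::metadata(out)$trueEffects <- ids[effects]
    out
  })
}

setMethod("show", "KineticGroundTruth", function(object) {
  ev <- eigen(object@trueJacobian, only.values = TRUE)$values
  cat(sprintf("KineticGroundTruth: %d metabolites, %d reactions\n",
              nrow(object@trueJacobian), length(object@network@reactions)))
  cat(sprintf("  Hurwitz margin: max Re(eig) = %.4g\n", max(Re(ev))))
})
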