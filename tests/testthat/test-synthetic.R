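test_that("the built-in serine network is chemically and structurally sound", {
  net <- serineNetwork()
  S <- stoichiometry(net)
  expect_equal(S[c("3PG", "NAD", "3PHP", "NADH"), "PHGDH"],
               c(`3PG` = -1, NAD = -1, `3PHP` = 1, NADH = 1))
  expect_equal(S[c("KGA", "NADH", "Glu", "NAD"), "GDH"],
               c(KGA = -1, NADH = -1, Glu = 1, NAD = 1))
  expect_true(jacobianSparsity(net)["NADH", "KGA"])
  expect_equal(countFreeParameters(net)$determinacy, "over-determined")
  # default parameterization is Hurwitz-stable
  tr <- makeGroundTruth(net, seed = 1)
  expect_true(stabilityReport(tr@trueJacobian)$stable)
})

test_that("ground truths satisfy their defining identities and are reproducible", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 42)
  expect_equal(tr@trueJacobian,
               stoichiometry(net) %*% tr@trueElasticities,
               ignore_attr = "dimnames")
  C <- tr@analyticCovariance@values
  resid <- tr@trueJacobian %*% C + C %*% t(tr@trueJacobian) +
    2 * tr@trueFluctuation
  expect_lt(norm(resid, "F"), 1e-10 * (1 + norm(C, "F")))
  expect_true(all(tr@trueElasticities[!elasticityPattern(net)] == 0))
  tr2 <- makeGroundTruth(net, seed = 42)
  expect_identical(tr@trueElasticities, tr2@trueElasticities)
})

test_that("single-metabolite OU variance matches D/theta", {
  tr <- makeGroundTruth(oneMetNetwork(), seed = 3)
  theta <- -tr@trueJacobian[1, 1]
  D <- tr@trueFluctuation[1, 1]
  p <- simulateOU(tr, nSamples = 100000, dt = 0.04 / theta, thinning = 1,
                  burnIn = 1000, seed = 1)
  v <- var(profileValues(p)[, 1])
  expect_lt(abs(v - D / theta) / (D / theta), 0.05)
})

test_that("OU sample covariance approaches the analytic stationary covariance", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 5)
  p <- simulateOU(tr, nSamples = 10000, thinning = 40, seed = 2)
  C <- tr@analyticCovariance@values
  err <- norm(as.matrix(sampleCovariance(p)) - C, "F") / norm(C, "F")
  expect_lte(err, 0.1)
})

test_that("the forward solution equals the exact-discretization stationary covariance", {
  skip_if_not_installed("pracma")
  set.seed(61)
  for (i in 1:3) {
    n <- sample(3:6, 1)
    net <- randomNetwork(n)
    tr <- makeGroundTruth(net, seed = 70 + i)
    J <- tr@trueJacobian; F2 <- 2 * tr@trueFluctuation
    dtv <- 0.3
    Phi <- pracma::expm(J * dtv)
    ss <- seq(0, dtv, length.out = 4001); h <- ss[2] - ss[1]
    Q <- matrix(0, n, n)
    for (k in seq_along(ss)) {
      w <- if (k == 1 || k == length(ss)) 0.5 else 1
      Es <- pracma::expm(J * ss[k])
      Q <- Q + w * h * (Es %*% F2 %*% t(Es))
    }
    Cd <- matrix(solve(diag(n * n) - Phi %x% Phi, as.numeric(Q)), n, n)
    expect_lt(max(abs(Cd - tr@analyticCovariance@values)), 1e-6)
  }
})

test_that("simulation guards and output contracts hold", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 7)
  maxev <- max(Mod(eigen(tr@trueJacobian, only.values = TRUE)$values))
  expect_error(simulateOU(tr, nSamples = 10, dt = 0.2 / maxev, seed = 1),
               "dt too large")
  p <- simulateOU(tr, nSamples = 50, seed = 1)
  expect_true(all(profileValues(p) > 0))
  expect_identical(metaboliteIds(p), metaboliteIds(net))
  # byte determinism
  p2 <- simulateOU(tr, nSamples = 50, seed = 1)
  expect_identical(profileValues(p), profileValues(p2))
})

test_that("perturbation only rewrites the affected reaction's couplings", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 9)
  expect_equal(perturbCondition(tr, "GDH", "KGA", 1)@trueJacobian,
               tr@trueJacobian)
  trp <- perturbCondition(tr, "GDH", "KGA", 0.3)
  dJ <- trp@trueJacobian - tr@trueJacobian
  changed <- which(abs(dJ) > 1e-12, arr.ind = TRUE)
  expect_true(all(colnames(dJ)[changed[, 2]] == "KGA"))
  expect_setequal(rownames(dJ)[changed[, 1]], c("KGA", "NADH", "Glu", "NAD"))
  # recompute by brute force from the perturbed elasticities
  expect_equal(trp@trueJacobian, stoichiometry(net) %*% trp@trueElasticities,
               ignore_attr = "dimnames")
  expect_error(perturbCondition(tr, "PGin", "3PG", 0.5), "not on the pattern")
  expect_error(perturbCondition(tr, "nope", "3PG", 0.5), "unknown reaction")
})

test_that("two-condition datasets are labeled, disjointly seeded and truth-tagged", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 11)
  dat <- generateTwoConditionDataset(tr, "GDH", "KGA", 0.3, nSamples = 30,
                                     seed = 13)
  lab <- sampleConditions(dat$profiles)
  expect_equal(table(lab)[["control"]], 30)
  expect_equal(table(lab)[["perturbed"]], 30)
  Xc <- profileValues(subsetCondition(dat$profiles, "control"))
  Xp <- profileValues(subsetCondition(dat$profiles, "perturbed"))
  expect_false(identical(unname(Xc), unname(Xp)))
  # factor = 1 keeps the analytic covariances identical
  dat1 <- generateTwoConditionDataset(tr, "GDH", "KGA", 1, nSamples = 5, seed = 3)
  expect_equal(dat1$truthControl@analyticCovariance@values,
               dat1$truthPerturbed@analyticCovariance@values)
})

test_that("the padded panel network keeps the pathway and adds independent bystanders", {
  net <- panelNetwork(40)
  expect_equal(nrow(net@metabolites), 40L)
  mask <- jacobianSparsity(net)
  expect_true(mask["NADH", "KGA"])
  expect_false(any(mask["B01", setdiff(colnames(mask), "B01")]))
  tr <- makeGroundTruth(net, seed = 2)
  expect_true(stabilityReport(tr@trueJacobian)$stable)
})

test_that("intensity panels are positive, labeled, and deterministic", {
  p <- simulateIntensityPanel(seed = 4)
  expect_equal(dim(profileValues(p)), c(12L, 40L))
  expect_true(all(profileValues(p) > 0))
  expect_length(S4Vectors::metadata(p)$trueEffects, 3L)
  expect_identical(profileValues(p), profileValues(simulateIntensityPanel(seed = 4)))
})
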