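test_that("PCA explains all variance with full components and matches the SVD oracle", {
  p <- simulateIntensityPanel(nMetabolites = 6, nPerClass = 5, seed = 3)
  m <- fitPCA(p, nComponents = 6)
  expect_equal(tail(m@r2xCum, 1), 1, tolerance = 1e-10)

  # loadings match an eigen-decomposition of the scaled data, up to sign
  Xs <- profileValues(paretoScale(p))
  eg <- eigen(crossprod(Xs))
  m3 <- fitPCA(p, nComponents = 3)
  for (a in 1:3)
    expect_equal(abs(sum(m3@xLoadings[, a] * eg$vectors[, a])), 1,
                 tolerance = 1e-8)
  expect_equal(m3@r2xCum, cumsum(eg$values / sum(eg$values))[1:3],
               tolerance = 1e-10)
})

test_that("PCA handles exact low-rank data and rejects degenerate input", {
  t_ <- seq(-1, 1, length.out = 8)
  X <- cbind(M1 = 5 + 2 * t_, M2 = 3 - t_, M3 = 1 + 0.5 * t_)
  p <- MetaboliteProfiles(X, rep("c", 8))
  m <- fitPCA(p, nComponents = 2, scaling = "none")
  expect_equal(m@r2xCum[1], 1, tolerance = 1e-10)

  pid <- MetaboliteProfiles(matrix(3, 4, 2, dimnames = list(NULL, c("a", "b"))),
                            rep("c", 4))
  expect_error(fitPCA(pid, 1), "degenerate|zero-variance")
  expect_error(fitPCA(p, 10), "nComponents")
})

test_that("PLS-DA reaches R2Y = 1 when the response sits in a single metabolite", {
  set.seed(9)
  y <- rep(c(-1, 1), each = 5)
  noise <- matrix(rnorm(30), 10, 3)
  noise <- noise - y %*% t(crossprod(noise, y)) / sum(y^2)  # orthogonal to y
  X <- cbind(M1 = 10 + y, M2 = 20 + noise[, 1], M3 = 30 + noise[, 2])
  p <- MetaboliteProfiles(X, ifelse(y > 0, "b", "a"))
  m <- fitPLSDA(p, nComponents = 1, scaling = "none")
  expect_equal(tail(m@r2yCum, 1), 1, tolerance = 1e-8)
})

test_that("successive PLS component scores are orthogonal", {
  p <- simulateIntensityPanel(nMetabolites = 12, nPerClass = 8, nEffects = 2,
                              seed = 5)
  m <- fitPLSDA(p, nComponents = 3)
  G <- crossprod(m@scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8 * max(diag(G)))
})

test_that("clearly separable classes give a high cross-validated Q2", {
  set.seed(12)
  n <- 20
  shift <- rep(c(0, 2), each = n)
  X <- cbind(M1 = 100 + 10 * (rnorm(2 * n) + shift),
             matrix(rnorm(2 * n * 5, 50, 5), 2 * n, 5,
                    dimnames = list(NULL, paste0("N", 1:5))))
  p <- MetaboliteProfiles(X, rep(c("ctrl", "ko"), each = n))
  m <- fitPLSDA(p, nComponents = 2)
  expect_gt(tail(m@q2Cum, 1), 0.5)
})

test_that("first-component scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  p <- simulateIntensityPanel(nMetabolites = 15, nPerClass = 8, nEffects = 4,
                              effectSize = 3, seed = 3)
  m <- fitPLSDA(p, nComponents = 1)
  Xs <- profileValues(paretoScale(p))
  mm <- mixOmics::plsda(Xs, factor(sampleConditions(p)), ncomp = 1, scale = FALSE)
  expect_gt(abs(cor(m@scores[, 1], mm$variates$X[, 1])), 1 - 1e-8)
  expect_gt(abs(cor(vipScores(m), as.numeric(mixOmics::vip(mm)))), 1 - 1e-8)
})

test_that("OPLS-DA with no orthogonal components reduces to 1-component PLS-DA", {
  p <- simulateIntensityPanel(nMetabolites = 10, nPerClass = 6, seed = 7)
  mo <- fitOPLSDA(p, nOrthogonal = 0)
  mp <- fitPLSDA(p, nComponents = 1)
  expect_equal(mo@scores[, 1], mp@scores[, 1], tolerance = 1e-10)
  expect_equal(mo@r2yCum, mp@r2yCum, tolerance = 1e-10)
  expect_equal(vipScores(mo), vipScores(mp), tolerance = 1e-10)
})

test_that("OPLS-DA orthogonal components are uncorrelated with the response and the predictive score", {
  p <- simulateIntensityPanel(nMetabolites = 12, nPerClass = 8, nEffects = 3,
                              seed = 8)
  cl <- ifelse(sampleConditions(p) == "case", 1, -1)
  m <- fitOPLSDA(p, nOrthogonal = 2)
  for (a in seq_len(ncol(m@orthoScores))) {
    expect_lt(abs(cov(m@orthoScores[, a], cl)), 1e-8 * sd(m@orthoScores[, a]))
    expect_lt(abs(cor(m@orthoScores[, a], m@scores[, 1])), 1e-8)
  }
})

test_that("removing a structured nuisance direction does not hurt prediction", {
  set.seed(21)
  n <- 12
  y <- rep(c(-1, 1), each = n)
  nuis <- rnorm(2 * n, sd = 4)                # strong label-orthogonal factor
  nuis <- nuis - y * sum(nuis * y) / sum(y^2)
  X <- sapply(1:10, function(j) 50 + y * 1.5 + nuis * rnorm(1) + rnorm(2 * n))
  colnames(X) <- paste0("M", 1:10)
  p <- MetaboliteProfiles(X - min(X) + 1, ifelse(y > 0, "b", "a"))
  q2o <- tail(fitOPLSDA(p, nOrthogonal = 1, cvSeed = 2)@q2Cum, 1)
  q2p <- tail(fitPLSDA(p, nComponents = 1, cvSeed = 2)@q2Cum, 1)
  expect_gte(q2o, q2p - 0.05)
})

test_that("VIP scores are normalized and flag the discriminating metabolite", {
  # equal weights force every VIP to 1
  set.seed(30)
  y <- rep(c(-1, 1), 6)
  X <- cbind(M1 = 10 + y + rnorm(12, sd = 1e-6), M2 = 20 + y + rnorm(12, sd = 1e-6))
  m1 <- fitPLSDA(MetaboliteProfiles(X, ifelse(y > 0, "b", "a")),
                 nComponents = 1, scaling = "none")
  expect_equal(unname(vipScores(m1)), c(1, 1), tolerance = 1e-3)

  maxed <- sapply(1:10, function(s) {
    p <- simulateIntensityPanel(nMetabolites = 20, nPerClass = 12, nEffects = 1,
                                effectSize = 3, seed = 400 + s)
    v <- vipScores(fitOPLSDA(p))
    eff <- S4Vectors::metadata(p)$trueEffects
    v[eff] > 1 && names(which.max(v)) == eff
  })
  expect_gte(sum(maxed), 9)
})

test_that("squared VIP scores sum to the metabolite count for every fitted model", {
  for (s in 1:5) {
    p <- simulateIntensityPanel(nMetabolites = 8 + s, nPerClass = 5,
                                nEffects = 2, seed = s)
    for (m in list(fitPLSDA(p, nComponents = 2), fitOPLSDA(p)))
      expect_equal(sum(vipScores(m)^2), 8 + s, tolerance = 1e-8)
  }
  expect_error(vipScores(fitPCA(simulateIntensityPanel(seed = 1), 2)),
               "undefined for PCA")
})
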