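test_that("fluctuation draws are reproducible, positive, and median-centered on the base", {
  m <- FluctuationModel(c(1, 2), spread = 0, seed = 5)
  expect_equal(sampleFluctuation(m, 2, 1), diag(c(1, 2)))
  expect_equal(sampleFluctuation(m, 2, 99), diag(c(1, 2)))

  m2 <- FluctuationModel(1, spread = 0.2, seed = 5)
  d1 <- sampleFluctuation(m2, 4, 7)
  expect_identical(d1, sampleFluctuation(m2, 4, 7))
  expect_false(identical(d1, sampleFluctuation(m2, 4, 8)))
  expect_true(all(diag(d1) > 0))

  # log-normal draws: sample median of each entry within 2% of the base
  draws <- vapply(1:10000, function(i) diag(sampleFluctuation(m2, 2, i)),
                  numeric(2))
  expect_lt(max(abs(apply(draws, 1, median) - 1)), 0.02)
})

test_that("one-metabolite self-regulation inverts exactly", {
  net <- MetabolicNetwork(list(list(id = "r", substrates = c(X = 1),
                                    products = c())))
  J <- invertOnce(CovarianceMatrix(matrix(1, dimnames = list("X", "X")), 2),
                  matrix(1), net, ridge = 0)
  expect_equal(unname(J), matrix(-1), ignore_attr = TRUE)
})

test_that("forward-inverse round trip recovers the true Jacobian on the serine network", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 42)
  Jhat <- invertOnce(tr@analyticCovariance, tr@trueFluctuation, net, ridge = 0)
  expect_lt(norm(Jhat - tr@trueJacobian, "F") / norm(tr@trueJacobian, "F"), 1e-8)
  # direct mode solves the same consistent system on the structural mask
  Jd <- invertOnce(tr@analyticCovariance, tr@trueFluctuation, net, ridge = 0,
                   mode = "direct")
  C <- tr@analyticCovariance@values
  residD <- Jd %*% C + C %*% t(Jd) + 2 * tr@trueFluctuation
  expect_lt(norm(residD, "F") / norm(2 * tr@trueFluctuation, "F"), 1e-8)
})

test_that("round trip holds across random determinate networks", {
  set.seed(202)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    nt <- randomDeterminateTruth(n, seed = 300 + 50 * i)
    tr <- nt$truth
    Jhat <- invertOnce(tr@analyticCovariance, tr@trueFluctuation, nt$net,
                       ridge = 0)
    expect_lt(norm(Jhat - tr@trueJacobian, "F") / norm(tr@trueJacobian, "F"), 1e-8)
  }
})

test_that("under-determined systems warn and still satisfy the Lyapunov residual", {
  ids <- paste0("M", 1:5)
  rx <- lapply(1:5, function(i)
    list(id = paste0("r", i), substrates = setNames(1, ids[i]), products = c(),
         modifiers = ids[-i]))
  net <- MetabolicNetwork(rx)                 # 25 unknowns, 15 equations
  J0 <- randomStableJacobian(5)
  F0 <- diag(5)
  C <- as.matrix(solveLyapunov(J0, F0))
  expect_warning(Jhat <- invertOnce(CovarianceMatrix(C, 2), F0, net, ridge = 0),
                 "under-determined")
  resid <- Jhat %*% C + C %*% t(Jhat) + 2 * F0
  expect_lt(norm(resid, "F") / norm(2 * F0, "F"), 1e-8)
})

test_that("joint rescaling of covariance and fluctuation leaves the solution unchanged", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 8)
  C <- tr@analyticCovariance
  J1 <- invertOnce(C, tr@trueFluctuation, net, ridge = 0)
  J2 <- invertOnce(CovarianceMatrix(3.7 * C@values, 2), 3.7 * tr@trueFluctuation,
                   net, ridge = 0)
  expect_equal(J2, J1, tolerance = 1e-9)
})

test_that("ensemble draws are exactly zero off the mask and sign-consistent with truth", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 42)
  flu <- FluctuationModel(diag(tr@trueFluctuation), spread = 0.2, seed = 9)
  ens <- ensembleInvert(inverseProblem(tr@analyticCovariance, net, flu,
                                       nDraws = 200, ridge = 0), "ctrl")
  off <- !sparsityMask(ens)
  for (d in seq_len(dim(ens@draws)[3]))
    expect_true(all(ens@draws[, , d][off] == 0))
  truthNZ <- tr@trueJacobian != 0
  expect_true(all(sign(medianJacobian(ens)[truthNZ]) ==
                  sign(tr@trueJacobian[truthNZ])))
})

test_that("zero spread collapses the ensemble; equal seeds are bit-identical", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 3)
  flu0 <- FluctuationModel(diag(tr@trueFluctuation), spread = 0, seed = 1)
  prob <- inverseProblem(tr@analyticCovariance, net, flu0, nDraws = 25, ridge = 0)
  ens <- ensembleInvert(prob, "a")
  expect_equal(max(iqrJacobian(ens)), 0)
  expect_equal(ens@draws[, , 1], ens@draws[, , 25])

  flu1 <- FluctuationModel(diag(tr@trueFluctuation), spread = 0.3, seed = 77)
  e1 <- ensembleInvert(inverseProblem(tr@analyticCovariance, net, flu1,
                                      nDraws = 50), "a")
  e2 <- ensembleInvert(inverseProblem(tr@analyticCovariance, net, flu1,
                                      nDraws = 50), "a")
  expect_identical(e1@draws, e2@draws)
  expect_identical(e1@median, e2@median)
})

test_that("median recovered elasticities converge to truth as samples grow", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 42)
  et <- trueFreeElasticities(tr)
  cors <- sapply(c(100, 1000), function(N) {
    p <- simulateOU(tr, nSamples = N, seed = 7)
    flu <- FluctuationModel(diag(tr@trueFluctuation), spread = 0.2, seed = 11)
    ens <- ensembleInvert(inverseProblem(sampleCovariance(p), net, flu,
                                         nDraws = 300, ridge = 0), "c")
    cor(ens@elasticityMedian, et)
  })
  expect_gt(cors[2], cors[1] - 0.02)   # no degradation with more data
  expect_gt(cors[2], 0.9)
})

test_that("mismatched inputs are rejected", {
  net <- serineNetwork()
  tr <- makeGroundTruth(net, seed = 1)
  expect_error(invertOnce(CovarianceMatrix(diag(3), 2), diag(3), net),
               "dimension mismatch")
  C <- tr@analyticCovariance@values[9:1, 9:1]
  expect_error(invertOnce(CovarianceMatrix(C, 2), tr@trueFluctuation, net),
               "order")
})
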