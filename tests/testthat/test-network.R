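test_that("reaction-list parsing builds the stoichiometric matrix with the forced sign convention", {
  f <- writeTempNetwork(c("r1 : A -> B", "r2 : B -> C"))
  net <- readNetwork(f)
  expect_identical(metaboliteIds(net), c("A", "B", "C"))
  S <- stoichiometry(net)
  expect_equal(unname(S), matrix(c(-1, 1, 0, 0, -1, 1), 3, 2))

  # coefficients, comments, modifiers, cofactor directive, blank lines
  f2 <- writeTempNetwork(c("# a comment", "cofactors: N", "",
                           "rx : 2 A + N -> B | modifiers: C",
                           "deg : C ->"))
  net2 <- readNetwork(f2)
  expect_equal(stoichiometry(net2)["A", "rx"], -2)
  expect_true(elasticityPattern(net2)["rx", "C"])   # modifier elasticity
  expect_false(elasticityPattern(net2)["rx", "B"])  # product off by default
  expect_true(net2@metabolites$is_cofactor[net2@metabolites$id == "N"])
  net2p <- readNetwork(f2, productElasticities = TRUE)
  expect_true(elasticityPattern(net2p)["rx", "B"])
})

test_that("parse and validation errors carry location/context", {
  expect_error(readNetwork(writeTempNetwork(c("# only a comment"))), "no reactions")
  expect_error(readNetwork(writeTempNetwork("r1 : A - B")), "line 1")
  expect_error(readNetwork(writeTempNetwork(c("r1 : A -> B", "r1 : B -> C"))),
               "duplicate reaction id")
  expect_error(readNetwork(writeTempNetwork("r1 : 2 2 A -> B")), "term")
  # a metabolite may not sit on both sides of one reaction
  expect_error(MetabolicNetwork(list(list(id = "r", substrates = c(A = 1),
                                          products = c(A = 1)))),
               "both sides")
})

test_that("packaged serine-pathway file matches the pathway chemistry", {
  net <- readNetwork(serineFixturePath())
  expect_equal(nrow(net@metabolites), 9L)
  expect_length(net@reactions, 4L)
  S <- stoichiometry(net)
  expect_equal(S[c("3PG", "NAD", "3PHP", "NADH"), "PHGDH"], c(`3PG` = -1, NAD = -1,
                                                              `3PHP` = 1, NADH = 1))
  expect_equal(S["KGA", "PSAT1"], 1)
  expect_setequal(reactionIds(net), c("PHGDH", "PSAT1", "PSPH", "SRR"))
})

test_that("network round-trips through the text format unchanged", {
  for (net in list(readNetwork(serineFixturePath()), serineNetwork(),
                   randomNetwork(5, seed = 11))) {
    f <- withr::local_tempfile(fileext = ".txt")
    writeNetwork(net, f)
    net2 <- readNetwork(f)
    expect_equal(net2@metabolites, net@metabolites)
    expect_equal(stoichiometry(net2), stoichiometry(net))
    expect_equal(elasticityPattern(net2), elasticityPattern(net))
  }
})

test_that("stoichiometry columns balance products minus substrates", {
  net <- serineNetwork()
  S <- stoichiometry(net)
  for (k in seq_along(net@reactions)) {
    rx <- net@reactions[[k]]
    expect_equal(sum(S[, k]), sum(rx$products) - sum(rx$substrates))
  }
})

test_that("jacobianSparsity equals the brute-force symbolic product mask", {
  net1 <- MetabolicNetwork(list(list(id = "r", substrates = c(X = 1), products = c())))
  expect_equal(unname(jacobianSparsity(net1)), matrix(TRUE, 1, 1))

  net <- readNetwork(writeTempNetwork(c("r1 : A -> B", "r2 : B -> C")))
  mask <- suppressWarnings(jacobianSparsity(net))
  S <- stoichiometry(net); P <- elasticityPattern(net)
  brute <- matrix(FALSE, 3, 3)
  for (i in 1:3) for (j in 1:3) for (k in 1:2)
    if (S[i, k] != 0 && P[k, j]) brute[i, j] <- TRUE
  expect_equal(unname(mask), brute)
  # a metabolite touched only by a zero-elasticity reaction has an
  # all-false row: no stable self-dynamics, flagged for downstream
  net0 <- readNetwork(writeTempNetwork(c("r1 : A -> B", "r2 : -> C")))
  expect_warning(jacobianSparsity(net0), "all-false")
})

test_that("adding a modifier never removes a true sparsity entry", {
  rx <- list(list(id = "r1", substrates = c(A = 1), products = c(B = 1)),
             list(id = "r2", substrates = c(B = 1), products = c()))
  m0 <- suppressWarnings(jacobianSparsity(MetabolicNetwork(rx)))
  rx[[1]]$modifiers <- "B"
  m1 <- suppressWarnings(jacobianSparsity(MetabolicNetwork(rx)))
  expect_true(all(m1[m0]))
  expect_true(sum(m1) > sum(m0))
})

test_that("free-parameter counting and determinacy labels", {
  net <- readNetwork(writeTempNetwork(c("r1 : A -> B", "r2 : B -> C")))
  cp <- countFreeParameters(net)
  expect_equal(cp$equations, 6L)
  expect_equal(cp$free, 2L)
  expect_equal(cp$determinacy, "over-determined")

  # hand enumeration for the closed serine network: one elasticity per
  # substrate occurrence across the 13 reactions
  cps <- countFreeParameters(serineNetwork())
  expect_equal(cps$free, 13L)
  expect_equal(cps$equations, 45L)

  # all-true pattern, 5 metabolites: 25 unknowns > 15 equations
  ids <- paste0("M", 1:5)
  rx <- lapply(1:5, function(i)
    list(id = paste0("r", i), substrates = setNames(1, ids[i]), products = c(),
         modifiers = ids[-i]))
  cpu <- countFreeParameters(MetabolicNetwork(rx))
  expect_equal(cpu$free, 25L)
  expect_equal(cpu$determinacy, "under-determined")
})
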