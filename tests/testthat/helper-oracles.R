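# Independent oracles and small fixture builders used across the suite.

# Brute-force Lyapunov solve through the vectorized n^2 x n^2 linear system
# (independent of the package's eigen-decomposition solver).
kronLyapunov <- function(J, F) {
  n <- nrow(J)
  matrix(solve(diag(n) %x% J + J %x% diag(n), as.numeric(-2 * F)), n, n)
}

# Random Hurwitz-stable Jacobian: random matrix shifted left of the
# imaginary axis by a margin.
randomStableJacobian <- function(n, margin = 0.5) {
  A <- matrix(rnorm(n * n), n, n)
  A - diag(max(Re(eigen(A, only.values = TRUE)$values)) + margin, n)
}

# Random determinate reaction network: every metabolite has a first-order
# degradation, plus random conversion reactions; free elasticities = 2n,
# always <= n(n+1)/2 equations for n >= 3.
randomNetwork <- function(n, nConv = n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("M", seq_len(n))
  rx <- lapply(seq_len(n), function(i)
    list(id = paste0("dg", i), substrates = setNames(1, ids[i]), products = c()))
  pairs <- expand.grid(a = seq_len(n), b = seq_len(n))
  pairs <- pairs[pairs$a != pairs$b, ]
  pick <- pairs[sample.int(nrow(pairs), min(nConv, nrow(pairs))), ]
  for (k in seq_len(nrow(pick))) {
    rx[[length(rx) + 1]] <- list(id = paste0("cv", k),
                                 substrates = setNames(1, ids[pick$a[k]]),
                                 products = setNames(1, ids[pick$b[k]]))
  }
  MetabolicNetwork(rx)
}

writeTempNetwork <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

serineFixturePath <- function() {
  system.file("extdata", "serine_pathway.txt", package = "metarecon")
}

# double-loop covariance oracle
bruteCovariance <- function(X) {
  n <- nrow(X); m <- ncol(X)
  ctr <- colMeans(X)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    V[i, j] <- sum((X[, i] - ctr[i]) * (X[, j] - ctr[j])) / (n - 1)
  V
}

# Random determinate network + truth: resamples until the inverse problem
# has full column rank at the truth's analytic covariance (the determinacy
# precondition of the round-trip property).
randomDeterminateTruth <- function(n, seed) {
  for (k in 0:20) {
    net <- randomNetwork(n, seed = seed + 31 * k)
    tr <- makeGroundTruth(net, seed = seed + 31 * k + 1)
    X <- metarecon:::.buildDesign(tr@analyticCovariance@values, net,
                                  "elasticity")$X
    sv <- svd(X)$d
    if (min(sv) > 1e-8 * max(sv)) return(list(net = net, truth = tr))
  }
  stop("no determinate random network found")
}

# tiny one-metabolite network (self-degradation plus inflow)
oneMetNetwork <- function() {
  MetabolicNetwork(list(
    list(id = "deg", substrates = c(X = 1), products = c()),
    list(id = "in", substrates = c(), products = c(X = 1))))
}
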