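test_that("model labels parse to the right specs and back", {
  sp <- parseModelSpec("mtmam+F+G")
  expect_identical(sp@family, "mtmam")
  expect_true(sp@plusF && sp@plusGamma)
  expect_identical(modelLabel(sp), "mtmam+F+G")
  expect_identical(modelAlphabet(sp), "AA")
  expect_identical(modelLabel(parseModelSpec("K80+G")), "K80+G")
  expect_error(parseModelSpec("WAG"), "unknown model family")
  expect_error(modelSpec("GTR", plusF = TRUE), "protein")
})

test_that("nested nucleotide models collapse onto JC", {
  jc <- buildRateMatrix(modelSpec("JC"))
  expect_equal(unname(jc@Q[1, 2]), 1 / 3, tolerance = 1e-12)
  k80 <- buildRateMatrix(modelSpec("K80"), kappa = 1)
  expect_equal(k80@Q, jc@Q, tolerance = 1e-12)
  gtr <- buildRateMatrix(modelSpec("GTR"), freqs = rep(0.25, 4),
                         gtrRates = rep(1, 5))
  expect_equal(gtr@Q, jc@Q, tolerance = 1e-12)
})

test_that("every built rate matrix satisfies the reversibility invariants", {
  set.seed(404)
  specs <- list(
    list(spec = modelSpec("JC")),
    list(spec = modelSpec("K80"), kappa = 4),
    list(spec = modelSpec("Poisson")),
    list(spec = modelSpec("JTT")),
    list(spec = modelSpec("mtmam")))
  for (r in 1:5) {
    f <- rgamma(4, 1) + 0.05; f <- f / sum(f)
    specs <- c(specs, list(list(spec = modelSpec("GTR"), freqs = f,
                                gtrRates = rgamma(5, 2))),
               list(list(spec = modelSpec("HKY"), freqs = f,
                         kappa = rgamma(1, 2) + 0.1)))
  }
  for (args in specs) {
    rm1 <- do.call(buildRateMatrix, args)
    Q <- rm1@Q; pi <- rm1@pi
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12)   # detailed balance
    expect_lt(abs(-sum(pi * diag(Q)) - 1), 1e-12)    # normalization
    expect_lt(max(abs(pi %*% Q)), 1e-12)             # stationarity
  }
})

test_that("frequency validation rejects bad vectors", {
  expect_error(buildRateMatrix(modelSpec("GTR"), freqs = c(0.5, 0.5, 0, 0)),
               "strictly positive")
  expect_error(buildRateMatrix(modelSpec("GTR"), freqs = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(buildRateMatrix(modelSpec("JTT", plusF = TRUE),
                               freqs = c(0.9, rep(0, 19)) + c(0, rep(0.1 / 19, 19)) * 0),
               "pseudocount")
})

test_that("transition probabilities behave like a CTMC", {
  set.seed(505)
  f <- c(0.4, 0.3, 0.2, 0.1)
  rm1 <- buildRateMatrix(modelSpec("GTR"), freqs = f, gtrRates = rgamma(5, 2))
  expect_equal(transitionProbabilities(rm1, 0), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  Pbig <- transitionProbabilities(rm1, 1e6)
  for (i in 1:4) expect_equal(unname(Pbig[i, ]), f, tolerance = 1e-9)
  # Chapman-Kolmogorov on random models
  for (r in 1:5) {
    fr <- rgamma(4, 1) + 0.05; fr <- fr / sum(fr)
    rmr <- buildRateMatrix(modelSpec("GTR"), freqs = fr, gtrRates = rgamma(5, 2))
    s <- runif(1, 0, 2); t <- runif(1, 0, 2)
    expect_equal(transitionProbabilities(rmr, s) %*% transitionProbabilities(rmr, t),
                 transitionProbabilities(rmr, s + t), tolerance = 1e-10)
  }
  expect_error(transitionProbabilities(rm1, -0.1), ">= 0")
})

test_that("JC transition probabilities match the closed form", {
  rm1 <- buildRateMatrix(modelSpec("JC"))
  for (t in c(0, 0.01, 0.1, 0.5, 1, 5)) {
    expect_equal(transitionProbabilities(rm1, t), jcTransitionProb(t),
                 tolerance = 1e-10)
  }
})

test_that("gamma discretization matches quadrature and limits", {
  expect_identical(discretizeGamma(3.7, 1)@rates, 1)
  hi <- discretizeGamma(1e4, 4)
  expect_true(all(abs(hi@rates - 1) < 0.05))
  for (alpha in c(0.2, 0.5, 1, 3)) {
    g <- discretizeGamma(alpha, 4)
    expect_equal(g@rates, gammaCategoryMeansQuadrature(alpha, 4),
                 tolerance = 1e-7)
    expect_equal(sum(g@rates * g@weights), 1, tolerance = 1e-12)
    expect_false(is.unsorted(g@rates))
  }
  expect_error(discretizeGamma(-1, 4), "> 0")
})

test_that("free-parameter counting follows the stated convention", {
  expect_identical(countFreeParameters(modelSpec("JC"), 3), 3L)
  expect_identical(countFreeParameters(parseModelSpec("GTR+G"), 9), 18L)
  expect_identical(countFreeParameters(modelSpec("mtmam"), 9), 9L)
  expect_identical(countFreeParameters(parseModelSpec("mtmam+F+G"), 9),
                   9L + 19L + 1L)
  expect_identical(countFreeParameters(parseModelSpec("HKY"), 5), 5L + 1L + 3L)
  # frequencies not counted under the alternative convention
  expect_identical(
    countFreeParameters(parseModelSpec("GTR+G", countFreqs = FALSE), 9),
    9L + 5L + 1L)
})

test_that("empirical amino-acid models are valid and stationary at their bf", {
  for (fam in c("JTT", "mtmam")) {
    rm1 <- buildRateMatrix(modelSpec(fam))
    expect_identical(rm1@alphabet, "AA")
    expect_equal(sum(rm1@pi), 1, tolerance = 1e-9)
    expect_lt(max(abs(rm1@pi %*% rm1@Q)), 1e-12)
  }
  # +F swaps in observed frequencies
  f <- rep(1 / 20, 20)
  rmF <- buildRateMatrix(modelSpec("mtmam", plusF = TRUE), freqs = f)
  expect_equal(unname(rmF@pi), f)
})
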