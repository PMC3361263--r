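test_that("pattern compression conserves columns and is invertible info", {
  aln <- ancestryAIC:::.newAlignment(
    matrix(c("A", "A", "A", "A",
             "A", "A", "A", "A"), 2, 4, byrow = TRUE,
           dimnames = list(c("a", "b"), NULL)), "DNA", provenance = "external")
  pat <- compressPatterns(aln)
  expect_identical(ncol(pat@states), 1L)
  expect_identical(pat@weights, 4)

  set.seed(77)
  big <- randomAlignment(paste0("t", 1:6), 100)
  pat2 <- compressPatterns(big)
  expect_identical(sum(pat2@weights), 100)
  # reconstructing columns recovers a permutation of the original
  rec <- pat2@states[, rep(seq_along(pat2@weights), pat2@weights)]
  orig <- matrix(match(alnChars(big), alphabetLetters("DNA")), 6, 100)
  expect_identical(sort(apply(rec, 2, paste, collapse = ",")),
                   sort(apply(orig, 2, paste, collapse = ",")))

  gappy <- ancestryAIC:::.newAlignment(
    matrix(c("A", "-", "A", "A"), 2, 2, dimnames = list(c("a", "b"), NULL)),
    "DNA", provenance = "external")
  expect_error(compressPatterns(gappy), "stripGapColumns")
})

test_that("pruning equals exhaustive internal-state enumeration", {
  set.seed(88)
  trees <- list(
    ape::read.tree(text = "(a:0.1,b:0.3,c:0.05);"),
    ape::read.tree(text = "((a:0.2,b:0.1):0.15,c:0.4,d:0.02);"),
    ape::read.tree(text = "((a:0.2,b:0.1):0.15,c:0.4,((d:0.3,e:0.1):0.2,f:0.25):0.12);"))
  jc <- buildRateMatrix(modelSpec("JC"))
  f <- c(0.35, 0.25, 0.15, 0.25)
  gtr <- buildRateMatrix(modelSpec("GTR"), freqs = f, gtrRates = rgamma(5, 2))
  g <- discretizeGamma(0.4, 4)
  for (tr in trees) {
    aln <- randomAlignment(tr$tip.label, 25)
    pat <- compressPatterns(aln)
    for (model in list(list(jc, NULL), list(gtr, NULL), list(gtr, g))) {
      expect_equal(logLikelihood(tr, pat, model[[1]], model[[2]]),
                   bruteForceLogLik(tr, pat, model[[1]], model[[2]]),
                   tolerance = 1e-9)
    }
  }
  # amino-acid models on smaller trees (enumeration is 20^nint)
  mt <- buildRateMatrix(modelSpec("mtmam"))
  for (tr in trees[1:2]) {
    aln <- randomAlignment(tr$tip.label, 10, alphabet = "AA")
    pat <- compressPatterns(aln)
    expect_equal(logLikelihood(tr, pat, mt, g),
                 bruteForceLogLik(tr, pat, mt, g), tolerance = 1e-9)
  }
})

test_that("two-tip JC likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(a:0.12,b:0.23);")
  jc <- buildRateMatrix(modelSpec("JC"))
  chars <- matrix(c("A", "A", "C", "A"), 2, 2,
                  dimnames = list(c("a", "b"), NULL))
  pat <- compressPatterns(ancestryAIC:::.newAlignment(chars, "DNA",
                                                      provenance = "external"))
  tt <- 0.12 + 0.23
  expected <- log(0.25 * jcTransitionProb(tt)["A", "A"]) +
    log(0.25 * jcTransitionProb(tt)["C", "A"])
  expect_equal(logLikelihood(tr, pat, jc), expected, tolerance = 1e-12)
})

test_that("likelihood is invariant to re-rooting and to compression", {
  set.seed(99)
  tr <- ape::read.tree(
    text = "((a:0.2,b:0.1):0.15,c:0.4,((d:0.3,e:0.1):0.2,f:0.25):0.12);")
  aln <- randomAlignment(tr$tip.label, 40)
  pat <- compressPatterns(aln)
  f <- c(0.3, 0.3, 0.2, 0.2)
  gtr <- buildRateMatrix(modelSpec("GTR"), freqs = f, gtrRates = rgamma(5, 2))
  g <- discretizeGamma(0.8, 4)
  base <- logLikelihood(tr, pat, gtr, g)
  for (node in c("a", "d", "f")) {
    rerooted <- ape::root(tr, outgroup = node, resolve.root = FALSE)
    expect_equal(logLikelihood(rerooted, pat, gtr, g), base, tolerance = 1e-9)
  }
  # pattern compression does not change the likelihood
  uncompressed <- pat
  uncompressed@states <- pat@states[, rep(seq_along(pat@weights), pat@weights)]
  uncompressed@weights <- rep(1, sum(pat@weights))
  expect_equal(logLikelihood(tr, uncompressed, gtr, g), base, tolerance = 1e-9)
})

test_that("identical sequences drive branch lengths to zero under JC", {
  chars <- matrix(rep(c("A", "C", "G", "T", "A"), each = 3), 3, 5,
                  dimnames = list(c("a", "b", "c"), NULL))
  aln <- ancestryAIC:::.newAlignment(chars, "DNA", provenance = "external")
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  fit <- maximizeLikelihood(tr, compressPatterns(aln), modelSpec("JC"))
  expect_true(all(unlist(estimates(fit)$edgeLengths) < 1e-4))
  # branch lengths sit at the optimizer's lower bound, not exactly 0
  expect_equal(fit@lnL, 5 * log(0.25), tolerance = 1e-5)
  expect_identical(fit@k, 3L)
})

test_that("ML recovers kappa within 5% from 1e5 simulated K80 sites", {
  tr <- familyTriple("g")
  k80 <- buildRateMatrix(modelSpec("K80"), kappa = 4)
  set.seed(12)
  fam <- simulateIndependent(nSites = 1e5, seed = 31, treeA = tr,
                             treeB = familyTriple("h"), rateMatrix = k80)$g
  chars <- do.call(rbind, strsplit(residues(fam), ""))
  rownames(chars) <- paste("g", taxa(fam), sep = "_")
  pat <- compressPatterns(ancestryAIC:::.newAlignment(chars, "DNA",
                                                      provenance = "external"))
  fit <- maximizeLikelihood(tr, pat, modelSpec("K80"))
  expect_lt(abs(estimates(fit)$kappa - 4) / 4, 0.05)
  # nesting: richer nucleotide models never fit worse
  fitJC <- maximizeLikelihood(tr, pat, modelSpec("JC"))
  fitHKY <- maximizeLikelihood(tr, pat, modelSpec("HKY"))
  fitGTR <- maximizeLikelihood(tr, pat, modelSpec("GTR"))
  expect_gte(fit@lnL, fitJC@lnL - 1e-4)
  expect_gte(fitHKY@lnL, fit@lnL - 1e-4)
  expect_gte(fitGTR@lnL, fitHKY@lnL - 1e-4)
})

test_that("alphabet mismatches are refused", {
  aln <- randomAlignment(c("a", "b", "c"), 10)
  pat <- compressPatterns(aln)
  mt <- buildRateMatrix(modelSpec("mtmam"))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  expect_error(logLikelihood(tr, pat, mt), "alphabet")
  expect_error(maximizeLikelihood(tr, pat, modelSpec("mtmam")), "alphabet")
})
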