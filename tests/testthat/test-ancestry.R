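makeFams <- function(seed = 17, nSites = 300) {
  simulateCommon(nSites = nSites, seed = seed,
                 tree = commonOriginTree(genes = c("cytb", "nd2")))
}

test_that("hypotheses have the right structure", {
  fams <- makeFams()
  hyps <- buildHypotheses(fams$cytb, fams$nd2)
  expect_identical(hyps$independent@name, "independent")
  expect_identical(sum(vapply(hyps$independent@trees,
                              function(tr) nrow(tr$edge), 1L)), 6L)
  expect_identical(nrow(hyps$common@trees[[1]]$edge), 9L)
  expect_setequal(hyps$common@trees[[1]]$tip.label,
                  c(paste0("cytb_", taxa(fams$cytb)),
                    paste0("nd2_", taxa(fams$nd2))))
  bad <- sequenceFamily("nd2", c(cow = "ACGT", deer = "ACGT"),
                        alphabet = "DNA")
  expect_error(buildHypotheses(fams$cytb, bad), "same 3 taxa")
})

test_that("aic is the exact formula", {
  expect_identical(aic(-100, 5), 210)
  expect_identical(aic(0, 0), 0)
  expect_equal(aic(-5169.2, 18), 10374.4)
})

test_that("JC nesting: common origin can only fit identical data better", {
  # with no free substitution parameters the independent fit is the
  # central-branch -> infinity boundary of the common fit
  fams <- simulateCommon(nSites = 300, seed = 23)
  aln <- unalignedPairing(fams$geneA, fams$geneB)
  hyps <- buildHypotheses(fams$geneA, fams$geneB)
  fi <- fitHypothesis(hyps$independent, aln, modelSpec("JC"))
  fc <- fitHypothesis(hyps$common, aln, modelSpec("JC"))
  expect_gte(fc@lnL, fi@lnL - 1e-3)
  expect_identical(fi@k, 6L)
  expect_identical(fc@k, 9L)
})

test_that("AIC decides for the true scenario on simulated data", {
  # common origin with a moderate central branch
  fams <- simulateCommon(nSites = 5000, seed = 41,
                         tree = commonOriginTree(centralBranch = 0.5))
  aln <- unalignedPairing(fams$geneA, fams$geneB)
  hyps <- buildHypotheses(fams$geneA, fams$geneB)
  fi <- fitHypothesis(hyps$independent, aln, modelSpec("JC"))
  fc <- fitHypothesis(hyps$common, aln, modelSpec("JC"))
  expect_lt(aicValue(fc), aicValue(fi))

  # independent families with uniform composition
  jc <- buildRateMatrix(modelSpec("JC"))
  fams2 <- simulateIndependent(nSites = 5000, seed = 43, rateMatrix = jc)
  aln2 <- unalignedPairing(fams2$geneA, fams2$geneB)
  fi2 <- fitHypothesis(hyps$independent, aln2, modelSpec("JC"))
  fc2 <- fitHypothesis(hyps$common, aln2, modelSpec("JC"))
  expect_lt(aicValue(fi2), aicValue(fc2))
})

test_that("homology statistic follows its definition", {
  # duplicated family: identity
  fam <- sequenceFamily("cytb", c(cow = "ACGTAC", deer = "ACGTTT",
                                  hippo = "AAGTAC"), alphabet = "DNA")
  fake <- sequenceFamily("nd2", residues(fam), alphabet = "DNA")
  expect_equal(homologyStat(list(fam, fake), pairing = "sameTaxon")$value, 1)

  pairA <- sequenceFamily("g1", c(x = "AAAA"), alphabet = "DNA")
  expect_equal(homologyStat(list(pairA, sequenceFamily("g2", c(x = "TTTT"),
                                                       alphabet = "DNA")))$value, 0)
  expect_equal(homologyStat(list(pairA, sequenceFamily("g2", c(x = "AATT"),
                                                       alphabet = "DNA")))$value, 0.5)

  # cross pairing averages over all 9 pairs; gapped columns are skipped per pair
  chars <- rbind(g1_a = c("A", "C", "G"), g1_b = c("A", "C", "G"),
                 g2_a = c("A", "-", "G"), g2_b = c("T", "C", "G"))
  aln <- ancestryAIC:::.newAlignment(chars, "DNA", provenance = "external")
  got <- homologyStat(aln)
  expect_equal(got$value, 1 - mean(c(0, 1 / 3, 0, 1 / 3)))
  expect_identical(homologyStat(aln, pairing = "sameTaxon")$pairing, "sameTaxon")
})

test_that("sweep produces consistent reports and TSV output", {
  fams <- simulateCommon(nSites = 400, seed = 59,
                         tree = commonOriginTree(genes = c("cytb", "nd2")))
  reports <- sweepGapPenalties(fams$cytb, fams$nd2,
                               specs = c("JC", "K80"),
                               grid = list(NULL, c(15, 6.66)),
                               control = list(tol = 1e-4))
  expect_length(reports, 2L)
  expect_match(reports[[1]]@label, "^No alignment \\(400 bp\\)$")
  expect_match(reports[[2]]@label, "GOP, GEP\\) = \\(15, 6.66\\)")
  for (rep in reports) {
    tab <- reportRows(rep)
    expect_identical(tab$model, c("JC", "K80"))
    ok <- ifelse(tab$aic_common < tab$aic_independent, "common", "independent")
    expect_identical(tab$preferred, ok)
    expect_equal(tab$delta_aic, tab$aic_independent - tab$aic_common)
    expect_true(rep@homology >= 0 && rep@homology <= 1)
  }
  tf <- withr::local_tempfile(fileext = ".tsv")
  reportTable(reports, tf)
  back <- utils::read.delim(tf)
  expect_identical(names(back),
                   c("dataset_label", "model", "aic_independent", "aic_common",
                     "preferred", "delta_aic", "homology"))
  expect_identical(nrow(back), 4L)
  expect_error(sweepGapPenalties(fams$cytb, fams$nd2, specs = list()),
               "at least one")
})

test_that("weaker gap penalties inflate homology between unrelated families", {
  fams <- simulateIndependent(nSites = 600, seed = 77,
                              composition = mtBiasComposition())
  seqs <- c(setNames(residues(fams$geneA), paste0("geneA_", taxa(fams$geneA))),
            setNames(residues(fams$geneB), paste0("geneB_", taxa(fams$geneB))))
  noaln <- homologyStat(unalignedPairing(fams$geneA, fams$geneB))$value
  hom <- sapply(list(c(100, 100), c(3, 6.66), c(1, 0.5)), function(p) {
    aln <- stripGapColumns(progressiveAlign(seqs, gop = p[1], gep = p[2]))
    homologyStat(aln)$value
  })
  # non-decreasing from no alignment through ever-weaker penalties
  expect_true(all(diff(c(noaln, hom)) >= -1e-12),
              label = paste("homology along weakening penalties:",
                            paste(round(c(noaln, hom), 3), collapse = " ")))
  expect_gt(hom[3], noaln)  # materially inflated at the weak end
})

test_that("shared composition bias induces false common-origin preference
           under frequency-blind models", {
  # JC cannot absorb composition into fitted frequencies, so the shared
  # codon-position bias masquerades as cross-family correlation
  ctl <- list(tol = 1e-4)
  hyps <- NULL
  deltas <- function(biased) sapply(1:6, function(seed) {
    fams <- if (biased)
      simulateIndependent(nSites = 1038, seed = seed,
                          composition = mtBiasComposition())
    else simulateIndependent(nSites = 1038, seed = seed)
    aln <- unalignedPairing(fams$geneA, fams$geneB)
    if (is.null(hyps)) hyps <<- buildHypotheses(fams$geneA, fams$geneB)
    fi <- fitHypothesis(hyps$independent, aln, modelSpec("JC"), control = ctl)
    fc <- fitHypothesis(hyps$common, aln, modelSpec("JC"), control = ctl)
    aicValue(fi) - aicValue(fc)
  })
  rateBiased <- mean(deltas(TRUE) > 0)
  rateUniform <- mean(deltas(FALSE) > 0)
  expect_gte(rateBiased - rateUniform, 0.25)
})

test_that("profile-vs-profile co-alignment is available in the sweep", {
  fams <- simulateIndependent(nSites = 200, seed = 91,
                              composition = mtBiasComposition())
  rep <- sweepGapPenalties(fams$geneA, fams$geneB, specs = "JC",
                           grid = list(c(15, 6.66)), alignMode = "profile",
                           control = list(tol = 1e-3))[[1]]
  tab <- reportRows(rep)
  expect_false(any(is.na(tab$aic_independent)))
  expect_identical(tab$preferred,
                   ifelse(tab$aic_common < tab$aic_independent,
                          "common", "independent"))
})
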