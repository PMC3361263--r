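## Sequence-evolution simulator: common-origin evolution along one 6-tip
## tree, or two independent 3-tip families with optional shared
## composition bias (mitochondrial-style codon-position bias for
## nucleotides, a shared global composition for amino acids).
##
## Reproducibility contract: a single seeded R generator drives all draws
## in a fixed order -- root sites first (site classes in index order),
## then child states edge by edge in the tree's cladewise edge order
## (family A entirely before family B in the independent scenario).

#' Default 3-taxon family tree ((cow, deer), hippo)
#'
#' An unrooted 3-tip star with the package's standard branch lengths
#' (cow 0.1, deer 0.05, hippo 0.15 expected substitutions per site).
#'
#' @param gene gene label used as tip-name prefix.
#' @param taxa the three taxon labels.
#' @param lens branch lengths for the three tips.
#' @return A `phylo` tree with tips `<gene>_<taxon>`.
#' @export
familyTriple <- function(gene = "geneA", taxa = c("cow", "deer", "hippo"),
                         lens = c(0.1, 0.05, 0.15)) {
  tips <- paste(gene, taxa, sep = "_")
  ape::read.tree(text = sprintf("(%s:%g,%s:%g,%s:%g);",
                                tips[1L], lens[1L], tips[2L], lens[2L],
                                tips[3L], lens[3L]))
}

#' Default 6-tip common-origin tree
#'
#' Two `((cow, deer), hippo)` family subtrees joined by a central branch:
#' the common-origin topology with 9 branches.
#'
#' @param genes the two gene labels.
#' @param taxa the three taxon labels.
#' @param centralBranch length of the branch connecting the two families.
#' @return A `phylo` tree with tips `<gene>_<taxon>`.
#' @export
commonOriginTree <- function(genes = c("geneA", "geneB"),
                             taxa = c("cow", "deer", "hippo"),
                             centralBranch = 0.5) {
  a <- paste(genes[1L], taxa, sep = "_")
  b <- paste(genes[2L], taxa, sep = "_")
  ape::read.tree(text = sprintf(
    "((%s:0.1,%s:0.05):0.05,%s:0.15,((%s:0.1,%s:0.05):0.05,%s:0.15):%g);",
    a[1L], a[2L], a[3L], b[1L], b[2L], b[3L], centralBranch))
}

#' Mitochondrial-style codon-position composition bias
#'
#' Three nucleotide frequency vectors, one per codon position: position 1
#' uniform, position 2 T-rich (T = 0.45), position 3 A-rich and G-poor
#' (A = 0.45, G = 0.04) -- the heavy-strand bias pattern of mammalian
#' mitochondrial protein-coding genes.
#'
#' @return List of three named frequency vectors (ACGT).
#' @export
mtBiasComposition <- function() {
  list(pos1 = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
       pos2 = c(A = 0.55 / 3, C = 0.55 / 3, G = 0.55 / 3, T = 0.45),
       pos3 = c(A = 0.45, C = 0.255, G = 0.04, T = 0.255))
}

#' Uniform codon-position composition (control)
#'
#' @return List of three uniform ACGT frequency vectors.
#' @export
uniformComposition <- function() {
  u <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  list(pos1 = u, pos2 = u, pos3 = u)
}

#' Expected chance identity of unrelated sequences
#'
#' The probability that two independent draws from frequency vectors
#' `freqsA` and `freqsB` coincide: `sum(freqsA * freqsB)`. This is the
#' expected no-alignment homology of unrelated site pairs.
#'
#' @param freqsA,freqsB frequency vectors over the same alphabet.
#' @return A single number in `[0, 1]`.
#' @examples
#' expectedRandomIdentity(rep(0.25, 4), rep(0.25, 4))  # 0.25
#' @export
expectedRandomIdentity <- function(freqsA, freqsB) {
  if (length(freqsA) != length(freqsB))
    stop("frequency vectors must have equal length")
  freqsA <- .checkFreqs(freqsA, length(freqsA))
  freqsB <- .checkFreqs(freqsB, length(freqsB))
  sum(freqsA * freqsB)
}

.checkComposition <- function(composition, s) {
  lapply(composition, function(f) .checkFreqs(f, s))
}

## Evolve states down one tree. rmList/rootFreqs are per site class;
## clsIdx assigns each site to a class; siteRates are per-site gamma
## rates (1 when no gamma).
.simulateTips <- function(tree, rmList, clsIdx, siteRates, rootFreqs) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  s <- length(rmList[[1L]]@pi)
  nSites <- length(clsIdx)
  states <- matrix(0L, nnode, nSites)
  root <- ntip + 1L
  for (ci in seq_along(rmList)) {
    idx <- which(clsIdx == ci)
    if (length(idx))
      states[root, idx] <- sample.int(s, length(idx), replace = TRUE,
                                      prob = rootFreqs[[ci]])
  }
  rateVals <- unique(siteRates)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    ch <- tree$edge[k, 2L]
    t <- tree$edge.length[k]
    out <- integer(nSites)
    for (ci in seq_along(rmList)) for (r in rateVals) {
      idx <- which(clsIdx == ci & siteRates == r)
      if (!length(idx)) next
      P <- transitionProbabilities(rmList[[ci]], t * r)
      ps <- states[p, idx]
      for (st in seq_len(s)) {
        ii <- idx[ps == st]
        if (length(ii))
          out[ii] <- sample.int(s, length(ii), replace = TRUE, prob = P[st, ])
      }
    }
    states[ch, ] <- out
  }
  letters_ok <- alphabetLetters(rmList[[1L]]@alphabet)
  tipSeqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                   function(v) paste(letters_ok[v], collapse = ""))
  setNames(tipSeqs, tree$tip.label)
}

.splitTipFamilies <- function(tipSeqs, alphabet) {
  genes <- sub("_.*$", "", names(tipSeqs))
  taxa <- sub("^[^_]*_", "", names(tipSeqs))
  out <- lapply(unique(genes), function(g) {
    sel <- genes == g
    sequenceFamily(g, setNames(tipSeqs[sel], taxa[sel]), alphabet = alphabet)
  })
  setNames(out, unique(genes))
}

.drawSiteRates <- function(gamma, nSites) {
  if (is.null(gamma)) return(rep(1, nSites))
  stopifnot(is(gamma, "GammaRates"))
  gamma@rates[sample.int(length(gamma@rates), nSites, replace = TRUE)]
}

#' Simulate a common-origin dataset
#'
#' Evolves one root sequence, drawn from the model's stationary
#' frequencies, down a 6-tip tree; the tips are split into two 3-taxon
#' families by their `<gene>_<taxon>` labels.
#'
#' @param nSites number of sites (default 1038, the standard
#'   mitochondrial window).
#' @param seed integer seed; fully determines the output.
#' @param tree a 6-tip `phylo` (default [commonOriginTree()]).
#' @param rateMatrix a [RateMatrix-class] (default JC).
#' @param gamma optional [GammaRates-class] for site-rate heterogeneity.
#' @return Named list of two [SequenceFamily-class] objects.
#' @export
simulateCommon <- function(nSites = 1038L, seed, tree = commonOriginTree(),
                           rateMatrix = buildRateMatrix(modelSpec("JC")),
                           gamma = NULL) {
  stopifnot(nSites >= 1L, inherits(tree, "phylo"))
  if (length(tree$tip.label) != 6L)
    stop("common-origin simulation needs a 6-tip tree")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative edge lengths")
  set.seed(seed)
  clsIdx <- rep(1L, nSites)
  siteRates <- .drawSiteRates(gamma, nSites)
  tips <- .simulateTips(tree, list(rateMatrix), clsIdx, siteRates,
                        list(rateMatrix@pi))
  fams <- .splitTipFamilies(tips, rateMatrix@alphabet)
  if (length(fams) != 2L)
    stop("tree tips must be named <gene>_<taxon> with exactly two genes")
  fams
}

#' Simulate two independently originated families
#'
#' Two root sequences are drawn independently -- from the generator's
#' stationary frequencies, or from shared composition-bias vectors when
#' `composition` is given -- and evolved within their own 3-tip trees.
#' No information flows between the families.
#'
#' For nucleotide data `composition` is a list of up to 3 frequency
#' vectors applied to interleaved codon-position site classes; each class
#' evolves under an HKY-style generator with those target frequencies
#' (shared by both families, emulating a genome-wide mutational bias).
#' For amino-acid data it is a single length-20 vector (shared
#' compositional convergence).
#'
#' @param nSites number of sites per family.
#' @param seed integer seed; fully determines the output.
#' @param treeA,treeB 3-tip `phylo` trees (default [familyTriple()] with
#'   genes `"geneA"`/`"geneB"`).
#' @param rateMatrix generator used when `composition` is `NULL`
#'   (default: HKY with uniform frequencies and `kappa`).
#' @param composition optional list of frequency vectors (see above).
#' @param kappa transition/transversion ratio of the HKY-style generator
#'   used for nucleotide site classes (default 8, a realistic
#'   mitochondrial value).
#' @param gamma optional [GammaRates-class].
#' @return Named list of two [SequenceFamily-class] objects.
#' @export
simulateIndependent <- function(nSites = 1038L, seed,
                                treeA = familyTriple("geneA"),
                                treeB = familyTriple("geneB"),
                                rateMatrix = NULL, composition = NULL,
                                kappa = 8, gamma = NULL) {
  stopifnot(nSites >= 1L, inherits(treeA, "phylo"), inherits(treeB, "phylo"))
  if (length(treeA$tip.label) != 3L || length(treeB$tip.label) != 3L)
    stop("independent-origins simulation needs two 3-tip trees")
  set.seed(seed)
  if (!is.null(composition)) {
    alphabet <- if (length(composition[[1L]]) == 4L) "DNA" else "AA"
    s <- if (alphabet == "DNA") 4L else 20L
    composition <- .checkComposition(composition, s)
    if (alphabet == "DNA") {
      rmList <- lapply(composition, function(f)
        buildRateMatrix(modelSpec("HKY"), freqs = f, kappa = kappa))
    } else {
      if (length(composition) != 1L)
        stop("amino-acid composition bias takes a single frequency vector")
      rmList <- lapply(composition, function(f)
        buildRateMatrix(modelSpec("Poisson", plusF = TRUE), freqs = f))
    }
    rootFreqs <- composition
    clsIdx <- rep_len(seq_along(composition), nSites)
  } else {
    if (is.null(rateMatrix))
      rateMatrix <- buildRateMatrix(modelSpec("HKY"), freqs = rep(0.25, 4L),
                                    kappa = kappa)
    rmList <- list(rateMatrix)
    rootFreqs <- list(rateMatrix@pi)
    clsIdx <- rep(1L, nSites)
  }
  alphabet <- rmList[[1L]]@alphabet
  ratesA <- .drawSiteRates(gamma, nSites)
  tipsA <- .simulateTips(treeA, rmList, clsIdx, ratesA, rootFreqs)
  ratesB <- .drawSiteRates(gamma, nSites)
  tipsB <- .simulateTips(treeB, rmList, clsIdx, ratesB, rootFreqs)
  fams <- .splitTipFamilies(c(tipsA, tipsB), alphabet)
  if (length(fams) != 2L)
    stop("tree tips must be named <gene>_<taxon> with two distinct genes")
  fams
}

#' Named simulation presets
#'
#' Standard study conditions as one-call presets:
#' * `"common-origin"`: 1,038 nt evolved down [commonOriginTree()] (JC).
#' * `"independent-uniform"`: two unrelated families, uniform composition.
#' * `"independent-mtbias"`: two unrelated families sharing the
#'   mitochondrial codon-position bias of [mtBiasComposition()].
#' * `"independent-aa-convergent"`: two unrelated 346-residue amino-acid
#'   families sharing the mtmam stationary composition (compositional
#'   convergence without common ancestry).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param nSites number of sites (default 1038 nt / 346 aa).
#' @return Named list of two [SequenceFamily-class] objects.
#' @export
simulationPreset <- function(name = c("common-origin", "independent-uniform",
                                      "independent-mtbias",
                                      "independent-aa-convergent"),
                             seed, nSites = NULL) {
  name <- match.arg(name)
  switch(name,
    "common-origin" = simulateCommon(
      nSites = if (is.null(nSites)) 1038L else nSites, seed = seed),
    "independent-uniform" = simulateIndependent(
      nSites = if (is.null(nSites)) 1038L else nSites, seed = seed),
    "independent-mtbias" = simulateIndependent(
      nSites = if (is.null(nSites)) 1038L else nSites, seed = seed,
      composition = mtBiasComposition()),
    "independent-aa-convergent" = simulateIndependent(
      nSites = if (is.null(nSites)) 346L else nSites, seed = seed,
      composition = list(.empiricalAAModel("mtmam")$freqs)))
}
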