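# Independent oracles used to freeze expected values:
#  - exhaustive enumeration of global alignments (literal gap-run scoring)
#  - closed-form Jukes-Cantor transition probabilities
#  - quadrature for discrete-gamma category means
#  - brute-force phylogenetic likelihood summing over internal-node states

# Score a pair of already-aligned (gapped) rows literally, charging
# gop + (run - 1) * gep per maximal gap run in either row.
literalAlignmentScore <- function(ra, rb, scores, gop, gep) {
  if (is.character(ra) && length(ra) == 1) ra <- strsplit(ra, "")[[1]]
  if (is.character(rb) && length(rb) == 1) rb <- strsplit(rb, "")[[1]]
  s <- 0
  run <- 0  # 0 none, 1 gap in a-row, 2 gap in b-row
  for (k in seq_along(ra)) {
    if (ra[k] == "-") {
      s <- s - if (run == 1) gep else gop
      run <- 1
    } else if (rb[k] == "-") {
      s <- s - if (run == 2) gep else gop
      run <- 2
    } else {
      s <- s + scores[ra[k], rb[k]]
      run <- 0
    }
  }
  s
}

# Enumerate every global alignment of the (ungapped) sequences `a`, `b`
# and return the best literal score.
bruteForceAlignScore <- function(a, b, scores, gop, gep) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  scoreAln <- function(ra, rb) literalAlignmentScore(ra, rb, scores, gop, gep)
  best <- -Inf
  recurse <- function(i, j, ra, rb) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, scoreAln(ra, rb))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1, j + 1, c(ra, ca[i]), c(rb, cb[j]))
    if (i <= length(ca))
      recurse(i + 1, j, c(ra, ca[i]), c(rb, "-"))
    if (j <= length(cb))
      recurse(i, j + 1, c(ra, "-"), c(rb, cb[j]))
  }
  recurse(1, 1, character(), character())
  best
}

# Closed-form JC transition probability for one site.
jcTransitionProb <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  m
}

# Mean of each equal-probability gamma(alpha, alpha) slice by numerical
# integration (independent of the incomplete-gamma identity used in the
# implementation).
gammaCategoryMeansQuadrature <- function(alpha, k) {
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  sapply(seq_len(k), function(i) {
    integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
              b[i], b[i + 1], rel.tol = 1e-10)$value * k
  })
}

# Brute-force tree likelihood: sum over all internal-node state
# assignments, mixing equally over gamma categories. `pat` is a
# PatternTable, `tree` an ape phylo.
bruteForceLogLik <- function(tree, pat, rateMatrix, gamma = NULL) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  s <- length(rateMatrix@pi)
  rates <- if (is.null(gamma)) 1 else gamma@rates
  states <- pat@states[tree$tip.label, , drop = FALSE]
  root <- ntip + 1
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), nint)))
  total <- numeric(ncol(states))
  for (r in rates) {
    Plist <- lapply(seq_len(nrow(tree$edge)), function(k)
      transitionProbabilities(rateMatrix, tree$edge.length[k] * r))
    for (p in seq_len(ncol(states))) {
      sitep <- 0
      for (g in seq_len(nrow(grid))) {
        nodeState <- function(v)
          if (v <= ntip) states[v, p] else grid[g, v - ntip]
        pr <- rateMatrix@pi[nodeState(root)]
        for (k in seq_len(nrow(tree$edge)))
          pr <- pr * Plist[[k]][nodeState(tree$edge[k, 1]),
                                nodeState(tree$edge[k, 2])]
        sitep <- sitep + pr
      }
      total[p] <- total[p] + sitep / length(rates)
    }
  }
  sum(pat@weights * log(total))
}

# Random gap-free alignment as a GappedAlignment.
randomAlignment <- function(ids, ncols, alphabet = "DNA") {
  letters_ok <- alphabetLetters(alphabet)
  chars <- matrix(sample(letters_ok, length(ids) * ncols, replace = TRUE),
                  length(ids), ncols, dimnames = list(ids, NULL))
  ancestryAIC:::.newAlignment(chars, alphabet, provenance = "external")
}
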