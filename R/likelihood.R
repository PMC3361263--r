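## Phylogenetic likelihood on fixed topologies: Felsenstein pruning with
## discrete-gamma rate mixing, and maximization by cyclic coordinate
## ascent (Brent per branch, bounded quasi-Newton over model parameters).

#' PatternTable: compressed site patterns
#'
#' @slot states integer matrix (tips x patterns) of state indices into the
#'   alphabet; rownames are tip labels.
#' @slot weights pattern multiplicities (sum to `ncols`).
#' @slot alphabet `"DNA"` or `"AA"`.
#' @slot ncols number of alignment columns represented.
#' @export
setClass("PatternTable",
  slots = c(states = "matrix", weights = "numeric", alphabet = "character",
            ncols = "integer"),
  validity = function(object) {
    msg <- character()
    if (is.null(rownames(object@states)))
      msg <- c(msg, "states must have tip labels as rownames")
    if (ncol(object@states) != length(object@weights))
      msg <- c(msg, "one weight per pattern required")
    if (sum(object@weights) != object@ncols)
      msg <- c(msg, "weights must sum to the column count")
    if (any(object@weights <= 0))
      msg <- c(msg, "weights must be positive")
    s <- length(alphabetLetters(object@alphabet))
    if (length(object@states) &&
        (min(object@states) < 1L || max(object@states) > s))
      msg <- c(msg, "state indices out of range for alphabet")
    key <- apply(object@states, 2L, paste, collapse = ",")
    if (anyDuplicated(key)) msg <- c(msg, "patterns must be distinct")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "PatternTable", function(object) {
  cat(sprintf("PatternTable (%s): %d tips, %d patterns from %d columns\n",
              object@alphabet, nrow(object@states), ncol(object@states),
              object@ncols))
})

#' Compress alignment columns into weighted site patterns
#'
#' @param aln a gap-free [GappedAlignment-class].
#' @param tipOrder optional ordering/subset of row names.
#' @return A [PatternTable-class] whose weights sum to `alnWidth(aln)`.
#' @export
compressPatterns <- function(aln, tipOrder = NULL) {
  stopifnot(is(aln, "GappedAlignment"))
  chars <- alnChars(aln)
  if (!is.null(tipOrder)) {
    if (!all(tipOrder %in% rownames(chars)))
      stop("tipOrder contains rows absent from the alignment")
    chars <- chars[tipOrder, , drop = FALSE]
  }
  if (any(chars == GAP_CHAR))
    stop("alignment contains gaps; apply stripGapColumns() first")
  letters_ok <- alphabetLetters(aln@alphabet)
  idx <- matrix(match(chars, letters_ok), nrow(chars), ncol(chars),
                dimnames = list(rownames(chars), NULL))
  key <- apply(idx, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  new("PatternTable", states = idx[, first, drop = FALSE], weights = weights,
      alphabet = aln@alphabet, ncols = ncol(chars))
}

## Precompute everything about one (tree, data) unit that does not change
## during optimization: postorder edge list and tip indicator matrices.
.makeUnit <- function(tree, pat) {
  stopifnot(inherits(tree, "phylo"), is(pat, "PatternTable"))
  if (!all(tree$tip.label %in% rownames(pat@states)))
    stop("tree tips missing from pattern table: ",
         paste(setdiff(tree$tip.label, rownames(pat@states)), collapse = ", "))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  s <- length(alphabetLetters(pat@alphabet))
  npat <- ncol(pat@states)
  tipInd <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    st <- pat@states[tree$tip.label[i], ]
    m <- matrix(0, s, npat)
    m[cbind(st, seq_len(npat))] <- 1
    tipInd[[i]] <- m
  }
  list(tree = tree, parent = tree$edge[, 1L], child = tree$edge[, 2L],
       edgeLen = tree$edge.length, ntip = ntip, root = ntip + 1L,
       nnode = ntip + tree$Nnode, tipInd = tipInd, w = pat@weights,
       npat = npat, s = s)
}

## Pruning log-likelihood of one unit for one set of edge lengths, with a
## per-node rescaling of conditional likelihoods. `rates` are the discrete
## gamma category rates (or 1); categories are mixed with equal weights.
.pruneLogLik <- function(unit, edgeLen, rm, rates) {
  e <- rm@eig
  s <- unit$s
  npat <- unit$npat
  ncat <- length(rates)
  llcat <- matrix(0, ncat, npat)
  for (ci in seq_len(ncat)) {
    L <- vector("list", unit$nnode)
    logsc <- numeric(npat)
    for (k in seq_along(unit$parent)) {
      ch <- unit$child[k]
      P <- e$U %*% (exp(e$values * (edgeLen[k] * rates[ci])) * e$Ui)
      P[P < 0] <- 0
      if (ch <= unit$ntip) {
        cl <- unit$tipInd[[ch]]
      } else {
        cl <- L[[ch]]
        mx <- do.call(pmax, lapply(seq_len(s), function(r) cl[r, ]))
        cl <- cl * rep(1 / mx, each = s)
        logsc <- logsc + log(mx)
      }
      contrib <- P %*% cl
      p <- unit$parent[k]
      L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    }
    llcat[ci, ] <- log(colSums(rm@pi * L[[unit$root]])) + logsc
  }
  if (ncat == 1L) {
    sitell <- llcat[1L, ]
  } else {
    mx <- do.call(pmax, lapply(seq_len(ncat), function(c) llcat[c, ]))
    sitell <- mx + log(colMeans(exp(llcat - rep(mx, each = ncat))))
  }
  sum(unit$w * sitell)
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Computes `sum_patterns w * log sum_categories (1/k) L(pattern)` on a
#' fixed tree with fixed parameters. The likelihood is invariant to the
#' rooting of the tree for these (reversible) models.
#'
#' @param tree an `ape::phylo` tree with edge lengths; tip labels must
#'   match rows of `pat`.
#' @param pat a [PatternTable-class] (see [compressPatterns()]).
#' @param rateMatrix a [RateMatrix-class].
#' @param gamma a [GammaRates-class], or `NULL` for a single rate class.
#' @return The log-likelihood (a single number, `<= 0`).
#' @export
logLikelihood <- function(tree, pat, rateMatrix, gamma = NULL) {
  stopifnot(is(rateMatrix, "RateMatrix"))
  if (rateMatrix@alphabet != pat@alphabet)
    stop("model alphabet (", rateMatrix@alphabet,
         ") does not match data alphabet (", pat@alphabet, ")")
  unit <- .makeUnit(tree, pat)
  if (is.null(unit$edgeLen))
    stop("tree has no edge lengths")
  rates <- if (is.null(gamma)) 1 else gamma@rates
  .pruneLogLik(unit, unit$edgeLen, rateMatrix, rates)
}

## Observed state frequencies from one or more pattern tables.
.patternFrequencies <- function(pats) {
  s <- length(alphabetLetters(pats[[1L]]@alphabet))
  counts <- numeric(s)
  for (pat in pats) {
    wrep <- rep(pat@weights, each = nrow(pat@states))
    for (r in seq_len(s)) counts[r] <- counts[r] + sum(wrep[pat@states == r])
  }
  setNames(counts / sum(counts), alphabetLetters(pats[[1L]]@alphabet))
}

## Distance-based initial branch lengths: tip edges start at half the mean
## JC-corrected p-distance to the other tips, internal edges at 0.05.
.initEdgeLengths <- function(unit, pat) {
  s <- unit$s
  ntip <- unit$ntip
  states <- pat@states[unit$tree$tip.label, , drop = FALSE]
  w <- pat@weights / sum(pat@weights)
  D <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip - 1L)) for (j in (i + 1L):ntip) {
    p <- sum(w * (states[i, ] != states[j, ]))
    p <- min(p, 0.95 * (s - 1) / s)
    D[i, j] <- D[j, i] <- -(s - 1) / s * log(1 - s / (s - 1) * p)
  }
  tipStart <- pmax(0.01, rowMeans(D) * ntip / max(1L, ntip - 1L) / 2)
  len <- ifelse(unit$child <= ntip, tipStart[unit$child], 0.05)
  pmin(pmax(len, 1e-6), 50)
}

#' Maximize the log-likelihood on one or more fixed topologies
#'
#' Branch lengths and free model parameters are optimized jointly by
#' cyclic coordinate ascent: a Brent line search per branch length
#' (bounded in `[0, branchMax]`), then bounded quasi-Newton over the
#' log-transformed model parameters (kappa or GTR rates, gamma shape
#' alpha in `[0.005, 100]`). Cycles repeat until a full cycle improves
#' the log-likelihood by less than `tol`. The fit is deterministic.
#'
#' When several `(tree, data)` units are supplied they share model
#' parameters (and pooled observed frequencies) but keep separate branch
#' lengths, and the reported log-likelihood is the sum.
#'
#' @param tree a `phylo` tree, or a list of trees.
#' @param pat a [PatternTable-class], or a list parallel to `tree`.
#' @param spec a [ModelSpec-class].
#' @param control list of optimizer settings: `tol` (default `1e-6`),
#'   `maxCycles` (default 200), `branchMax` (default 50).
#' @return A [FitResult-class].
#' @export
maximizeLikelihood <- function(tree, pat, spec,
                               control = list()) {
  stopifnot(is(spec, "ModelSpec"))
  ctrl <- utils::modifyList(list(tol = 1e-6, maxCycles = 200L, branchMax = 50),
                            control)
  trees <- if (inherits(tree, "phylo")) list(tree) else tree
  pats <- if (is(pat, "PatternTable")) list(pat) else pat
  stopifnot(length(trees) == length(pats), length(trees) >= 1L)
  for (p in pats)
    if (p@alphabet != modelAlphabet(spec))
      stop("model alphabet (", modelAlphabet(spec),
           ") does not match data alphabet (", p@alphabet, ")")
  units <- mapply(.makeUnit, trees, pats, SIMPLIFY = FALSE)
  edges <- mapply(.initEdgeLengths, units, pats, SIMPLIFY = FALSE)

  needFreqs <- spec@family %in% c("HKY", "GTR") || spec@plusF
  freqs <- if (needFreqs) .patternFrequencies(pats) else NULL
  hasKappa <- spec@family %in% c("K80", "HKY")
  hasGTR <- spec@family == "GTR"
  kappa <- 2
  gtrRates <- rep(1, 5)
  alpha <- 0.5

  buildRM <- function() buildRateMatrix(spec, freqs, kappa, gtrRates)
  buildRates <- function() {
    if (spec@plusGamma) discretizeGamma(alpha, spec@nCat)@rates else 1
  }

  rm <- buildRM()
  rates <- buildRates()
  ## optimizers may probe parameter regions where some pattern gets
  ## (numerically) zero probability; treat those as very bad, not fatal
  .finite <- function(x) if (is.finite(x)) x else -1e12
  totalLnL <- function() {
    sum(vapply(seq_along(units), function(u)
      .pruneLogLik(units[[u]], edges[[u]], rm, rates), numeric(1L)))
  }
  lnL <- totalLnL()
  converged <- FALSE

  ## model-parameter vector on log scale
  thetaNames <- c(if (hasKappa) "kappa",
                  if (hasGTR) paste0("r", 1:5),
                  if (spec@plusGamma) "alpha")
  getTheta <- function() {
    th <- c(if (hasKappa) kappa, if (hasGTR) gtrRates,
            if (spec@plusGamma) alpha)
    if (is.null(th)) numeric(0) else log(th)
  }
  setTheta <- function(th) {
    i <- 1L
    if (hasKappa) { kappa <<- exp(th[i]); i <- i + 1L }
    if (hasGTR) { gtrRates <<- exp(th[i:(i + 4L)]); i <- i + 5L }
    if (spec@plusGamma) alpha <<- exp(th[i])
  }

  thetaBounds <- function() {
    n <- length(thetaNames)
    lower <- rep(log(1e-4), n)
    upper <- rep(log(1e4), n)
    if (spec@plusGamma && n) {
      lower[n] <- log(0.005)
      upper[n] <- log(100)
    }
    list(lower = lower, upper = upper)
  }

  ## one full cycle of coordinate ascent: Brent per branch, then bounded
  ## quasi-Newton on the log model parameters
  oneCycle <- function() {
    for (u in seq_along(units)) {
      for (k in seq_along(edges[[u]])) {
        f <- function(t) {
          ed <- edges[[u]]
          ed[k] <- t
          -.finite(.pruneLogLik(units[[u]], ed, rm, rates))
        }
        opt <- optimize(f, c(1e-8, ctrl$branchMax), tol = 1e-6)
        if (-opt$objective >= .pruneLogLik(units[[u]], edges[[u]], rm, rates))
          edges[[u]][k] <<- opt$minimum
      }
    }
    if (length(thetaNames)) {
      th0 <- getTheta()
      b <- thetaBounds()
      fn <- function(th) {
        setTheta(th)
        rmL <- buildRM()
        ratesL <- buildRates()
        -.finite(sum(vapply(seq_along(units), function(u)
          .pruneLogLik(units[[u]], edges[[u]], rmL, ratesL), numeric(1L))))
      }
      opt <- optim(th0, fn, method = "L-BFGS-B", lower = b$lower,
                   upper = b$upper,
                   control = list(maxit = 10L,
                                  ndeps = rep(1e-5, length(th0))))
      if (-opt$value >= -fn(th0)) setTheta(opt$par) else setTheta(th0)
    }
    rm <<- buildRM()
    rates <<- buildRates()
    lnL <<- totalLnL()
  }

  ## joint bounded quasi-Newton over all log branch lengths and log model
  ## parameters; pure coordinate ascent zigzags on the correlated
  ## branch-length/alpha directions and this finishes in a few dozen
  ## gradient steps what cycling would spend hundreds of rounds on
  jointPolish <- function() {
    nE <- lengths(edges)
    b <- thetaBounds()
    par0 <- c(log(pmax(unlist(edges), 1e-8)), getTheta())
    lower <- c(rep(log(1e-8), sum(nE)), b$lower)
    upper <- c(rep(log(ctrl$branchMax), sum(nE)), b$upper)
    setPar <- function(p) {
      ed <- exp(p[seq_len(sum(nE))])
      edges <<- split(ed, rep(seq_along(nE), nE))
      if (length(thetaNames)) setTheta(p[-seq_len(sum(nE))])
    }
    fn <- function(p) {
      setPar(p)
      rmL <- buildRM()
      ratesL <- buildRates()
      -.finite(sum(vapply(seq_along(units), function(u)
        .pruneLogLik(units[[u]], edges[[u]], rmL, ratesL), numeric(1L))))
    }
    opt <- optim(par0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 300L, factr = 1e3,
                                ndeps = rep(1e-5, length(par0))))
    setPar(if (opt$value <= -lnL) opt$par else par0)
    rm <<- buildRM()
    rates <<- buildRates()
    lnL <<- totalLnL()
  }

  cyclesUsed <- 0L
  runCycles <- function(n, stopTol) {
    imp <- Inf
    while (n > 0L && imp >= stopTol) {
      lnL0 <- lnL
      oneCycle()
      imp <- lnL - lnL0
      n <- n - 1L
      cyclesUsed <<- cyclesUsed + 1L
    }
    imp
  }

  imp <- runCycles(min(4L, ctrl$maxCycles), max(ctrl$tol, 0.05))
  round <- 0L
  while (imp >= ctrl$tol && cyclesUsed < ctrl$maxCycles && round < 5L) {
    round <- round + 1L
    jointPolish()
    imp <- runCycles(min(3L, ctrl$maxCycles - cyclesUsed), ctrl$tol)
  }
  converged <- imp < ctrl$tol
  if (!converged)
    warning("maximizeLikelihood did not converge in ", ctrl$maxCycles,
            " cycles (last improvement ", format(imp), ")")

  nBranches <- sum(lengths(edges))
  k <- countFreeParameters(spec, nBranches)
  outTrees <- lapply(seq_along(units), function(u) {
    tr <- units[[u]]$tree
    tr$edge.length <- edges[[u]]
    tr
  })
  est <- list(edgeLengths = edges, freqs = freqs)
  if (hasKappa) est$kappa <- kappa
  if (hasGTR) est$gtrRates <- c(gtrRates, GT = 1)
  if (spec@plusGamma) est$alpha <- alpha
  new("FitResult", lnL = lnL, estimates = est, k = k,
      aic = 2 * k - 2 * lnL, converged = converged, spec = spec,
      trees = outTrees)
}
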