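## Substitution models: normalized reversible rate matrices for JC, K80,
## HKY, GTR (nucleotide) and Poisson, JTT, mtmam (amino acid), with +F and
## discrete-gamma modifiers, transition probabilities via symmetric
## eigendecomposition, and AIC free-parameter counting.

#' Construct a ModelSpec
#'
#' @param family model family: `"JC"`, `"K80"`, `"HKY"`, `"GTR"`,
#'   `"Poisson"`, `"JTT"` or `"mtmam"`.
#' @param plusF use observed amino-acid frequencies (protein only).
#' @param plusGamma discrete-gamma rate heterogeneity.
#' @param nCat gamma categories (default 4).
#' @param countFreqs whether data-estimated frequencies count toward the
#'   AIC dimension (default `TRUE`).
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(family, plusF = FALSE, plusGamma = FALSE, nCat = 4L,
                      countFreqs = TRUE) {
  new("ModelSpec", family = family, plusF = plusF, plusGamma = plusGamma,
      nCat = as.integer(nCat), countFreqs = countFreqs)
}

#' Parse a model label such as "GTR+G" or "mtmam+F+G"
#'
#' Recognised labels: `JC`, `K80`, `HKY`, `GTR`, `K80+G`, `HKY+G`,
#' `GTR+G`, `Poisson`, `JTT`, `mtmam`, `Poisson+G`, `JTT+F+G`,
#' `mtmam+F+G` (and any other family/flag combination of the same form).
#'
#' @param label model label string.
#' @inheritParams modelSpec
#' @return A [ModelSpec-class].
#' @examples
#' parseModelSpec("GTR+G")
#' @export
parseModelSpec <- function(label, nCat = 4L, countFreqs = TRUE) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  fams <- c("JC", "K80", "HKY", "GTR", "Poisson", "JTT", "mtmam")
  fam <- fams[match(toupper(parts[1L]), toupper(fams))]
  if (is.na(fam)) stop("unknown model family '", parts[1L], "'")
  flags <- toupper(parts[-1L])
  if (!all(flags %in% c("F", "G", "GAMMA")))
    stop("unknown model modifier in '", label, "'")
  modelSpec(fam, plusF = "F" %in% flags,
            plusGamma = any(c("G", "GAMMA") %in% flags),
            nCat = nCat, countFreqs = countFreqs)
}

#' Label of a ModelSpec ("mtmam+F+G" style)
#'
#' @param spec a [ModelSpec-class].
#' @return Character label.
#' @export
modelLabel <- function(spec) {
  paste0(spec@family, if (spec@plusF) "+F" else "", if (spec@plusGamma) "+G" else "")
}

#' Alphabet of a model family
#'
#' @param spec a [ModelSpec-class].
#' @return `"DNA"` or `"AA"`.
#' @export
modelAlphabet <- function(spec) {
  if (spec@family %in% c("JC", "K80", "HKY", "GTR")) "DNA" else "AA"
}

## Canonical empirical amino-acid models (PAML .dat values, PAML residue
## order), taken from phangorn's copies: a 20x20 symmetric exchangeability
## matrix and the model's stationary frequencies.
.empiricalAAModel <- function(family) {
  stopifnot(family %in% c("JTT", "mtmam"))
  tmp <- get(paste0(".", family), envir = environment(phangorn::pml))
  s <- matrix(0, 20L, 20L, dimnames = list(AA_LETTERS, AA_LETTERS))
  s[lower.tri(s)] <- tmp$Q
  s <- s + t(s)
  list(exch = s, freqs = setNames(as.numeric(tmp$bf), AA_LETTERS))
}

.checkFreqs <- function(freqs, s, plusF = FALSE) {
  if (length(freqs) != s)
    stop("frequency vector must have length ", s)
  if (any(!is.finite(freqs)) || any(freqs < 0))
    stop("frequencies must be non-negative finite numbers")
  if (any(freqs == 0)) {
    if (plusF)
      stop("a residue has observed frequency 0; +F needs every residue ",
           "present (add a pseudocount or use the model's own frequencies)")
    stop("frequencies must be strictly positive")
  }
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must sum to 1 (got ", format(sum(freqs)), ")")
  freqs / sum(freqs)
}

#' Build a normalized reversible rate matrix
#'
#' Constructs `Q` with `Q[i,j] = s[i,j] * pi[j]` from the family's
#' exchangeabilities `s`, rescaled so the expected substitution rate
#' `-sum(pi * diag(Q))` is exactly 1 (branch lengths are then expected
#' substitutions per site). JC/K80 use uniform base frequencies; HKY/GTR
#' use the supplied (observed) frequencies; Poisson is uniform over 20
#' amino acids; JTT/mtmam use their published frequencies unless `+F`
#' replaces them with observed ones.
#'
#' @param spec a [ModelSpec-class].
#' @param freqs stationary frequencies where the model uses data
#'   frequencies (HKY, GTR, or any protein family with `+F`).
#' @param kappa transition/transversion rate ratio (K80, HKY).
#' @param gtrRates the five free GTR exchangeabilities
#'   `(AC, AG, AT, CG, CT)`; `GT` is fixed to 1.
#' @return A [RateMatrix-class].
#' @examples
#' buildRateMatrix(modelSpec("JC"))
#' @export
buildRateMatrix <- function(spec, freqs = NULL, kappa = 2,
                            gtrRates = rep(1, 5)) {
  stopifnot(is(spec, "ModelSpec"))
  fam <- spec@family
  if (fam %in% c("JC", "K80", "HKY", "GTR")) {
    letters_ok <- DNA_LETTERS
    s <- matrix(1, 4L, 4L, dimnames = list(letters_ok, letters_ok))
    if (fam %in% c("K80", "HKY")) {
      if (!(is.numeric(kappa) && kappa > 0)) stop("kappa must be > 0")
      s["A", "G"] <- s["G", "A"] <- kappa
      s["C", "T"] <- s["T", "C"] <- kappa
    } else if (fam == "GTR") {
      if (length(gtrRates) != 5L || any(!is.finite(gtrRates)) ||
          any(gtrRates <= 0))
        stop("gtrRates must be 5 positive rates (AC, AG, AT, CG, CT)")
      s["A", "C"] <- s["C", "A"] <- gtrRates[1L]
      s["A", "G"] <- s["G", "A"] <- gtrRates[2L]
      s["A", "T"] <- s["T", "A"] <- gtrRates[3L]
      s["C", "G"] <- s["G", "C"] <- gtrRates[4L]
      s["C", "T"] <- s["T", "C"] <- gtrRates[5L]
      s["G", "T"] <- s["T", "G"] <- 1
    }
    pi <- if (fam %in% c("JC", "K80")) rep(0.25, 4L)
          else .checkFreqs(freqs, 4L)
  } else {
    letters_ok <- AA_LETTERS
    if (fam == "Poisson") {
      s <- matrix(1, 20L, 20L, dimnames = list(letters_ok, letters_ok))
      pi <- if (spec@plusF) .checkFreqs(freqs, 20L, plusF = TRUE)
            else rep(1 / 20, 20L)
    } else {
      emp <- .empiricalAAModel(fam)
      s <- emp$exch
      pi <- if (spec@plusF) .checkFreqs(freqs, 20L, plusF = TRUE)
            else .checkFreqs(emp$freqs, 20L)
    }
  }
  names(pi) <- letters_ok
  Q <- s * rep(pi, each = length(pi))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  beta <- -sum(pi * diag(Q))
  Q <- Q / beta
  ## symmetric eigendecomposition of diag(sqrt(pi)) Q diag(1/sqrt(pi))
  rpi <- sqrt(pi)
  B <- Q * (rpi %o% (1 / rpi))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors / rpi       # rows scaled: diag(1/sqrt(pi)) %*% V
  Ui <- t(eig$vectors * rpi)   # t(diag(sqrt(pi)) %*% V)
  new("RateMatrix", Q = Q, pi = pi, alphabet = modelAlphabet(spec),
      eig = list(values = eig$values, U = U, Ui = Ui))
}

#' RateMatrix: normalized reversible substitution rate matrix
#'
#' Validity enforces zero row sums, stationarity and detailed balance of
#' `pi` and normalization `-sum(pi * diag(Q)) == 1`, all to 1e-12; the
#' symmetric eigendecomposition used by [transitionProbabilities()] is
#' cached in the `eig` slot.
#'
#' @slot Q rate matrix (4x4 or 20x20).
#' @slot pi stationary frequencies.
#' @slot alphabet `"DNA"` or `"AA"`.
#' @slot eig cached eigendecomposition (`values`, `U`, `Ui`).
#' @export
setClass("RateMatrix",
  slots = c(Q = "matrix", pi = "numeric", alphabet = "character",
            eig = "list"),
  validity = function(object) {
    msg <- character()
    Q <- object@Q; pi <- object@pi
    if (nrow(Q) != ncol(Q) || nrow(Q) != length(pi))
      return("Q must be square with one frequency per state")
    if (max(abs(rowSums(Q))) > 1e-12)
      msg <- c(msg, "rows of Q must sum to 0")
    if (max(abs(pi * Q - t(pi * Q))) > 1e-12)
      msg <- c(msg, "Q must satisfy detailed balance")
    if (abs(-sum(pi * diag(Q)) - 1) > 1e-12)
      msg <- c(msg, "Q must be normalized to 1 expected substitution")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "RateMatrix", function(object) {
  cat(sprintf("RateMatrix (%s, %d states), normalized; pi:\n",
              object@alphabet, length(object@pi)))
  print(round(object@pi, 4))
})

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param rateMatrix a [RateMatrix-class].
#' @param t branch length (expected substitutions per site), `>= 0`.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @examples
#' transitionProbabilities(buildRateMatrix(modelSpec("JC")), 0.1)
#' @export
transitionProbabilities <- function(rateMatrix, t) {
  stopifnot(is(rateMatrix, "RateMatrix"))
  if (!(is.numeric(t) && length(t) == 1L && is.finite(t)))
    stop("t must be a single finite number")
  if (t < 0) stop("branch length t must be >= 0")
  e <- rateMatrix@eig
  P <- e$U %*% (exp(e$values * t) * e$Ui)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(rateMatrix@Q)
  P
}

#' GammaRates: discretized gamma rate distribution
#'
#' @slot alpha shape parameter.
#' @slot rates category rates (non-decreasing, mean exactly 1).
#' @slot weights equal category weights `1/k`.
#' @export
setClass("GammaRates",
  slots = c(alpha = "numeric", rates = "numeric", weights = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
    if (length(object@rates) != length(object@weights))
      msg <- c(msg, "rates and weights must be parallel")
    if (abs(sum(object@rates * object@weights) - 1) > 1e-9)
      msg <- c(msg, "mean rate must be 1")
    if (is.unsorted(object@rates))
      msg <- c(msg, "rates must be non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' Discretize a gamma rate distribution (equal-probability categories)
#'
#' Yang's mean-of-slice discretization: the gamma(alpha, alpha)
#' distribution is cut into `k` equal-probability slices and each
#' category's rate is the mean of its slice, renormalized so the mean is
#' exactly 1.
#'
#' @param alpha shape parameter (> 0).
#' @param k number of categories (>= 1).
#' @return A [GammaRates-class].
#' @examples
#' discretizeGamma(0.5, 4)
#' @export
discretizeGamma <- function(alpha, k = 4L) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) &&
        alpha > 0))
    stop("alpha must be a single number > 0")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L)
    return(new("GammaRates", alpha = alpha, rates = 1, weights = 1))
  b <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  ## E[X 1(a < X < b)] for X ~ Gamma(alpha, alpha) is
  ## pgamma(b, alpha + 1, alpha) - pgamma(a, alpha + 1, alpha)
  mass <- diff(pgamma(b, shape = alpha + 1, rate = alpha))
  rates <- mass * k
  rates <- rates / mean(rates)
  new("GammaRates", alpha = alpha, rates = rates, weights = rep(1 / k, k))
}

#' Free-parameter count of a model fit (the AIC dimension)
#'
#' `k = n_branches + substitution parameters + 1 if +Gamma + frequency
#' parameters`. Substitution parameters: 0 (JC, Poisson, JTT, mtmam),
#' 1 (K80, HKY), 5 (GTR). Frequency parameters, counted only when
#' `countFreqs(spec)` is `TRUE`: 3 for HKY/GTR, 19 for `+F`, else 0.
#'
#' @param spec a [ModelSpec-class].
#' @param nBranches number of free branch lengths (>= 0).
#' @return Integer `k`.
#' @examples
#' countFreeParameters(modelSpec("JC"), 3)                     # 3
#' countFreeParameters(parseModelSpec("GTR+G"), 9)             # 18
#' @export
countFreeParameters <- function(spec, nBranches) {
  stopifnot(is(spec, "ModelSpec"), nBranches >= 0)
  subst <- switch(spec@family, JC = 0L, Poisson = 0L, JTT = 0L, mtmam = 0L,
                  K80 = 1L, HKY = 1L, GTR = 5L)
  freq <- 0L
  if (spec@countFreqs) {
    if (spec@family %in% c("HKY", "GTR")) freq <- 3L
    if (spec@plusF) freq <- 19L
  }
  as.integer(nBranches) + subst + freq + as.integer(spec@plusGamma)
}

#' Observed residue frequencies of a gap-free alignment
#'
#' @param aln a [GappedAlignment-class] (gap-free), or a character matrix.
#' @param alphabet alphabet, required when `aln` is a bare matrix.
#' @return Named frequency vector over the alphabet.
#' @export
observedFrequencies <- function(aln, alphabet = NULL) {
  if (is(aln, "GappedAlignment")) {
    alphabet <- aln@alphabet
    chars <- alnChars(aln)
  } else chars <- aln
  letters_ok <- alphabetLetters(alphabet)
  counts <- vapply(letters_ok, function(z) sum(chars == z), numeric(1L))
  counts / sum(counts)
}
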