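## Clustal-like global alignment with explicit affine gap penalties.
## A gap run of length L costs gop + (L - 1) * gep; terminal gaps are
## penalised like internal ones. The same Gotoh dynamic programme serves
## both residue-residue and profile-profile alignment (the latter with
## sum-of-pairs column scores), so the progressive aligner inherits the
## "once a gap always a gap" behaviour.

#' Nucleotide scoring table
#'
#' Clustal-style IUB scores: identical bases score `match` (default 1.9),
#' all mismatches score `mismatch` (default 0).
#'
#' @param match,mismatch scores.
#' @return 4x4 numeric matrix with ACGT dimnames.
#' @export
nucleotideScores <- function(match = 1.9, mismatch = 0) {
  m <- matrix(mismatch, 4L, 4L, dimnames = list(DNA_LETTERS, DNA_LETTERS))
  diag(m) <- match
  m
}

#' Protein scoring table (BLOSUM62)
#'
#' @return 20x20 BLOSUM62 matrix in the package's amino-acid order.
#' @export
proteinScores <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_LETTERS, AA_LETTERS]
}

#' Default Clustal W gap penalties
#'
#' `(15, 6.66)` for nucleotide and `(10, 0.1)` for amino-acid sequences.
#'
#' @param alphabet `"DNA"` or `"AA"`.
#' @return Numeric `c(gop, gep)`.
#' @export
defaultGapPenalty <- function(alphabet) {
  alphabet <- match.arg(alphabet, c("DNA", "AA"))
  if (alphabet == "DNA") c(gop = 15, gep = 6.66) else c(gop = 10, gep = 0.1)
}

.checkPenalty <- function(gop, gep) {
  if (!(is.numeric(gop) && length(gop) == 1L && is.finite(gop) && gop >= 0))
    stop("gop must be a single non-negative number")
  if (!(is.numeric(gep) && length(gep) == 1L && is.finite(gep) && gep >= 0))
    stop("gep must be a single non-negative number")
}

.inferAlphabet <- function(seqs) {
  ch <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  ch <- setdiff(ch, GAP_CHAR)
  if (all(ch %in% DNA_LETTERS)) "DNA" else "AA"
}

## Gotoh affine-gap global DP on a precomputed n x m column-score matrix.
## States: M (residue/residue), Ix (row item over gap), Iy (gap over column
## item). Ix<->Iy transitions open a fresh gap, so every path scores each
## literal gap run as gop + (run - 1) * gep. The Iy recursion is folded
## into a cummax scan so each row is fully vectorised.
.gotoh <- function(smat, gop, gep) {
  n <- nrow(smat)
  m <- ncol(smat)
  M <- Ix <- Iy <- matrix(-Inf, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n > 0L) Ix[seq_len(n) + 1L, 1L] <- -(gop + (seq_len(n) - 1L) * gep)
  if (m > 0L) Iy[1L, seq_len(m) + 1L] <- -(gop + (seq_len(m) - 1L) * gep)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    r <- i + 1L
    prevM <- M[r - 1L, ]
    prevIx <- Ix[r - 1L, ]
    prevIy <- Iy[r - 1L, ]
    M[r, jj + 1L] <- smat[i, ] +
      pmax(prevM[jj], prevIx[jj], prevIy[jj])
    Ix[r, jj + 1L] <- pmax(prevM[jj + 1L] - gop,
                           prevIy[jj + 1L] - gop,
                           prevIx[jj + 1L] - gep)
    ## Iy[r, j] = max_{k < j} max(M[r,k], Ix[r,k]) - gop - (j-1-k)*gep
    base <- pmax(M[r, seq_len(m)], Ix[r, seq_len(m)])  # cells j = 0..m-1
    cm <- cummax(base + gep * (seq_len(m) - 1L))
    Iy[r, jj + 1L] <- cm - gop - gep * (jj - 1L)
  }
  list(M = M, Ix = Ix, Iy = Iy,
       score = max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L]))
}

## Traceback with fixed tie-breaking: state preference M > Ix > Iy
## (diagonal > up > left), applied both to the final cell and to every
## predecessor choice. Values are compared with a small tolerance because
## boundary cells are filled in closed form while interior cells accumulate
## the same quantities term by term.
.gotohTraceback <- function(dp, gop, gep) {
  M <- dp$M; Ix <- dp$Ix; Iy <- dp$Iy
  n <- nrow(M) - 1L
  m <- ncol(M) - 1L
  eps <- 1e-6
  states <- c("M", "Ix", "Iy")
  pick <- function(vals, target) {
    hit <- which(vals >= target - eps)
    if (length(hit)) hit[1L] else which.max(vals)
  }
  i <- n; j <- m
  vals <- c(M[i + 1L, j + 1L], Ix[i + 1L, j + 1L], Iy[i + 1L, j + 1L])
  state <- states[pick(vals, max(vals))]
  ops <- character(n + m)
  nops <- 0L
  while (i > 0L || j > 0L) {
    nops <- nops + 1L
    if (state == "M") {
      ops[nops] <- "D"
      target <- M[i + 1L, j + 1L] - dp$smat[i, j]
      state <- states[pick(c(M[i, j], Ix[i, j], Iy[i, j]), target)]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {
      ops[nops] <- "U"
      target <- Ix[i + 1L, j + 1L]
      state <- states[pick(c(M[i, j + 1L] - gop,
                             Ix[i, j + 1L] - gep,
                             Iy[i, j + 1L] - gop), target)]
      i <- i - 1L
    } else {
      ops[nops] <- "L"
      target <- Iy[i + 1L, j + 1L]
      state <- states[pick(c(M[i + 1L, j] - gop,
                             Ix[i + 1L, j] - gop,
                             Iy[i + 1L, j] - gep), target)]
      j <- j - 1L
    }
  }
  rev(ops[seq_len(nops)])
}

.alignCore <- function(smat, gop, gep) {
  dp <- .gotoh(smat, gop, gep)
  dp$smat <- smat
  ops <- .gotohTraceback(dp, gop, gep)
  ai <- integer(length(ops))  # source column in a (0 = gap)
  bi <- integer(length(ops))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != "L") { ia <- ia + 1L; ai[k] <- ia }
    if (ops[k] != "U") { ib <- ib + 1L; bi[k] <- ib }
  }
  list(score = dp$score, ai = ai, bi = bi)
}

.expandColumns <- function(chars, idx) {
  out <- matrix(GAP_CHAR, nrow(chars), length(idx),
                dimnames = list(rownames(chars), NULL))
  out[, idx > 0L] <- chars[, idx[idx > 0L], drop = FALSE]
  out
}

#' Pairwise global alignment (Gotoh, affine gaps)
#'
#' Finds the globally optimal alignment of two sequences under
#' `score = sum(column scores) - sum(gop + (run - 1) * gep)` over gap
#' runs, with deterministic tie-breaking (diagonal > up > left).
#'
#' @param a,b single residue strings (optionally length-1 named vectors;
#'   names become row ids).
#' @param gop,gep gap-open and gap-extension penalties (non-negative).
#' @param scores substitution score matrix; defaults to
#'   [nucleotideScores()] or [proteinScores()] by alphabet.
#' @param alphabet `"DNA"` or `"AA"`; inferred from the residues if missing.
#' @return A two-row [GappedAlignment-class]; the optimal score is in the
#'   `score` slot (see [alnScore()]).
#' @examples
#' aln <- pairwiseAlign(c(x = "ACGT"), c(y = "ACT"), gop = 2, gep = 1,
#'                      scores = nucleotideScores(1, -1))
#' alnChars(aln)
#' @export
pairwiseAlign <- function(a, b, gop, gep, scores = NULL, alphabet = NULL) {
  .checkPenalty(gop, gep)
  ida <- if (!is.null(names(a))) names(a)[1L] else "a"
  idb <- if (!is.null(names(b))) names(b)[1L] else "b"
  a <- unname(a); b <- unname(b)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  if (is.null(alphabet)) alphabet <- .inferAlphabet(c(a, b))
  if (is.null(scores))
    scores <- if (alphabet == "DNA") nucleotideScores() else proteinScores()
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  res <- .alignCore(scores[ca, cb, drop = FALSE], gop, gep)
  chars <- rbind(.expandColumns(matrix(ca, 1L, dimnames = list(ida, NULL)), res$ai),
                 .expandColumns(matrix(cb, 1L, dimnames = list(idb, NULL)), res$bi))
  .newAlignment(chars, alphabet, gop = gop, gep = gep,
                provenance = "gotoh", score = res$score)
}

## Residue frequency profile of an alignment block: s x ncol matrix of
## per-column residue proportions (gaps contribute zero weight).
.profileFreqs <- function(chars, letters_ok) {
  s <- length(letters_ok)
  out <- matrix(0, s, ncol(chars), dimnames = list(letters_ok, NULL))
  for (r in seq_len(s)) out[r, ] <- colSums(chars == letters_ok[r])
  out / nrow(chars)
}

.profileAlign <- function(charsA, charsB, scores, gop, gep, letters_ok) {
  fa <- .profileFreqs(charsA, letters_ok)
  fb <- .profileFreqs(charsB, letters_ok)
  smat <- crossprod(fa, scores %*% fb)  # sum-of-pairs average column score
  res <- .alignCore(smat, gop, gep)
  list(chars = rbind(.expandColumns(charsA, res$ai),
                     .expandColumns(charsB, res$bi)),
       score = res$score)
}

## p-distance between two gapped rows: proportion of differing sites among
## columns where both carry a residue.
.pDistance <- function(chA, chB) {
  use <- chA != GAP_CHAR & chB != GAP_CHAR
  if (!any(use)) return(NA_real_)
  mean(chA[use] != chB[use])
}

#' Progressive multiple alignment
#'
#' Clustal-like progressive alignment: a UPGMA guide tree is built from
#' pairwise Gotoh-alignment p-distances, then profiles are merged in
#' guide-tree order by profile-profile Gotoh alignment with sum-of-pairs
#' column scores. Gaps, once inserted, are never removed. Rows of the
#' result keep the input order.
#'
#' @param seqs named character vector of >= 2 residue strings (or a
#'   [SequenceFamily-class]).
#' @inheritParams pairwiseAlign
#' @return A [GappedAlignment-class] with provenance `"gotoh"`.
#' @export
progressiveAlign <- function(seqs, gop, gep, scores = NULL, alphabet = NULL) {
  .checkPenalty(gop, gep)
  seqs <- .asResidueVector(seqs)
  if (length(seqs) < 2L) stop("progressive alignment needs >= 2 sequences")
  if (any(!nzchar(seqs))) stop("cannot align an empty sequence")
  if (is.null(alphabet)) alphabet <- .inferAlphabet(seqs)
  if (is.null(scores))
    scores <- if (alphabet == "DNA") nucleotideScores() else proteinScores()
  letters_ok <- alphabetLetters(alphabet)
  ids <- names(seqs)
  if (length(seqs) == 2L) {
    aln <- pairwiseAlign(seqs[1L], seqs[2L], gop, gep, scores, alphabet)
    return(aln)
  }
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pa <- pairwiseAlign(seqs[i], seqs[j], gop, gep, scores, alphabet)
    d <- .pDistance(alnChars(pa)[1L, ], alnChars(pa)[2L, ])
    if (is.na(d)) d <- 1
    D[i, j] <- D[j, i] <- d
  }
  hc <- hclust(as.dist(D), method = "average")
  blocks <- lapply(seq_len(n), function(i)
    matrix(strsplit(seqs[i], "", fixed = TRUE)[[1L]], 1L,
           dimnames = list(ids[i], NULL)))
  merged <- vector("list", n - 1L)
  score <- NA_real_
  for (k in seq_len(n - 1L)) {
    pickBlock <- function(v) if (v < 0L) blocks[[-v]] else merged[[v]]
    res <- .profileAlign(pickBlock(hc$merge[k, 1L]), pickBlock(hc$merge[k, 2L]),
                         scores, gop, gep, letters_ok)
    merged[[k]] <- res$chars
    score <- res$score
  }
  chars <- merged[[n - 1L]][ids, , drop = FALSE]
  .newAlignment(chars, alphabet, gop = gop, gep = gep,
                provenance = "gotoh", score = score)
}

#' Drop every alignment column that contains a gap
#'
#' Mirrors complete-data likelihood analysis (PAML `cleandata`): only
#' columns with a residue in every row are kept, in their original order.
#'
#' @param aln a [GappedAlignment-class].
#' @return A [GappedAlignment-class] with the same rows and provenance.
#' @export
stripGapColumns <- function(aln) {
  stopifnot(is(aln, "GappedAlignment"))
  chars <- alnChars(aln)
  keep <- colSums(chars == GAP_CHAR) == 0L
  .newAlignment(chars[, keep, drop = FALSE], aln@alphabet,
                gop = aln@gop, gep = aln@gep, provenance = aln@provenance)
}

#' Pair two equal-length families without aligning them
#'
#' Builds the "no alignment" dataset: rows of both families stacked with
#' 1:1 site pairing and no gaps. All sequences must have equal length.
#'
#' @param famA,famB two [SequenceFamily-class] objects on the same alphabet.
#' @return A gap-free [GappedAlignment-class] with provenance `"none"`;
#'   rows are named `<gene>_<taxon>`.
#' @export
unalignedPairing <- function(famA, famB) {
  stopifnot(is(famA, "SequenceFamily"), is(famB, "SequenceFamily"))
  if (famA@alphabet != famB@alphabet) stop("families must share an alphabet")
  seqs <- c(setNames(residues(famA), paste(famA@gene, taxa(famA), sep = "_")),
            setNames(residues(famB), paste(famB@gene, taxa(famB), sep = "_")))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("no-alignment pairing needs equal-length sequences; got lengths ",
         paste(unique(len), collapse = ", "))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  .newAlignment(chars, famA@alphabet, provenance = "none")
}

## Family-vs-family profile alignment: each family is aligned on its own,
## then the two family profiles are merged with a single profile-profile
## Gotoh pass (the alternative co-alignment strategy of the sweep).
.profilePairAlign <- function(famA, famB, gop, gep, scores = NULL) {
  alphabet <- famA@alphabet
  if (is.null(scores))
    scores <- if (alphabet == "DNA") nucleotideScores() else proteinScores()
  letters_ok <- alphabetLetters(alphabet)
  blockOf <- function(fam) {
    seqs <- setNames(residues(fam), paste(fam@gene, taxa(fam), sep = "_"))
    alnChars(progressiveAlign(seqs, gop, gep, scores, alphabet))
  }
  res <- .profileAlign(blockOf(famA), blockOf(famB), scores, gop, gep,
                       letters_ok)
  .newAlignment(res$chars, alphabet, gop = gop, gep = gep,
                provenance = "gotoh", score = res$score)
}
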