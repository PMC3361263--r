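#' @import methods
#' @importFrom stats optim optimize pgamma qgamma hclust as.dist setNames
NULL

## Alphabets. DNA in ACGT order; amino acids in the PAML ordering used by
## the empirical rate-matrix tables (ARNDCQEGHILKMFPSTWYV).
DNA_LETTERS <- c("A", "C", "G", "T")
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHAR <- "-"

#' Residue letters of an alphabet
#'
#' @param alphabet `"DNA"` or `"AA"`.
#' @return Character vector of allowed residue letters (gap excluded).
#' @examples
#' alphabetLetters("DNA")
#' @export
alphabetLetters <- function(alphabet) {
  alphabet <- match.arg(alphabet, c("DNA", "AA"))
  if (alphabet == "DNA") DNA_LETTERS else AA_LETTERS
}

.checkAlphabet <- function(alphabet) {
  if (!(is.character(alphabet) && length(alphabet) == 1L &&
        alphabet %in% c("DNA", "AA")))
    return("alphabet must be \"DNA\" or \"AA\"")
  NULL
}

#' SequenceFamily: one gene family, one sequence per taxon
#'
#' A labelled set of unaligned, gap-free sequences for a single gene,
#' one per taxon. Residues are validated strictly against the alphabet:
#' ambiguity codes (N, X, ...) are rejected.
#'
#' @slot gene single gene label, e.g. `"cytb"`.
#' @slot taxa character vector of taxon labels, one per sequence.
#' @slot residues character vector of residue strings, parallel to `taxa`.
#' @slot alphabet `"DNA"` or `"AA"`.
#' @export
setClass("SequenceFamily",
  slots = c(gene = "character", taxa = "character",
            residues = "character", alphabet = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@gene) != 1L || !nzchar(object@gene))
      msg <- c(msg, "gene must be a single non-empty string")
    if (!is.null(.checkAlphabet(object@alphabet)))
      msg <- c(msg, .checkAlphabet(object@alphabet))
    if (length(object@taxa) != length(object@residues))
      msg <- c(msg, "taxa and residues must have equal length")
    if (anyDuplicated(object@taxa))
      msg <- c(msg, "taxon labels must be unique")
    if (length(msg) == 0L) {
      letters_ok <- alphabetLetters(object@alphabet)
      for (i in seq_along(object@residues)) {
        bad <- .firstIllegalResidue(object@residues[i], letters_ok)
        if (!is.na(bad))
          msg <- c(msg, sprintf(
            "illegal residue '%s' at position %d of sequence '%s'",
            substr(object@residues[i], bad, bad), bad, object@taxa[i]))
      }
    }
    if (length(msg)) msg else TRUE
  })

.firstIllegalResidue <- function(residues, letters_ok) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(ch %in% letters_ok))
  if (length(bad)) bad[1L] else NA_integer_
}

#' Construct a SequenceFamily
#'
#' @param gene gene label.
#' @param residues character vector of residue strings; names are used as
#'   taxon labels when `taxa` is missing.
#' @param taxa taxon labels.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return A [SequenceFamily-class] object.
#' @examples
#' sequenceFamily("toy", c(cow = "ACGT", deer = "ACGA"), alphabet = "DNA")
#' @export
sequenceFamily <- function(gene, residues, taxa = names(residues), alphabet) {
  if (is.null(taxa))
    stop("taxa must be given (or residues must be named)")
  new("SequenceFamily", gene = as.character(gene), taxa = as.character(taxa),
      residues = toupper(unname(residues)), alphabet = alphabet)
}

#' @describeIn SequenceFamily-class gene label accessor
#' @param object,x a `SequenceFamily`.
#' @export
setGeneric("geneName", function(object) standardGeneric("geneName"))

#' @export
setMethod("geneName", "SequenceFamily", function(object) object@gene)

#' @describeIn SequenceFamily-class taxon labels accessor
#' @export
setGeneric("taxa", function(object) standardGeneric("taxa"))

#' @export
setMethod("taxa", "SequenceFamily", function(object) object@taxa)

#' @describeIn SequenceFamily-class residue strings, named by taxon
#' @export
setGeneric("residues", function(object) standardGeneric("residues"))

#' @export
setMethod("residues", "SequenceFamily",
          function(object) setNames(object@residues, object@taxa))

#' @export
setMethod("length", "SequenceFamily", function(x) length(x@taxa))

setMethod("show", "SequenceFamily", function(object) {
  cat(sprintf("SequenceFamily '%s' (%s): %d sequences\n",
              object@gene, object@alphabet, length(object@taxa)))
  for (i in seq_along(object@taxa))
    cat(sprintf("  %-12s %d residues\n", object@taxa[i],
                nchar(object@residues[i])))
})

#' GappedAlignment: rectangular gapped residue matrix with provenance
#'
#' Rows are sequences (one residue per cell, `-` for gaps), columns are
#' alignment sites. `provenance` records how the object was made:
#' `"none"` (unaligned 1:1 pairing of equal-length sequences), `"gotoh"`
#' (built by the package's progressive aligner, with the gap penalties
#' used), or `"external"` (imported).
#'
#' @slot chars character matrix, rownames are sequence ids.
#' @slot alphabet `"DNA"` or `"AA"`.
#' @slot gop,gep gap-open and gap-extension penalties (`NA` unless
#'   `provenance == "gotoh"`).
#' @slot provenance `"none"`, `"gotoh"` or `"external"`.
#' @slot score optimal alignment score (`NA` unless produced by the aligner).
#' @export
setClass("GappedAlignment",
  slots = c(chars = "matrix", alphabet = "character",
            gop = "numeric", gep = "numeric",
            provenance = "character", score = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.character(object@chars))
      msg <- c(msg, "chars must be a character matrix")
    if (is.null(rownames(object@chars)) || anyDuplicated(rownames(object@chars)))
      msg <- c(msg, "chars must have unique rownames")
    if (!is.null(.checkAlphabet(object@alphabet)))
      msg <- c(msg, .checkAlphabet(object@alphabet))
    if (!(object@provenance %in% c("none", "gotoh", "external")))
      msg <- c(msg, "provenance must be 'none', 'gotoh' or 'external'")
    if (length(msg) == 0L) {
      ok <- c(alphabetLetters(object@alphabet), GAP_CHAR)
      if (length(object@chars) && !all(object@chars %in% ok))
        msg <- c(msg, "alignment contains characters outside alphabet + gap")
    }
    if (length(msg)) msg else TRUE
  })

.newAlignment <- function(chars, alphabet, gop = NA_real_, gep = NA_real_,
                          provenance = "external", score = NA_real_) {
  new("GappedAlignment", chars = chars, alphabet = alphabet,
      gop = gop, gep = gep, provenance = provenance, score = score)
}

#' @describeIn GappedAlignment-class number of alignment columns
#' @param object,x a `GappedAlignment`.
#' @export
setGeneric("alnWidth", function(object) standardGeneric("alnWidth"))

#' @export
setMethod("alnWidth", "GappedAlignment", function(object) ncol(object@chars))

#' @describeIn GappedAlignment-class residue character matrix accessor
#' @export
setGeneric("alnChars", function(object) standardGeneric("alnChars"))

#' @export
setMethod("alnChars", "GappedAlignment", function(object) object@chars)

#' @describeIn GappedAlignment-class `(gop, gep)` penalty accessor
#' @export
setGeneric("gapPenalty", function(object) standardGeneric("gapPenalty"))

#' @export
setMethod("gapPenalty", "GappedAlignment",
          function(object) c(gop = object@gop, gep = object@gep))

#' @describeIn GappedAlignment-class alignment score accessor
#' @export
setGeneric("alnScore", function(object) standardGeneric("alnScore"))

#' @export
setMethod("alnScore", "GappedAlignment", function(object) object@score)

#' @export
setMethod("dim", "GappedAlignment", function(x) dim(x@chars))

setMethod("show", "GappedAlignment", function(object) {
  prov <- switch(object@provenance,
    none = "unaligned 1:1 pairing",
    gotoh = sprintf("progressive alignment, (GOP, GEP) = (%g, %g)",
                    object@gop, object@gep),
    external = "imported alignment")
  cat(sprintf("GappedAlignment (%s): %d sequences x %d columns [%s]\n",
              object@alphabet, nrow(object@chars), ncol(object@chars), prov))
  w <- min(60L, ncol(object@chars))
  for (id in rownames(object@chars))
    cat(sprintf("  %-12s %s%s\n", id,
                paste(object@chars[id, seq_len(w)], collapse = ""),
                if (ncol(object@chars) > w) "..." else ""))
})

#' ModelSpec: a substitution model specification
#'
#' @slot family one of `"JC"`, `"K80"`, `"HKY"`, `"GTR"` (nucleotide) or
#'   `"Poisson"`, `"JTT"`, `"mtmam"` (amino acid).
#' @slot plusF logical; replace the empirical model's frequencies with
#'   observed data frequencies (protein families only).
#' @slot plusGamma logical; discrete-gamma rate heterogeneity.
#' @slot nCat number of gamma rate categories (default 4).
#' @slot countFreqs logical; whether data-estimated frequencies count as
#'   free parameters in the AIC dimension (default `TRUE`).
#' @export
setClass("ModelSpec",
  slots = c(family = "character", plusF = "logical", plusGamma = "logical",
            nCat = "integer", countFreqs = "logical"),
  validity = function(object) {
    msg <- character()
    fams <- c("JC", "K80", "HKY", "GTR", "Poisson", "JTT", "mtmam")
    if (!(length(object@family) == 1L && object@family %in% fams))
      msg <- c(msg, paste("family must be one of:", paste(fams, collapse = ", ")))
    if (isTRUE(object@plusF) &&
        object@family %in% c("JC", "K80", "HKY", "GTR"))
      msg <- c(msg, "+F applies to protein models only")
    if (object@nCat < 1L) msg <- c(msg, "nCat must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' FitResult: a maximised model fit on fixed topology
#'
#' @slot lnL maximised log-likelihood.
#' @slot estimates named list of parameter estimates (edge lengths per
#'   tree, `kappa`, `rates`, `alpha`, `freqs` as applicable).
#' @slot k free-parameter count (the AIC dimension).
#' @slot aic `2k - 2 lnL`.
#' @slot converged logical.
#' @slot spec the [ModelSpec-class] fitted.
#' @slot trees list of `phylo` trees with optimised edge lengths.
#' @export
setClass("FitResult",
  slots = c(lnL = "numeric", estimates = "list", k = "integer",
            aic = "numeric", converged = "logical", spec = "ModelSpec",
            trees = "list"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@aic, 2 * object@k - 2 * object@lnL,
                          tolerance = 1e-8)))
      msg <- c(msg, "aic must equal 2k - 2 lnL")
    if (object@lnL > 1e-9)
      msg <- c(msg, "log-likelihood of discrete data must be <= 0")
    if (length(msg)) msg else TRUE
  })

#' @export
setMethod("logLik", "FitResult", function(object, ...) {
  structure(object@lnL, df = object@k, class = "logLik")
})

#' @describeIn FitResult-class AIC accessor
#' @param object a `FitResult`.
#' @export
setGeneric("aicValue", function(object) standardGeneric("aicValue"))

#' @export
setMethod("aicValue", "FitResult", function(object) object@aic)

#' @describeIn FitResult-class parameter estimates accessor
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @export
setMethod("estimates", "FitResult", function(object) object@estimates)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: lnL = %.4f, k = %d, AIC = %.1f%s\n",
              modelLabel(object@spec), object@lnL, object@k, object@aic,
              if (!object@converged) " (NOT converged)" else ""))
})

#' Hypothesis: independent-origins or common-origin tree set
#'
#' The independent-origins hypothesis holds two disjoint 3-tip trees (no
#' branch connects the families); the common-origin hypothesis holds one
#' 6-tip unrooted tree whose central branch joins the two family subtrees.
#'
#' @slot name `"independent"` or `"common"`.
#' @slot trees list of `phylo` objects (two 3-tip trees, or one 6-tip tree).
#' @slot tipMap list (parallel to `trees`) of character vectors giving the
#'   alignment row name for each tree tip.
#' @export
setClass("Hypothesis",
  slots = c(name = "character", trees = "list", tipMap = "list"),
  validity = function(object) {
    msg <- character()
    if (!(object@name %in% c("independent", "common")))
      msg <- c(msg, "name must be 'independent' or 'common'")
    if (length(object@trees) != length(object@tipMap))
      msg <- c(msg, "trees and tipMap must be parallel lists")
    if (object@name == "independent" && length(object@trees) != 2L)
      msg <- c(msg, "independent hypothesis needs exactly two trees")
    if (object@name == "common" && length(object@trees) != 1L)
      msg <- c(msg, "common hypothesis needs exactly one tree")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Hypothesis", function(object) {
  nb <- sum(vapply(object@trees, function(tr) nrow(tr$edge), 1L))
  cat(sprintf("Hypothesis '%s': %d tree(s), %d free branch lengths\n",
              object@name, length(object@trees), nb))
})

#' AncestryReport: one grid point of the AIC sweep
#'
#' @slot table data.frame with one row per model: `model`,
#'   `aic_independent`, `aic_common`, `preferred`, `delta_aic`.
#' @slot homology homology statistic (1 - mean cross-family p-distance).
#' @slot nSites number of gap-free sites analysed.
#' @slot label dataset label, e.g. `"(GOP, GEP) = (15, 6.66) (999 bp)"`.
#' @slot bestModel label of the minimum-AIC model over both hypotheses.
#' @export
setClass("AncestryReport",
  slots = c(table = "data.frame", homology = "numeric", nSites = "integer",
            label = "character", bestModel = "character"),
  validity = function(object) {
    msg <- character()
    need <- c("model", "aic_independent", "aic_common", "preferred", "delta_aic")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
    if (length(msg) == 0L && nrow(object@table)) {
      tab <- object@table
      fine <- is.na(tab$aic_independent) | is.na(tab$aic_common)
      pref_ok <- ifelse(tab$aic_common < tab$aic_independent, "common", "independent")
      if (any(!fine & tab$preferred != pref_ok))
        msg <- c(msg, "preferred must be the lower-AIC hypothesis (ties -> independent)")
      if (any(!fine & abs(tab$delta_aic -
                          (tab$aic_independent - tab$aic_common)) > 1e-8))
        msg <- c(msg, "delta_aic must equal aic_independent - aic_common")
    }
    if (length(msg)) msg else TRUE
  })
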