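## The common-ancestry test: build the independent-origins and
## common-origin hypotheses for two 3-taxon gene families, fit both by
## maximum likelihood, compare by AIC, compute the homology statistic,
## and sweep substitution models x gap penalties.

#' Akaike information criterion
#'
#' @param lnL maximized log-likelihood.
#' @param k free-parameter count (>= 0).
#' @return `2 * k - 2 * lnL`.
#' @examples
#' aic(-100, 5)  # 210
#' @export
aic <- function(lnL, k) {
  stopifnot(is.numeric(lnL), is.numeric(k), k >= 0)
  2 * k - 2 * lnL
}

.famTips <- function(fam) paste(fam@gene, taxa(fam), sep = "_")

.tripleNewick <- function(labels, topology, lens = c(0.1, 0.1, 0.1, 0.05)) {
  ## rooted triple ((t1, t2), t3); as an unrooted 3-tip tree this is a star
  i <- match(topology, labels)
  sprintf("(%s:%g,%s:%g,%s:%g);", labels[i[1L]], lens[1L],
          labels[i[2L]], lens[2L], labels[i[3L]], lens[3L])
}

#' Build the independent-origins and common-origin hypotheses
#'
#' The independent-origins hypothesis is two disjoint unrooted 3-tip trees
#' (3 branches each, 6 in total) -- no branch connects the two gene
#' families. The common-origin hypothesis joins the two rooted triples
#' through a single central branch into one unrooted 6-tip tree with
#' `2 * 6 - 3 = 9` branches.
#'
#' @param famA,famB two [SequenceFamily-class] objects over the same 3
#'   taxa.
#' @param topology character vector of the 3 taxon labels as
#'   `(cherry1, cherry2, outgroup)`, i.e. `((t1, t2), t3)`; defaults to
#'   the taxon order of `famA`.
#' @return Named list with elements `independent` and `common`, both
#'   [Hypothesis-class] objects. Tree tips are named `<gene>_<taxon>`.
#' @export
buildHypotheses <- function(famA, famB, topology = taxa(famA)) {
  stopifnot(is(famA, "SequenceFamily"), is(famB, "SequenceFamily"))
  if (!setequal(taxa(famA), taxa(famB)) || length(taxa(famA)) != 3L)
    stop("both families must cover the same 3 taxa (got {",
         paste(taxa(famA), collapse = ", "), "} and {",
         paste(taxa(famB), collapse = ", "), "})")
  if (!setequal(topology, taxa(famA)) || length(topology) != 3L)
    stop("topology must list the 3 taxon labels")
  if (famA@gene == famB@gene) stop("the two families must have distinct genes")
  tipsA <- paste(famA@gene, topology, sep = "_")
  tipsB <- paste(famB@gene, topology, sep = "_")
  starA <- ape::read.tree(text = .tripleNewick(tipsA, tipsA))
  starB <- ape::read.tree(text = .tripleNewick(tipsB, tipsB))
  common <- ape::read.tree(text = sprintf(
    "((%s:0.1,%s:0.1):0.05,%s:0.1,((%s:0.1,%s:0.1):0.05,%s:0.1):0.5);",
    tipsA[1L], tipsA[2L], tipsA[3L], tipsB[1L], tipsB[2L], tipsB[3L]))
  list(independent = new("Hypothesis", name = "independent",
                         trees = list(starA, starB),
                         tipMap = list(tipsA, tipsB)),
       common = new("Hypothesis", name = "common", trees = list(common),
                    tipMap = list(c(tipsA, tipsB))))
}

#' Fit one ancestry hypothesis to a gap-free paired alignment
#'
#' The common-origin hypothesis is a single [maximizeLikelihood()] fit
#' over all six rows. The independent-origins hypothesis is two separate
#' fits (each family with its own substitution parameters and branch
#' lengths) whose log-likelihoods and parameter counts are summed;
#' `sharedParams = TRUE` instead shares substitution parameters (and
#' pooled frequencies) between the two family fits.
#'
#' @param hypothesis a [Hypothesis-class] from [buildHypotheses()].
#' @param aln gap-free [GappedAlignment-class] whose row names match the
#'   hypothesis tips.
#' @param spec a [ModelSpec-class].
#' @param sharedParams share substitution parameters across the two
#'   independent family fits (default `FALSE`).
#' @param control optimizer control, see [maximizeLikelihood()].
#' @return A [FitResult-class].
#' @export
fitHypothesis <- function(hypothesis, aln, spec, sharedParams = FALSE,
                          control = list()) {
  stopifnot(is(hypothesis, "Hypothesis"), is(aln, "GappedAlignment"))
  pats <- lapply(hypothesis@tipMap, function(tips)
    compressPatterns(aln, tipOrder = tips))
  if (hypothesis@name == "common" || sharedParams) {
    fit <- maximizeLikelihood(hypothesis@trees, pats, spec, control)
    return(fit)
  }
  fits <- lapply(seq_along(hypothesis@trees), function(i)
    maximizeLikelihood(hypothesis@trees[[i]], pats[[i]], spec, control))
  lnL <- sum(vapply(fits, function(f) f@lnL, numeric(1L)))
  k <- sum(vapply(fits, function(f) f@k, integer(1L)))
  new("FitResult", lnL = lnL,
      estimates = lapply(fits, estimates),
      k = k, aic = 2 * k - 2 * lnL,
      converged = all(vapply(fits, function(f) f@converged, logical(1L))),
      spec = spec, trees = unlist(lapply(fits, function(f) f@trees),
                                  recursive = FALSE))
}

#' Homology statistic: 1 - mean cross-family p-distance
#'
#' For each sequence pair the p-distance is the proportion of differing
#' sites among columns where both sequences carry a residue. The default
#' pairing averages over all cross-family pairs (9 for two 3-taxon
#' families); `"sameTaxon"` averages only over the 3 pairs from the same
#' taxon.
#'
#' @param x a [GappedAlignment-class] whose row names are
#'   `<gene>_<taxon>` for exactly two genes, or a list of two
#'   [SequenceFamily-class] objects of equal sequence length (the
#'   no-alignment case).
#' @param pairing `"cross"` or `"sameTaxon"`.
#' @return List with `value` (in `[0, 1]`), `pairing` and `nSites`.
#' @export
homologyStat <- function(x, pairing = c("cross", "sameTaxon")) {
  pairing <- match.arg(pairing)
  if (is.list(x) && length(x) == 2L && is(x[[1L]], "SequenceFamily"))
    x <- unalignedPairing(x[[1L]], x[[2L]])
  stopifnot(is(x, "GappedAlignment"))
  chars <- alnChars(x)
  ids <- rownames(chars)
  genes <- sub("_.*$", "", ids)
  if (length(unique(genes)) != 2L)
    stop("alignment rows must belong to exactly two genes (rows named ",
         "<gene>_<taxon>); found: ", paste(unique(genes), collapse = ", "))
  g <- unique(genes)
  rowsA <- which(genes == g[1L])
  rowsB <- which(genes == g[2L])
  if (ncol(chars) == 0L) stop("zero usable sites")
  pd <- c()
  for (i in rowsA) for (j in rowsB) {
    if (pairing == "sameTaxon" &&
        sub("^[^_]*_", "", ids[i]) != sub("^[^_]*_", "", ids[j])) next
    pd <- c(pd, .pDistance(chars[i, ], chars[j, ]))
  }
  if (!length(pd) || all(is.na(pd))) stop("zero usable sites")
  list(value = 1 - mean(pd, na.rm = TRUE), pairing = pairing,
       nSites = ncol(chars))
}

.specList <- function(specs, countFreqs = TRUE) {
  if (length(specs) == 0L) stop("at least one model spec is required")
  lapply(specs, function(s) {
    if (is(s, "ModelSpec")) s else parseModelSpec(s, countFreqs = countFreqs)
  })
}

#' Sweep substitution models across a gap-penalty grid
#'
#' For every grid entry the two families are turned into one gap-free
#' paired dataset -- `NULL` means the unaligned 1:1 site pairing, a
#' `c(gop, gep)` pair means joint progressive alignment of all six
#' sequences followed by removal of every gap-containing column -- and
#' every model is fitted under both hypotheses and compared by AIC.
#'
#' @param famA,famB two [SequenceFamily-class] objects over the same taxa.
#' @param specs list of [ModelSpec-class] objects or model labels
#'   (see [parseModelSpec()]).
#' @param grid list of gap-penalty entries: `NULL` (no alignment) or
#'   numeric `c(gop, gep)`.
#' @param topology rooted-triple topology, as in [buildHypotheses()].
#' @param sharedParams see [fitHypothesis()].
#' @param alignMode `"joint"` (progressive alignment of all six sequences,
#'   the default) or `"profile"` (align each family separately, then merge
#'   the two family profiles with one profile-profile alignment).
#' @param control optimizer control, see [maximizeLikelihood()].
#' @return List of [AncestryReport-class], one per grid entry. A failed
#'   fit leaves `NA` in that report row (with a warning) and the sweep
#'   continues.
#' @export
sweepGapPenalties <- function(famA, famB, specs, grid = list(NULL),
                              topology = taxa(famA), sharedParams = FALSE,
                              alignMode = c("joint", "profile"),
                              control = list()) {
  specs <- .specList(specs)
  alignMode <- match.arg(alignMode)
  hyps <- buildHypotheses(famA, famB, topology)
  unit <- if (famA@alphabet == "DNA") "bp" else "aa"
  lapply(grid, function(pen) {
    if (is.null(pen) || all(is.na(pen))) {
      aln <- unalignedPairing(famA, famB)
      label <- sprintf("No alignment (%d %s)", alnWidth(aln), unit)
    } else {
      seqs <- c(setNames(residues(famA), .famTips(famA)),
                setNames(residues(famB), .famTips(famB)))
      if (alignMode == "joint") {
        aln <- progressiveAlign(seqs, gop = pen[1L], gep = pen[2L],
                                alphabet = famA@alphabet)
      } else {
        aln <- .profilePairAlign(famA, famB, gop = pen[1L], gep = pen[2L])
      }
      aln <- stripGapColumns(aln)
      label <- sprintf("(GOP, GEP) = (%g, %g) (%d %s)",
                       pen[1L], pen[2L], alnWidth(aln), unit)
    }
    hom <- homologyStat(aln)
    rows <- lapply(specs, function(sp) {
      fitOne <- function(h) tryCatch(
        aicValue(fitHypothesis(h, aln, sp, sharedParams, control)),
        error = function(e) {
          warning("fit failed for ", modelLabel(sp), " (", h@name, "): ",
                  conditionMessage(e))
          NA_real_
        })
      ai <- fitOne(hyps$independent)
      ac <- fitOne(hyps$common)
      data.frame(model = modelLabel(sp), aic_independent = ai,
                 aic_common = ac,
                 preferred = if (any(is.na(c(ai, ac)))) NA_character_
                             else if (ac < ai) "common" else "independent",
                 delta_aic = ai - ac, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    best <- NA_character_
    if (any(!is.na(tab$aic_independent) | !is.na(tab$aic_common))) {
      mins <- pmin(tab$aic_independent, tab$aic_common, na.rm = TRUE)
      best <- tab$model[which.min(mins)]
    }
    new("AncestryReport", table = tab, homology = hom$value,
        nSites = as.integer(alnWidth(aln)), label = label, bestModel = best)
  })
}

#' Flatten sweep reports to a TSV-ready data frame
#'
#' Columns: `dataset_label`, `model`, `aic_independent`, `aic_common`,
#' `preferred`, `delta_aic`, `homology`.
#'
#' @param reports list of [AncestryReport-class] (or a single one).
#' @param path optional file; when given, the table is written as
#'   tab-separated text.
#' @return The data frame, invisibly when `path` is given.
#' @export
reportTable <- function(reports, path = NULL) {
  if (is(reports, "AncestryReport")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    cbind(dataset_label = r@label, r@table, homology = r@homology,
          stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

setMethod("show", "AncestryReport", function(object) {
  cat(sprintf("%s   Homology = %.3f\n", object@label, object@homology))
  cat(sprintf("%-12s %14s %14s\n", "Model", "Independent", "Common"))
  for (i in seq_len(nrow(object@table))) {
    r <- object@table[i, ]
    mark <- function(side) {
      if (is.na(r$preferred)) "" else if (r$preferred == side) " *" else "  "
    }
    cat(sprintf("%-12s %12.1f%s %12.1f%s\n", r$model,
                r$aic_independent, mark("independent"),
                r$aic_common, mark("common")))
  }
  cat(sprintf("Best model: %s\n", object@bestModel))
})

#' @describeIn AncestryReport-class per-model AIC table accessor
#' @param object an `AncestryReport`.
#' @export
setGeneric("reportRows", function(object) standardGeneric("reportRows"))

#' @export
setMethod("reportRows", "AncestryReport", function(object) object@table)

#' @describeIn AncestryReport-class homology statistic accessor
#' @export
setGeneric("homologyValue", function(object) standardGeneric("homologyValue"))

#' @export
setMethod("homologyValue", "AncestryReport", function(object) object@homology)
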