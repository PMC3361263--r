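## Sequence and alignment I/O: FASTA (Biostrings), sequential PHYLIP
## (PAML dialect), 5'-window trimming and vertebrate-mitochondrial
## translation.

#' Read sequences from a FASTA file
#'
#' Records are upper-cased and validated strictly against the alphabet;
#' ambiguity codes (N, X, ...) are rejected with the offending record and
#' position named. A terminal stop symbol `*` is stripped from protein
#' records. An empty file yields an empty vector.
#'
#' @param path FASTA file.
#' @param alphabet `"DNA"` or `"AA"`.
#' @return Named character vector of residue strings (names = record ids).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "ACGT"), tf)
#' readFasta(tf, "DNA")
#' @export
readFasta <- function(path, alphabet) {
  alphabet <- match.arg(alphabet, c("DNA", "AA"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in '", path,
                                           "': ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (alphabet == "AA") seqs <- sub("\\*$", "", seqs)
  letters_ok <- alphabetLetters(alphabet)
  for (i in seq_along(seqs)) {
    bad <- .firstIllegalResidue(seqs[i], letters_ok)
    if (!is.na(bad))
      stop(sprintf("illegal %s residue '%s' at position %d of record '%s'",
                   alphabet, substr(seqs[i], bad, bad), bad, ids[i]))
  }
  setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings, a
#'   [SequenceFamily-class], or a [GappedAlignment-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
  seqs <- .asResidueVector(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
  invisible(path)
}

.asResidueVector <- function(x) {
  if (is(x, "SequenceFamily")) return(residues(x))
  if (is(x, "GappedAlignment"))
    return(setNames(apply(alnChars(x), 1L, paste, collapse = ""),
                    rownames(alnChars(x))))
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(x)
  }
  stop("cannot interpret object of class ", class(x)[1L], " as sequences")
}

#' Write an alignment in sequential PHYLIP (PAML dialect)
#'
#' Header is `"<ntaxa> <ncols>"`; each taxon name is padded to at least 10
#' characters and followed by its full gapped row on one line. Round-trips
#' through [importAlignment()].
#'
#' @param alignment a [GappedAlignment-class] (or named character vector of
#'   equal-length strings).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writePhylip <- function(alignment, path) {
  seqs <- .asResidueVector(alignment)
  if (length(seqs) == 0L) stop("cannot write PHYLIP with 0 sequences")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("alignment is not rectangular: row lengths ",
         paste(unique(len), collapse = ", "))
  pad <- max(10L, max(nchar(names(seqs))) + 2L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(seqs), len[1L]), con)
  writeLines(sprintf("%-*s%s", pad, names(seqs), seqs), con)
  invisible(path)
}

#' Import a pre-computed alignment
#'
#' Reads a gapped FASTA or sequential PHYLIP alignment into a
#' [GappedAlignment-class] with provenance `"external"`. Rows must be
#' equal length.
#'
#' @param path alignment file.
#' @param alphabet `"DNA"` or `"AA"`.
#' @param format `"fasta"` or `"phylip"`; default guesses from the first
#'   non-blank character (`>` means FASTA).
#' @return A [GappedAlignment-class].
#' @export
importAlignment <- function(path, alphabet,
                            format = c("auto", "fasta", "phylip")) {
  alphabet <- match.arg(alphabet, c("DNA", "AA"))
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(trimws(readLines(path, n = 1L)), 1L, 1L)
    format <- if (identical(first, ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("malformed FASTA in '", path,
                                             "': ", conditionMessage(e)))
    seqs <- setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
  } else {
    type <- if (alphabet == "DNA") "DNA" else "AA"
    pd <- tryCatch(phangorn::read.phyDat(path, format = "sequential", type = type),
                   error = function(e) stop("cannot parse PHYLIP '", path,
                                            "': ", conditionMessage(e)))
    m <- toupper(as.character(pd))
    seqs <- setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
  }
  if (length(seqs) == 0L) stop("no sequences in '", path, "'")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("ragged alignment in '", path, "': row lengths ",
         paste(unique(len), collapse = ", "))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  .newAlignment(chars, alphabet, provenance = "external")
}

#' Take the 5'-terminal window of a coding sequence
#'
#' Returns `length` bases from the 5' end, optionally skipping the
#' initiation codon (the first 3 bases). Coordinates are 0-based
#' half-open: skipping returns bases `[3, 3 + length)`.
#'
#' @param seq a single nucleotide residue string.
#' @param length number of bases to keep.
#' @param skipInitiationCodon drop the first codon first (default `TRUE`).
#' @return Residue string of exactly `length` bases.
#' @examples
#' trim5Prime("ATGAAACCC", 6)            # "AAACCC"
#' trim5Prime("ATGAAACCC", 9, FALSE)     # identity
#' @export
trim5Prime <- function(seq, length, skipInitiationCodon = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, length >= 1L)
  offset <- if (skipInitiationCodon) 3L else 0L
  need <- offset + length
  if (nchar(seq) < need)
    stop(sprintf("sequence has %d bases but %d are required (%d + %s)",
                 nchar(seq), need, length,
                 if (skipInitiationCodon) "3 for the initiation codon" else "0"))
  substr(seq, offset + 1L, offset + length)
}

#' Translate with the vertebrate mitochondrial code
#'
#' Uses NCBI translation table 2 (so `TGA` is tryptophan and `ATA` is
#' methionine). The input length must be a multiple of 3 and must not
#' contain a stop codon.
#'
#' @param seq a single nucleotide residue string (ACGT only).
#' @return Amino-acid residue string of length `nchar(seq)/3`.
#' @examples
#' translateMito("TGAATAACG")  # "WMT"
#' @export
translateMito <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) %% 3L != 0L)
    stop("sequence length ", nchar(seq), " is not divisible by 3")
  bad <- .firstIllegalResidue(seq, DNA_LETTERS)
  if (!is.na(bad))
    stop(sprintf("illegal base '%s' at position %d", substr(seq, bad, bad), bad))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    genetic.code = Biostrings::getGeneticCode("2")))
  stops <- which(strsplit(aa, "", fixed = TRUE)[[1L]] == "*")
  if (length(stops))
    stop("stop codon at codon index ", stops[1L],
         " under the vertebrate mitochondrial code")
  aa
}

#' Translate every member of a nucleotide SequenceFamily
#'
#' @param family a DNA [SequenceFamily-class].
#' @return An AA [SequenceFamily-class] with the same gene and taxa.
#' @export
translateFamily <- function(family) {
  stopifnot(is(family, "SequenceFamily"), family@alphabet == "DNA")
  sequenceFamily(family@gene,
                 vapply(residues(family), translateMito, character(1L)),
                 alphabet = "AA")
}
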