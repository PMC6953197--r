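#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet matchPattern vmatchPattern reverseComplement
#'   alphabetFrequency PDict matchPDict startIndex IUPAC_CODE_MAP
#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors DataFrame elementNROWS
NULL

#' Restriction enzyme model
#'
#' A type II restriction enzyme is described by its recognition motif (IUPAC
#' nucleotide codes) and the offset of the top-strand cut within that motif.
#' For example ClaI recognises \code{ATCGAT} and cuts after the second base
#' (AT^CGAT), leaving compatible 5' overhangs whose re-ligation restores the
#' full site.
#'
#' @slot name single character, enzyme name.
#' @slot recognition single character, IUPAC recognition motif (length >= 4).
#' @slot cutOffset integer, 0 <= cutOffset <= nchar(recognition); number of
#'   motif bases left of the top-strand cut.
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  rec <- object@recognition
  if (length(rec) != 1L || nchar(rec) < 4L)
    msg <- c(msg, "'recognition' must be a single motif of length >= 4")
  else {
    bad <- setdiff(strsplit(toupper(rec), "")[[1]],
                   names(Biostrings::IUPAC_CODE_MAP))
    if (length(bad))
      msg <- c(msg, paste0("invalid IUPAC code(s) in motif: ",
                           paste(unique(bad), collapse = ", ")))
  }
  off <- object@cutOffset
  if (length(off) != 1L || is.na(off) || off < 0L ||
      (length(rec) == 1L && off > nchar(rec)))
    msg <- c(msg, "'cutOffset' must be in [0, nchar(recognition)]")
  if (length(msg)) msg else TRUE
})

#' Construct a restriction enzyme
#'
#' @param name enzyme name, e.g. \code{"ClaI"}.
#' @param recognition IUPAC recognition motif, e.g. \code{"ATCGAT"}.
#' @param cutOffset 0-based offset of the top-strand cut within the motif
#'   (ClaI AT^CGAT has \code{cutOffset = 2}).
#' @return A \linkS4class{RestrictionEnzyme} object.
#' @examples
#' restrictionEnzyme("ClaI", "ATCGAT", 2)
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = as.character(name),
      recognition = toupper(as.character(recognition)),
      cutOffset = as.integer(cutOffset))
}

#' @describeIn restrictionEnzyme enzyme name accessor
#' @param x a \code{RestrictionEnzyme}.
#' @export
enzymeName <- function(x) x@name

#' @describeIn restrictionEnzyme recognition motif accessor
#' @export
recognitionSite <- function(x) x@recognition

#' @describeIn restrictionEnzyme cut offset accessor
#' @export
cutOffset <- function(x) x@cutOffset

#' @describeIn restrictionEnzyme motif length in bp
#' @export
motifLength <- function(x) nchar(x@recognition)

#' @describeIn restrictionEnzyme is the motif its own reverse complement?
#' @export
isPalindromic <- function(x) {
  rc <- as.character(reverseComplement(DNAString(x@recognition)))
  identical(rc, x@recognition)
}

setMethod("show", "RestrictionEnzyme", function(object) {
  rec <- object@recognition
  cut <- paste0(substr(rec, 1, object@cutOffset), "^",
                substr(rec, object@cutOffset + 1L, nchar(rec)))
  cat("RestrictionEnzyme", object@name, ":", cut,
      if (isPalindromic(object)) "(palindromic)" else "(non-palindromic)",
      "\n")
})

#' Built-in enzymes
#'
#' The two 6-cutters used for BAC-end junction libraries in this package:
#' ClaI (AT^CGAT) and MluI (A^CGCGT). Both are palindromic.
#'
#' @return \code{builtinEnzymes()} returns a named list of
#'   \linkS4class{RestrictionEnzyme} objects; \code{enzyme(name)} returns one
#'   by name (built-in or from \code{config}).
#' @examples
#' enzyme("ClaI")
#' @export
builtinEnzymes <- function() {
  list(ClaI = restrictionEnzyme("ClaI", "ATCGAT", 2L),
       MluI = restrictionEnzyme("MluI", "ACGCGT", 1L))
}

#' @rdname builtinEnzymes
#' @param name enzyme name.
#' @param config optional enzyme list, e.g. from \code{readEnzymeConfig()},
#'   searched before the built-ins.
#' @export
enzyme <- function(name, config = NULL) {
  pool <- c(config, builtinEnzymes())
  if (!name %in% names(pool))
    stop_input("unknown enzyme '", name, "'; known: ",
               paste(names(pool), collapse = ", "))
  pool[[name]]
}

#' Read enzyme definitions from a config file
#'
#' Expects a tab-separated file with columns \code{name}, \code{recognition}
#' and \code{cut_offset} (header required). Motifs are validated as IUPAC.
#'
#' @param path path to the TSV config.
#' @return named list of \linkS4class{RestrictionEnzyme} objects.
#' @export
readEnzymeConfig <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "recognition", "cut_offset")
  if (!all(need %in% names(tab)))
    stop_input("enzyme config must have columns: ",
               paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    restrictionEnzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i]))
  names(out) <- tab$name
  out
}
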