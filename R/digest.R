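#' Find restriction sites in a sequence
#'
#' Scans a nucleotide sequence for all (possibly overlapping) matches of an
#' enzyme's IUPAC recognition motif. Palindromic motifs need only a
#' forward-strand scan; for non-palindromic motifs the reverse-complement
#' motif is also scanned (on the forward sequence) and reported with strand
#' \code{"-"}. Bases outside the motif's IUPAC sets never match; in
#' particular an \code{N} in the sequence never supports a site call.
#'
#' @param sequence a single character string or \code{DNAString} (A/C/G/T/N,
#'   case-insensitive).
#' @param enz a \linkS4class{RestrictionEnzyme}.
#' @return data.frame with columns \code{start} (1-based motif start,
#'   ascending) and \code{strand} (\code{"+"}/\code{"-"}).
#' @examples
#' findSites("GGATCGATGGGATCGATGG", enzyme("ClaI"))
#' @export
findSites <- function(sequence, enz) {
  stopifnot(is(enz, "RestrictionEnzyme"))
  subj <- DNAString(as_seq_chr(sequence))
  pat <- DNAString(recognitionSite(enz))
  st <- start(matchPattern(pat, subj, fixed = "subject"))
  strand <- rep("+", length(st))
  if (!isPalindromic(enz)) {
    st2 <- start(matchPattern(reverseComplement(pat), subj,
                              fixed = "subject"))
    strand <- c(strand, rep("-", length(st2)))
    st <- c(st, st2)
  }
  o <- order(st, strand)
  data.frame(start = as.integer(st[o]), strand = strand[o])
}

#' Digest a linear sequence in silico
#'
#' Complete digestion: every motif match contributes a cut at
#' \code{site start + cutOffset}; the fragments tile the sequence exactly
#' (fragments = sites + 1 on a linear molecule). A sequence with no site
#' yields itself as a single fragment.
#'
#' @inheritParams findSites
#' @return \code{IRanges} of fragment intervals (1-based closed) tiling the
#'   sequence.
#' @examples
#' width(digestLinear("GGATCGATGGGATCGATGG", enzyme("ClaI")))  # 4 9 6
#' @export
digestLinear <- function(sequence, enz) {
  seqc <- as_seq_chr(sequence)
  len <- nchar(seqc)
  sites <- findSites(seqc, enz)
  # cut point in "bases before the cut" units; dedupe coincident cuts and
  # drop cuts at the very ends, which would create empty fragments
  cuts <- sort(unique(sites$start - 1L + cutOffset(enz)))
  cuts <- cuts[cuts > 0L & cuts < len]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  IRanges(start = starts, end = ends)
}

#' Genome-wide digestion profile
#'
#' Aggregates \code{digestLinear()} over every sequence of a genome and
#' reports per-sequence and total site counts, fragment counts and mean
#' fragment lengths. This is the in-silico digestion used to choose an
#' enzyme for a junction library: a 6-cutter on a typical genome yields
#' fragments of a few kb, so clone-end junction gaps concentrate just below
#' the insert size.
#'
#' @param genome a \code{DNAStringSet}, or path to a (optionally gzipped)
#'   FASTA file.
#' @param enz a \linkS4class{RestrictionEnzyme}.
#' @return object of class \code{DigestSummary}: list with \code{enzyme},
#'   \code{total_sites}, \code{fragment_count}, \code{mean_fragment_length}
#'   and \code{per_chrom} (data.frame seq_id, length, sites, fragments,
#'   mean_length).
#' @export
digestProfile <- function(genome, enz) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop_input("empty genome")
  per <- lapply(seq_along(genome), function(i) {
    frags <- digestLinear(as.character(genome[[i]]), enz)
    data.frame(seq_id = names(genome)[i],
               length = length(genome[[i]]),
               sites = nrow(findSites(as.character(genome[[i]]), enz)),
               fragments = length(frags),
               mean_length = mean(width(frags)))
  })
  per <- do.call(rbind, per)
  out <- list(enzyme = enzymeName(enz),
              total_sites = sum(per$sites),
              fragment_count = sum(per$fragments),
              mean_fragment_length = sum(per$length) / sum(per$fragments),
              per_chrom = per)
  class(out) <- "DigestSummary"
  out
}

#' @export
print.DigestSummary <- function(x, ...) {
  cat("In-silico digest [", x$enzyme, "]: ", x$total_sites, " sites, ",
      x$fragment_count, " fragments, mean ",
      round(x$mean_fragment_length, 1), " bp over ",
      nrow(x$per_chrom), " sequence(s)\n", sep = "")
  invisible(x)
}

#' Write a digestion profile to disk
#'
#' Writes the per-sequence table as TSV and the totals as JSON.
#'
#' @param x a \code{DigestSummary}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return invisibly, the two paths written.
#' @export
writeDigestSummary <- function(x, prefix) {
  stopifnot(inherits(x, "DigestSummary"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  utils::write.table(x$per_chrom, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(x[c("enzyme", "total_sites", "fragment_count",
                           "mean_fragment_length")],
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

# accept a DNAStringSet or a FASTA path
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop_input("FASTA not found: ", genome)
    genome <- tryCatch(readDNAStringSet(genome),
                       error = function(e)
                         stop_input("unreadable FASTA: ", conditionMessage(e)))
  }
  stopifnot(is(genome, "DNAStringSet"))
  if (length(genome) == 0L) return(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  # FASTA headers may carry descriptions; keep the first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}
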