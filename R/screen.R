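#' Screening results
#'
#' Container returned by \code{\link{screenReads}} / \code{\link{screenFastq}}:
#' the emitted split reads plus conservation-checked screening statistics.
#'
#' @slot splits data.frame of split reads, one row per emitted read, columns
#'   \code{read_id}, \code{mate}, \code{sequence}, \code{site_pos} (1-based
#'   motif start within the read), \code{site_strand}, \code{left_flank},
#'   \code{right_flank}, \code{enzyme}, \code{n_sites_in_read}.
#' @slot stats named integer vector: \code{total}, \code{with_site},
#'   \code{no_site}, \code{rejected_flank}, \code{skipped}, \code{emitted};
#'   \code{total = no_site + rejected_flank + skipped + emitted}.
#' @export
setClass("ScreenResult",
  representation(splits = "data.frame", stats = "integer"))

setValidity("ScreenResult", function(object) {
  s <- object@stats
  need <- c("total", "with_site", "no_site", "rejected_flank", "skipped",
            "emitted")
  if (!all(need %in% names(s)))
    return(paste("stats must contain:", paste(need, collapse = ", ")))
  if (s["total"] != s["no_site"] + s["rejected_flank"] + s["skipped"] +
      s["emitted"])
    return("screening counts are not conserved")
  if (s["emitted"] != nrow(object@splits))
    return("emitted count does not match number of split reads")
  TRUE
})

#' @describeIn ScreenResult-class split-read table accessor
#' @param x a \code{ScreenResult}.
#' @export
splitReads <- function(x) x@splits

#' @describeIn ScreenResult-class screening statistics accessor
#' @export
screenStats <- function(x) x@stats

setMethod("show", "ScreenResult", function(object) {
  s <- object@stats
  cat("ScreenResult:", s["total"], "reads;", s["with_site"],
      "carried a site;", s["emitted"], "split reads emitted\n")
  cat("  (no site:", s["no_site"], "| flank too short:", s["rejected_flank"],
      "| skipped:", s["skipped"], ")\n")
})

empty_splits <- function() {
  data.frame(read_id = character(), mate = character(),
             sequence = character(), site_pos = integer(),
             site_strand = character(), left_flank = character(),
             right_flank = character(), enzyme = character(),
             n_sites_in_read = integer())
}

#' Screen reads for an enzyme cut site and split them into flanks
#'
#' A read is selected when its sequence carries a match of the enzyme's
#' recognition motif with at least \code{minFlank} bases on both sides of
#' the motif. Selected reads are split at the motif: the flank before the
#' motif (\code{left_flank}) and after it (\code{right_flank}) are the two
#' anchors later aligned independently; the motif bases themselves belong to
#' neither flank. When several sites qualify, the one maximising the shorter
#' flank is chosen (ties: leftmost), which maximises the weaker anchor.
#' Reads containing letters other than A/C/G/T/N are skipped.
#'
#' @param reads named \code{DNAStringSet} (or named character vector) of
#'   read sequences.
#' @param enz a \linkS4class{RestrictionEnzyme}.
#' @param minFlank minimum flank length in bp on each side of the motif
#'   (default 19, i.e. more than 18 bp).
#' @param mate label stored in the \code{mate} column (\code{"single"},
#'   \code{"R1"} or \code{"R2"}).
#' @return a \linkS4class{ScreenResult}.
#' @examples
#' r <- Biostrings::DNAStringSet(c(a = paste0(strrep("A", 20), "ATCGAT",
#'                                            strrep("C", 20))))
#' splitReads(screenReads(r, enzyme("ClaI")))
#' @export
screenReads <- function(reads, enz, minFlank = 19L, mate = "single") {
  stopifnot(is(enz, "RestrictionEnzyme"), minFlank >= 1L)
  if (is.character(reads)) reads <- DNAStringSet(toupper(reads))
  n <- length(reads)
  if (n > 0L && is.null(names(reads)))
    names(reads) <- paste0("read", seq_len(n))
  stats <- c(total = n, with_site = 0L, no_site = 0L, rejected_flank = 0L,
             skipped = 0L, emitted = 0L)
  if (n == 0L)
    return(new("ScreenResult", splits = empty_splits(), stats = stats))

  af <- alphabetFrequency(reads)
  ok_letters <- rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE]) ==
    width(reads)
  stats["skipped"] <- sum(!ok_letters)
  if (stats["skipped"] > 0L)
    warning(stats["skipped"], " read(s) with non-ACGTN letters skipped")

  pat <- DNAString(recognitionSite(enz))
  L <- motifLength(enz)
  hits <- vmatchPattern(pat, reads, fixed = "subject")
  starts <- lapply(hits, start)
  strands <- lapply(starts, function(s) rep("+", length(s)))
  if (!isPalindromic(enz)) {
    hits2 <- vmatchPattern(reverseComplement(pat), reads, fixed = "subject")
    starts <- mapply(c, starts, lapply(hits2, start), SIMPLIFY = FALSE)
    strands <- mapply(function(a, b) c(a, rep("-", length(b))),
                      strands, lapply(hits2, start), SIMPLIFY = FALSE)
  }

  seqs <- as.character(reads)
  wid <- width(reads)
  sel_pos <- integer(n)       # chosen site start, 0 = none selected
  sel_strand <- character(n)
  nsites <- lengths(starts)
  for (i in seq_len(n)) {
    if (!ok_letters[i] || nsites[i] == 0L) next
    st <- starts[[i]]
    left <- st - 1L
    right <- wid[i] - (st - 1L) - L
    ok <- left >= minFlank & right >= minFlank
    if (!any(ok)) next
    sc <- pmin(left, right)
    sc[!ok] <- -1L
    j <- which.max(sc)  # ties: leftmost
    sel_pos[i] <- st[j]
    sel_strand[i] <- strands[[i]][j]
  }
  stats["no_site"] <- sum(ok_letters & nsites == 0L)
  stats["with_site"] <- sum(ok_letters & nsites > 0L)
  stats["rejected_flank"] <- sum(ok_letters & nsites > 0L & sel_pos == 0L)
  emit <- which(sel_pos > 0L)
  stats["emitted"] <- length(emit)
  splits <- if (length(emit)) data.frame(
    read_id = names(reads)[emit], mate = mate, sequence = seqs[emit],
    site_pos = sel_pos[emit], site_strand = sel_strand[emit],
    left_flank = substr(seqs[emit], 1L, sel_pos[emit] - 1L),
    right_flank = substr(seqs[emit], sel_pos[emit] + L, wid[emit]),
    enzyme = enzymeName(enz), n_sites_in_read = nsites[emit])
  else empty_splits()
  rownames(splits) <- NULL
  new("ScreenResult", splits = splits, stats = stats)
}

#' @describeIn screenReads screen a single read; returns a one-row
#'   data.frame, or \code{NULL} when the read is not selected.
#' @param sequence single read sequence.
#' @param id read identifier.
#' @export
screenRead <- function(sequence, id, enz, minFlank = 19L, mate = "single") {
  x <- DNAStringSet(toupper(as.character(sequence)))
  names(x) <- id
  res <- screenReads(x, enz, minFlank = minFlank, mate = mate)
  if (nrow(splitReads(res)) == 0L) NULL else splitReads(res)
}

#' Screen FASTQ files
#'
#' Applies \code{\link{screenReads}} to one or two (R1/R2) FASTQ files,
#' gzipped or plain. Paired files are screened independently read-by-read:
#' a pair may contribute up to two split reads, matching the per-read
#' accounting of junction-library profiling.
#'
#' @param files character vector of one or two FASTQ paths.
#' @inheritParams screenReads
#' @return a \linkS4class{ScreenResult} with pooled statistics.
#' @export
screenFastq <- function(files, enz, minFlank = 19L) {
  stopifnot(length(files) %in% 1:2)
  mates <- if (length(files) == 2L) c("R1", "R2") else "single"
  parts <- lapply(seq_along(files), function(i) {
    f <- files[i]
    if (!file.exists(f)) stop_input("FASTQ not found: ", f)
    con <- gzfile(f, "r")
    nlines <- length(readLines(con, warn = FALSE))
    close(con)
    if (nlines %% 4L != 0L)
      stop_input("truncated FASTQ '", f, "': record ", nlines %/% 4L + 1L,
                 " is incomplete")
    reads <- tryCatch(readDNAStringSet(f, format = "fastq"),
                      error = function(e)
                        stop_input("malformed FASTQ '", f, "': ",
                                   conditionMessage(e)))
    names(reads) <- sub("\\s.*$", "", names(reads))
    screenReads(reads, enz, minFlank = minFlank, mate = mates[i])
  })
  splits <- do.call(rbind, lapply(parts, splitReads))
  stats <- Reduce(`+`, lapply(parts, screenStats))
  new("ScreenResult", splits = splits, stats = stats)
}

#' Deduplicate split reads by sequence
#'
#' Keeps the first occurrence of each exact read sequence (optionally of the
#' lexicographic minimum of the sequence and its reverse complement, so that
#' a read and its reverse-complement duplicate collapse). Order is otherwise
#' preserved; the operation is idempotent.
#'
#' @param splits split-read data.frame from \code{\link{screenReads}}.
#' @param canonical collapse reverse-complement duplicates too
#'   (default \code{FALSE}).
#' @return list with \code{splits} (deduplicated data.frame) and
#'   \code{counts = c(input, unique)}.
#' @export
dedupeBySequence <- function(splits, canonical = FALSE) {
  key <- splits$sequence
  if (canonical && nrow(splits) > 0L) {
    rc <- as.character(reverseComplement(DNAStringSet(key)))
    key <- pmin(key, rc)
  }
  keep <- !duplicated(key)
  out <- splits[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(splits = out,
       counts = c(input = nrow(splits), unique = nrow(out)))
}

#' Write flank sequences for external alignment
#'
#' Writes every split read's two flanks as FASTA records named
#' \code{<read_id>|L} and \code{<read_id>|R}, the naming contract expected
#' by \code{\link{readFlankSam}} when alignments come back from an external
#' aligner.
#'
#' @param splits split-read data.frame.
#' @param path output FASTA path.
#' @return invisibly, \code{path}.
#' @export
writeFlankFasta <- function(splits, path) {
  seqs <- DNAStringSet(c(splits$left_flank, splits$right_flank))
  names(seqs) <- c(paste0(splits$read_id, "|L"),
                   paste0(splits$read_id, "|R"))
  # interleave L/R per read for readability
  o <- order(rep(seq_len(nrow(splits)), 2L))
  writeXStringSet(seqs[o], path)
  invisible(path)
}

#' Write split-read metadata as TSV
#'
#' @param splits split-read data.frame.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeSplitReads <- function(splits, path) {
  utils::write.table(splits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
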