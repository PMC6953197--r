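empty_alignments <- function() {
  data.frame(read_id = character(), side = character(), mapped = logical(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), mapq = integer(),
             has_secondary = logical())
}

#' Exact-match toy aligner for split-read flanks
#'
#' Places each flank of each split read on the reference by exhaustive
#' exact-match search of the full flank sequence, forward and
#' reverse-complement. A flank with exactly one hit across both strands is
#' reported with MAPQ 60; a flank with several hits gets MAPQ 0 and
#' \code{has_secondary = TRUE} (first hit, by chromosome then position, kept
#' as primary); a flank with no hit is unmapped. This is a test-scoped
#' stand-in for a real short-read aligner: no mismatches, no indels, no
#' soft-clipping.
#'
#' Internally, candidate loci are found with a constant-width seed
#' dictionary (\code{Biostrings::PDict} on the first \code{seedWidth} bases
#' of each flank / reverse-complemented flank) and verified over the full
#' flank length, which is equivalent to the naive search but linear in
#' genome size.
#'
#' @param splits split-read data.frame from \code{\link{screenReads}}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param seedWidth seed length for the candidate search; must not exceed
#'   the shortest flank (default: shortest flank, capped at 19).
#' @return alignment data.frame with one row per flank (mapped or not):
#'   \code{read_id}, \code{side} (L/R), \code{mapped}, \code{chrom},
#'   \code{start}, \code{end} (1-based closed), \code{strand}, \code{mapq},
#'   \code{has_secondary}.
#' @export
alignFlanksToy <- function(splits, genome, seedWidth = NULL) {
  genome <- as_genome(genome)
  if (nrow(splits) == 0L) return(empty_alignments())
  pats <- c(splits$left_flank, splits$right_flank)
  ids <- rep(splits$read_id, 2L)
  sides <- rep(c("L", "R"), each = nrow(splits))
  plen <- nchar(pats)
  if (is.null(seedWidth)) seedWidth <- min(19L, min(plen))
  if (seedWidth > min(plen))
    stop_input("seedWidth exceeds the shortest flank (", min(plen), " bp)")

  rc <- as.character(reverseComplement(DNAStringSet(pats)))
  hits <- find_exact_hits(pats, rc, plen, genome, seedWidth)

  n <- length(pats)
  nhits <- tabulate(hits$pat, nbins = n)
  # primary hit per pattern: first by chromosome, then position, then strand
  o <- order(hits$pat, match(hits$chrom, names(genome)), hits$start,
             hits$strand)
  first <- o[!duplicated(hits$pat[o])]
  pi <- hits$pat[first]

  res <- data.frame(read_id = ids, side = sides, mapped = nhits > 0L,
                    chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    mapq = NA_integer_, has_secondary = nhits > 1L)
  res$chrom[pi] <- hits$chrom[first]
  res$start[pi] <- hits$start[first]
  res$end[pi] <- hits$start[first] + plen[pi] - 1L
  res$strand[pi] <- hits$strand[first]
  res$mapq[pi] <- ifelse(nhits[pi] == 1L, 60L, 0L)
  res <- res[order(match(res$read_id, splits$read_id), res$side), ]
  rownames(res) <- NULL
  res
}

# seed-and-verify exact search; returns data.frame(pat, chrom, start, strand)
# with one row per verified exact hit of the full pattern
find_exact_hits <- function(pats, rc, plen, genome, w) {
  n <- length(pats)
  seeds <- DNAStringSet(substr(c(pats, rc), 1L, w))
  pd <- PDict(seeds)
  acc <- list()
  for (ci in seq_along(genome)) {
    chr_char <- as.character(genome[[ci]])
    clen <- nchar(chr_char)
    m <- matchPDict(pd, genome[[ci]])
    sidx <- Biostrings::startIndex(m)
    lens <- lengths(sidx)
    if (sum(lens) == 0L) next
    k <- rep.int(seq_along(lens), lens)       # seed index per candidate
    cand <- unlist(sidx, use.names = FALSE)
    fwd <- k <= n
    i <- k - n * (!fwd)                       # pattern index
    full <- c(pats, rc)[k]
    ok <- cand + plen[i] - 1L <= clen
    ok[ok] <- substring(chr_char, cand[ok],
                        cand[ok] + plen[i[ok]] - 1L) == full[ok]
    if (!any(ok)) next
    acc[[length(acc) + 1L]] <- data.frame(
      pat = i[ok], chrom = names(genome)[ci], start = cand[ok],
      strand = ifelse(fwd[ok], "+", "-"))
  }
  if (!length(acc))
    return(data.frame(pat = integer(), chrom = character(),
                      start = integer(), strand = character()))
  do.call(rbind, acc)
}

#' Load flank alignments from a SAM file
#'
#' Parses primary alignment records of flanks named \code{<read_id>|L} /
#' \code{<read_id>|R} (the contract of \code{\link{writeFlankFasta}}) into
#' the alignment table consumed by \code{\link{classifyJunctions}}.
#' Secondary/supplementary records (FLAG 0x100/0x800) are not used for
#' pairing but mark the primary record's \code{has_secondary}; records with
#' the unmapped flag (0x4) yield an unmapped flank. The reference interval
#' is computed from POS and the CIGAR reference-consuming operations
#' (M/D/N/=/X); SAM's 1-based coordinates are kept as 1-based closed
#' intervals.
#'
#' @param path SAM file path.
#' @return alignment data.frame as in \code{\link{alignFlanksToy}}.
#' @export
readFlankSam <- function(path) {
  if (!file.exists(path)) stop_input("SAM not found: ", path)
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  rows <- vector("list", length(body))
  sec <- character()
  for (j in seq_along(body)) {
    ln <- body[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop_input("malformed SAM line ", ln, ": fewer than 11 fields")
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stop_input("malformed SAM line ", ln, ": non-numeric FLAG/POS/MAPQ")
    qname <- f[1]
    if (!grepl("\\|[LR]$", qname)) {
      warning("SAM record '", qname, "' lacks the |L / |R suffix; skipped")
      next
    }
    id <- sub("\\|[LR]$", "", qname)
    side <- sub("^.*\\|", "", qname)
    if (bitwAnd(flag, 0x100L) > 0L || bitwAnd(flag, 0x800L) > 0L) {
      sec <- c(sec, qname)
      next
    }
    if (bitwAnd(flag, 0x4L) > 0L) {
      rows[[j]] <- data.frame(read_id = id, side = side, mapped = FALSE,
                              chrom = NA_character_, start = NA_integer_,
                              end = NA_integer_, strand = NA_character_,
                              mapq = NA_integer_, has_secondary = FALSE)
      next
    }
    rows[[j]] <- data.frame(
      read_id = id, side = side, mapped = TRUE, chrom = f[3],
      start = pos, end = pos + cigar_ref_width(f[6], ln) - 1L,
      strand = if (bitwAnd(flag, 0x10L) > 0L) "-" else "+",
      mapq = mapq, has_secondary = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty_alignments())
  key <- paste0(out$read_id, "|", out$side)
  out$has_secondary <- key %in% sec
  rownames(out) <- NULL
  out
}

cigar_ref_width <- function(cigar, line) {
  if (cigar == "*") return(1L)
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L)
    stop_input("malformed SAM line ", line, ": bad CIGAR '", cigar, "'")
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^\\d+", "", toks)
  w <- sum(n[op %in% c("M", "D", "N", "=", "X")])
  max(w, 1L)
}
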