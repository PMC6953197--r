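#' Classified junction calls
#'
#' Container returned by \code{\link{classifyJunctions}}: one call per read,
#' plus the filtering parameters used.
#'
#' @slot calls data.frame, one row per read: \code{read_id},
#'   \code{category} (MATCH_SAME_CHR / MATCH_DIFF_CHR / NO_MATCH),
#'   \code{subtype} (BAC_END / INSERTION / DISCORDANT_STRAND / NA),
#'   \code{uniqueness} (UNIQUE / MULTI / NA), \code{gap} (bp, same-chromosome
#'   concordant calls only), \code{in_gap_window}, and the anchor
#'   coordinates \code{chromL}, \code{innerL}, \code{strandL}, \code{chromR},
#'   \code{innerR}, \code{strandR}. Inner coordinates are junction offsets
#'   (number of reference bases before the flank's inner edge), so two
#'   abutting flanks have gap 0.
#' @slot params named list: \code{mapq_min}, \code{gap_min}, \code{gap_max}.
#' @export
setClass("JunctionCallSet",
  representation(calls = "data.frame", params = "list"))

setValidity("JunctionCallSet", function(object) {
  cl <- object@calls
  need <- c("read_id", "category", "subtype", "uniqueness", "gap",
            "in_gap_window", "chromL", "innerL", "strandL", "chromR",
            "innerR", "strandR")
  if (!all(need %in% names(cl)))
    return(paste("calls must contain:", paste(need, collapse = ", ")))
  if (any(!is.na(cl$gap) & cl$gap < 0))
    return("negative gap")
  bad <- cl$category != "MATCH_SAME_CHR" & !is.na(cl$gap)
  if (any(bad))
    return("gap must be absent outside MATCH_SAME_CHR")
  p <- object@params
  if (!is.null(p$gap_min) && !is.null(p$gap_max) && p$gap_min >= p$gap_max)
    return("gap_min must be < gap_max")
  TRUE
})

#' @describeIn JunctionCallSet-class calls table accessor
#' @param x a \code{JunctionCallSet}.
#' @export
junctionCalls <- function(x) x@calls

#' @describeIn JunctionCallSet-class classification parameters accessor
#' @export
callParams <- function(x) x@params

setMethod("show", "JunctionCallSet", function(object) {
  cl <- object@calls
  cat("JunctionCallSet:", nrow(cl), "reads\n")
  if (nrow(cl)) {
    print(table(category = cl$category))
    same <- cl$category == "MATCH_SAME_CHR"
    if (any(same)) print(table(subtype = cl$subtype[same],
                               uniqueness = cl$uniqueness[same]))
  }
})

#' Classify flank-alignment pairs into junction calls
#'
#' For each read, the placements of its two flanks are compared:
#' \itemize{
#' \item neither flank mapped: \code{NO_MATCH};
#' \item exactly one mapped, or the two on different chromosomes:
#'   \code{MATCH_DIFF_CHR};
#' \item both on the same chromosome and strand: \code{MATCH_SAME_CHR},
#'   subtyped by flank order. With inner coordinates \code{gL} (left flank's
#'   motif-adjacent edge: its end on \code{+}, its start on \code{-}) and
#'   \code{gR} (right flank's motif-adjacent edge, mirrored): on \code{+},
#'   \code{gR >= gL} is a clone-end junction (\code{BAC_END}, gap
#'   \code{gR - gL}) and \code{gR < gL} an internal-fragment
#'   circularization (\code{INSERTION}, gap \code{gL - gR}); mirrored on
#'   \code{-}. Abutting flanks give a degenerate \code{BAC_END} of gap 0.
#' \item same chromosome, opposite strands: subtype
#'   \code{DISCORDANT_STRAND}, no gap.
#' }
#' A call is \code{UNIQUE} when both flanks mapped with
#' \code{mapq >= mapqMin} and neither has a secondary alignment, else
#' \code{MULTI}. \code{in_gap_window} flags gaps inside
#' \code{[gapMin, gapMax]}; out-of-window calls keep their category but are
#' excluded from the gap reports.
#'
#' @param alignments alignment data.frame from \code{\link{alignFlanksToy}}
#'   or \code{\link{readFlankSam}} (one row per flank, sides L/R).
#' @param mapqMin minimum MAPQ for a unique call (default 30).
#' @param gapMin,gapMax internal-gap window in bp (defaults 1000 and
#'   150000, the gapped-alignment search window).
#' @return a \linkS4class{JunctionCallSet}.
#' @export
classifyJunctions <- function(alignments, mapqMin = 30L, gapMin = 1000L,
                              gapMax = 150000L) {
  stopifnot(gapMin < gapMax)
  ids <- unique(alignments$read_id)
  al <- alignments
  key <- paste0(al$read_id, "\r", al$side)
  iL <- match(paste0(ids, "\rL"), key)
  iR <- match(paste0(ids, "\rR"), key)

  n <- length(ids)
  calls <- data.frame(
    read_id = ids,
    category = NA_character_, subtype = NA_character_,
    uniqueness = NA_character_, gap = NA_integer_, in_gap_window = FALSE,
    chromL = NA_character_, innerL = NA_integer_, strandL = NA_character_,
    chromR = NA_character_, innerR = NA_integer_, strandR = NA_character_)

  getm <- function(i) !is.na(i) && isTRUE(al$mapped[i])
  for (k in seq_len(n)) {
    L <- iL[k]; R <- iR[k]
    ml <- getm(L); mr <- getm(R)
    if (!ml && !mr) { calls$category[k] <- "NO_MATCH"; next }
    if (ml) {
      calls$chromL[k] <- al$chrom[L]; calls$strandL[k] <- al$strand[L]
      calls$innerL[k] <- inner_coord(al$start[L], al$end[L], al$strand[L],
                                     side = "L")
    }
    if (mr) {
      calls$chromR[k] <- al$chrom[R]; calls$strandR[k] <- al$strand[R]
      calls$innerR[k] <- inner_coord(al$start[R], al$end[R], al$strand[R],
                                     side = "R")
    }
    if (!ml || !mr || al$chrom[L] != al$chrom[R]) {
      calls$category[k] <- "MATCH_DIFF_CHR"
      calls$uniqueness[k] <- "MULTI"
      if (ml && mr)
        calls$uniqueness[k] <- uniqueness_of(al, L, R, mapqMin)
      next
    }
    calls$category[k] <- "MATCH_SAME_CHR"
    calls$uniqueness[k] <- uniqueness_of(al, L, R, mapqMin)
    if (al$strand[L] != al$strand[R]) {
      calls$subtype[k] <- "DISCORDANT_STRAND"
      next
    }
    d <- if (al$strand[L] == "+") calls$innerR[k] - calls$innerL[k]
         else calls$innerL[k] - calls$innerR[k]
    if (d >= 0L) { calls$subtype[k] <- "BAC_END"; calls$gap[k] <- d }
    else { calls$subtype[k] <- "INSERTION"; calls$gap[k] <- -d }
    calls$in_gap_window[k] <- calls$gap[k] >= gapMin & calls$gap[k] <= gapMax
  }
  new("JunctionCallSet", calls = calls,
      params = list(mapq_min = mapqMin, gap_min = gapMin, gap_max = gapMax))
}

# inner (motif-adjacent) junction offset of a flank alignment.
# 1-based closed [start,end] on "+": L's inner edge is its end -> offset end;
# R's inner edge is its start -> offset start-1. Mirrored on "-".
inner_coord <- function(start, end, strand, side) {
  if (side == "L") { if (strand == "+") end else start - 1L }
  else             { if (strand == "+") start - 1L else end }
}

uniqueness_of <- function(al, L, R, mapqMin) {
  if (al$mapq[L] >= mapqMin && al$mapq[R] >= mapqMin &&
      !al$has_secondary[L] && !al$has_secondary[R]) "UNIQUE" else "MULTI"
}

#' Deduplicate junction calls by anchor position
#'
#' Junction reads sequenced from the same junction molecule at different
#' offsets yield identical anchor coordinates; this removes such positional
#' duplicates, keeping the first call per key
#' (category, subtype, chromL, innerL, strandL, chromR, innerR, strandR).
#' Idempotent.
#'
#' @param calls calls data.frame (or a \code{JunctionCallSet}).
#' @return list with \code{calls} (deduplicated data.frame) and
#'   \code{counts = c(input, unique)}.
#' @export
dedupeByPosition <- function(calls) {
  if (is(calls, "JunctionCallSet")) calls <- junctionCalls(calls)
  key <- with(calls, paste(category, subtype, chromL, innerL, strandL,
                           chromR, innerR, strandR, sep = "\r"))
  keep <- !duplicated(key)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, counts = c(input = nrow(calls), unique = nrow(out)))
}

#' Write junction calls as TSV
#'
#' @param calls calls data.frame or \code{JunctionCallSet}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeJunctionCalls <- function(calls, path) {
  if (is(calls, "JunctionCallSet")) calls <- junctionCalls(calls)
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export same-chromosome anchors as BED
#'
#' One interval per same-chromosome concordant call, spanning
#' \code{[min(innerL, innerR), max(innerL, innerR))} on the reference
#' (BED half-open), named by read id, scored with \code{gap / 1000} (kb).
#'
#' @param calls calls data.frame or \code{JunctionCallSet}.
#' @param path output BED path.
#' @return invisibly, \code{path}.
#' @export
writeAnchorsBed <- function(calls, path) {
  if (is(calls, "JunctionCallSet")) calls <- junctionCalls(calls)
  cl <- calls[calls$category == "MATCH_SAME_CHR" & !is.na(calls$gap), ,
              drop = FALSE]
  lo <- pmin(cl$innerL, cl$innerR)
  hi <- pmax(cl$innerL, cl$innerR)
  gr <- GenomicRanges::GRanges(
    seqnames = cl$chromL,
    ranges = IRanges(start = lo + 1L, end = pmax(hi, lo + 1L)),
    strand = cl$strandL,
    name = cl$read_id, score = cl$gap / 1000)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
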