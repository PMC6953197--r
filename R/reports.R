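#' Category mapping ratios
#'
#' Recomputes the library-quality ratios of the read-category accounting
#' table: the share of site-carrying unique reads whose flank pair mapped at
#' all (same chromosome, both subtypes, plus different-chromosome /
#' one-end calls), and the share mapped to a single chromosome.
#' Percentages are rounded half-up to 2 decimals, the convention used for
#' all printed percentages here.
#'
#' @param samechrBacend same-chromosome clone-end (BAC_END) read count.
#' @param samechrInsertion same-chromosome INSERTION read count.
#' @param diffchr different-chromosome / one-end-mapped read count.
#' @param nomatch count of reads with neither flank mapped.
#' @param uniqueTotal total unique site-carrying reads (>= sum of the
#'   categories).
#' @return list with \code{mapped_pct}, \code{samechr_pct}, the raw counts
#'   and \code{degenerate} (TRUE when \code{uniqueTotal} is 0 and the ratios
#'   are reported as 0).
#' @examples
#' mappingRatioReport(1549145, 445813, 2433257, 22046957, 9819130)
#' @export
mappingRatioReport <- function(samechrBacend, samechrInsertion, diffchr,
                               nomatch, uniqueTotal) {
  cats <- c(samechrBacend, samechrInsertion, diffchr)
  stopifnot(all(cats >= 0), nomatch >= 0)
  if (uniqueTotal < sum(cats))
    stop_input("uniqueTotal is smaller than the sum of mapped categories")
  degenerate <- uniqueTotal == 0
  mapped <- if (degenerate) 0 else sum(cats) / uniqueTotal * 100
  samechr <- if (degenerate) 0 else
    (samechrBacend + samechrInsertion) / uniqueTotal * 100
  list(mapped_pct = roundHalfUp(mapped, 2),
       samechr_pct = roundHalfUp(samechr, 2),
       counts = c(samechr_bacend = samechrBacend,
                  samechr_insertion = samechrInsertion,
                  diffchr = diffchr, nomatch = nomatch,
                  unique_total = uniqueTotal),
       degenerate = degenerate)
}

#' Gap histogram bin scheme
#'
#' The regular reporting bins for internal gaps: \code{[1, 10)},
#' \code{[10, 20)}, ..., \code{[140, 150]} kb — lower-inclusive, with the
#' window maximum included in the last bin.
#'
#' @param window gap window in bp, default \code{c(1000, 150000)}.
#' @param binWidth bin width in bp (default 10000).
#' @return data.frame with \code{label}, \code{lo}, \code{hi} (bp; lo
#'   inclusive, hi exclusive except the last bin).
#' @export
gapBins <- function(window = c(1000, 150000), binWidth = 10000) {
  lo <- c(window[1], seq(binWidth, window[2] - binWidth, by = binWidth))
  hi <- c(lo[-1], window[2])
  data.frame(label = paste0(round(lo / 1000), "-", round(hi / 1000)),
             lo = lo, hi = hi)
}

bin_index <- function(gap, bins) {
  i <- findInterval(gap, c(bins$lo, bins$hi[nrow(bins)]),
                    rightmost.closed = TRUE)
  i[gap < bins$lo[1] | gap > bins$hi[nrow(bins)]] <- NA_integer_
  i
}

#' Bin internal gaps into the reporting histogram
#'
#' Counts in-window gaps per 10 kb bin, stratified by subtype
#' (BAC_END / INSERTION) and uniqueness (UNIQUE / MULTI). Gaps outside the
#' window are excluded (they are flagged \code{in_gap_window = FALSE} by the
#' classifier).
#'
#' @param calls calls data.frame or \code{JunctionCallSet}.
#' @param window,binWidth see \code{\link{gapBins}}.
#' @return data.frame: bin \code{label}, \code{lo}, \code{hi}, and counts
#'   \code{bacend_unique}, \code{bacend_multi}, \code{insertion_unique},
#'   \code{insertion_multi}.
#' @export
binGapHistogram <- function(calls, window = c(1000, 150000),
                            binWidth = 10000) {
  if (is(calls, "JunctionCallSet")) calls <- junctionCalls(calls)
  bins <- gapBins(window, binWidth)
  strata <- list(bacend_unique = c("BAC_END", "UNIQUE"),
                 bacend_multi = c("BAC_END", "MULTI"),
                 insertion_unique = c("INSERTION", "UNIQUE"),
                 insertion_multi = c("INSERTION", "MULTI"))
  for (s in names(strata)) {
    sel <- !is.na(calls$gap) &
      calls$subtype %in% strata[[s]][1] &
      calls$uniqueness %in% strata[[s]][2]
    idx <- bin_index(calls$gap[sel], bins)
    bins[[s]] <- tabulate(idx[!is.na(idx)], nbins = nrow(bins))
  }
  bins
}

#' Fraction of a gap histogram falling in a sub-window
#'
#' Computes the share (in percent, rounded half-up to 2 decimals) of
#' binned gap counts lying in \code{[low, high)}; with the defaults, the
#' share of 60-100 kb gaps among all in-window gaps — the key
#' library-quality figure for a ~90 kb insert library.
#'
#' @param counts integer vector of per-bin counts (one per row of
#'   \code{\link{gapBins}}), e.g. one stratum column of
#'   \code{\link{binGapHistogram}}.
#' @param low,high sub-window bounds in bp (bin-aligned).
#' @param window,binWidth see \code{\link{gapBins}}.
#' @return list with \code{pct}, \code{in_range} and \code{total}.
#' @export
gapWindowFraction <- function(counts, low = 60000, high = 100000,
                              window = c(1000, 150000), binWidth = 10000) {
  bins <- gapBins(window, binWidth)
  stopifnot(length(counts) == nrow(bins))
  sel <- bins$lo >= low & bins$hi <= high
  tot <- sum(counts)
  inr <- sum(counts[sel])
  list(pct = if (tot > 0) roundHalfUp(inr / tot * 100, 2) else 0,
       in_range = inr, total = tot)
}

anchor_positions <- function(calls) {
  # anchor position = midpoint of the two inner coordinates
  data.frame(read_id = calls$read_id, chrom = calls$chromL,
             pos = floor((calls$innerL + calls$innerR) / 2))
}

#' Per-chromosome anchor summary
#'
#' Restricts to same-chromosome clone-end (BAC_END) calls whose gap falls in
#' \code{[gapLow, gapHigh)} — by default the 60-100 kb window matching a
#' ~90 kb insert library — and reports per chromosome: total calls, unique
#' calls after positional deduplication, and the dense/sparse partition of
#' the unique anchors by distance to the nearest adjacent anchor
#' (\code{< adjacency} = dense). dense + sparse = unique per chromosome and
#' overall.
#'
#' @param calls calls data.frame or \code{JunctionCallSet}.
#' @param gapLow,gapHigh anchor gap window in bp (lower-inclusive,
#'   upper-exclusive; defaults 60000 and 100000).
#' @param adjacency adjacency threshold in bp (default 100000).
#' @return list with \code{per_chrom} (data.frame chrom, total, unique,
#'   dense, sparse), \code{totals} (named vector), and \code{anchors}
#'   (unique anchors with chrom, pos, dense flag).
#' @export
chromosomeAnchorSummary <- function(calls, gapLow = 60000, gapHigh = 100000,
                                    adjacency = 100000) {
  if (is(calls, "JunctionCallSet")) calls <- junctionCalls(calls)
  sel <- calls$category == "MATCH_SAME_CHR" &
    !is.na(calls$subtype) & calls$subtype == "BAC_END" &
    !is.na(calls$gap) & calls$gap >= gapLow & calls$gap < gapHigh
  cl <- calls[sel, , drop = FALSE]
  if (nrow(cl) == 0L)
    return(list(per_chrom = data.frame(chrom = character(),
                                       total = integer(), unique = integer(),
                                       dense = integer(), sparse = integer()),
                totals = c(total = 0L, unique = 0L, dense = 0L, sparse = 0L),
                anchors = data.frame(read_id = character(),
                                     chrom = character(), pos = integer(),
                                     dense = logical())))
  uq <- dedupeByPosition(cl)$calls
  anchors <- anchor_positions(uq)
  anchors <- flag_dense(anchors, adjacency)
  chroms <- sort(unique(cl$chromL))
  per <- data.frame(
    chrom = chroms,
    total = as.integer(table(factor(cl$chromL, levels = chroms))),
    unique = as.integer(table(factor(uq$chromL, levels = chroms))),
    dense = vapply(chroms, function(ch)
      sum(anchors$dense[anchors$chrom == ch]), integer(1)),
    sparse = vapply(chroms, function(ch)
      sum(!anchors$dense[anchors$chrom == ch]), integer(1)))
  rownames(per) <- NULL
  list(per_chrom = per,
       totals = c(total = sum(per$total), unique = sum(per$unique),
                  dense = sum(per$dense), sparse = sum(per$sparse)),
       anchors = anchors)
}

flag_dense <- function(anchors, threshold) {
  anchors$dense <- FALSE
  for (ch in unique(anchors$chrom)) {
    i <- which(anchors$chrom == ch)
    p <- sort(anchors$pos[i])
    o <- order(anchors$pos[i])
    if (length(p) == 1L) next
    d <- diff(p)
    dense_sorted <- c(d[1] < threshold,
                      if (length(p) > 2L)
                        pmin(d[-length(d)], d[-1]) < threshold,
                      d[length(d)] < threshold)
    anchors$dense[i[o]] <- dense_sorted
  }
  anchors
}

#' Dense/sparse partition of anchors by adjacency
#'
#' An anchor is dense when its distance to at least one adjacent anchor on
#' the same chromosome (previous or next, by position) is below the
#' threshold; otherwise sparse. A chromosome's single anchor is sparse.
#'
#' @param anchors data.frame with \code{chrom} and \code{pos}.
#' @param threshold adjacency threshold in bp (default 100000).
#' @return data.frame per chromosome: \code{chrom}, \code{dense},
#'   \code{sparse}, \code{n}.
#' @export
adjacencyPartition <- function(anchors, threshold = 100000) {
  anchors <- flag_dense(anchors, threshold)
  chroms <- sort(unique(anchors$chrom))
  out <- data.frame(
    chrom = chroms,
    dense = vapply(chroms, function(ch)
      sum(anchors$dense[anchors$chrom == ch]), integer(1)),
    sparse = vapply(chroms, function(ch)
      sum(!anchors$dense[anchors$chrom == ch]), integer(1)))
  out$n <- out$dense + out$sparse
  rownames(out) <- NULL
  out
}

#' Anchor counts in fixed windows along each chromosome
#'
#' Tiles each chromosome with non-overlapping windows from position 0 and
#' counts anchors per window; the physical-map view of anchor density.
#'
#' @param anchors data.frame with \code{chrom} and \code{pos}.
#' @param window window size in bp (default 100000).
#' @return list with \code{tiles} (data.frame chrom, tile_start, count;
#'   zero-count tiles up to each chromosome's last anchor included) and
#'   \code{max_count}.
#' @export
windowDensity <- function(anchors, window = 100000) {
  if (nrow(anchors) == 0L)
    return(list(tiles = data.frame(chrom = character(),
                                   tile_start = integer(),
                                   count = integer()),
                max_count = 0L))
  out <- lapply(sort(unique(anchors$chrom)), function(ch) {
    p <- anchors$pos[anchors$chrom == ch]
    idx <- p %/% window
    nt <- max(idx) + 1L
    data.frame(chrom = ch,
               tile_start = (seq_len(nt) - 1L) * window,
               count = tabulate(idx + 1L, nbins = nt))
  })
  tiles <- do.call(rbind, out)
  list(tiles = tiles, max_count = max(tiles$count))
}

#' Categorize long (Sanger-style) clone-end sequences by interlength
#'
#' For clone-end sequences read by long-read chemistry, each side of the cut
#' site is aligned independently (e.g. by BLAST) and a side counts as
#' matched when its best alignment is longer than \code{minAlign} bp and the
#' input sequence itself is longer than \code{minInput} bp (strict mode:
#' alignment length / input length > \code{minCoverage} instead). Clones are
#' then categorized like short-read junctions — both sides on one chromosome
#' (with interlength = distance between the two positions), different
#' chromosomes, one side only, or no match — and same-chromosome clones are
#' binned with the irregular published bin scheme (<1, 1-10, 10-30, 30-40,
#' ..., 140-150, >150 kb).
#'
#' @param hits data.frame with one row per alignment: \code{clone_id},
#'   \code{side} (1/2 or L/R), \code{chrom}, \code{position},
#'   \code{align_length}, \code{input_length}. More than one hit per side is
#'   resolved by the longest alignment.
#' @param minAlign matched-side alignment length threshold in bp
#'   (default 300).
#' @param minInput input-length threshold in bp (default 1000).
#' @param strict use the coverage-ratio rule instead (default FALSE).
#' @param minCoverage coverage ratio for strict mode (default 0.8).
#' @return list with \code{records} (data.frame clone_id, category,
#'   interlength, bin) and \code{bin_counts} (named integer vector over the
#'   same-chromosome bins plus the three other categories).
#' @export
interlengthCategorize <- function(hits, minAlign = 300, minInput = 1000,
                                  strict = FALSE, minCoverage = 0.8) {
  stopifnot(all(c("clone_id", "side", "chrom", "position", "align_length",
                  "input_length") %in% names(hits)))
  clones <- unique(hits$clone_id)
  rec <- data.frame(clone_id = clones, category = NA_character_,
                    interlength = NA_real_, bin = NA_character_)
  for (k in seq_along(clones)) {
    h <- hits[hits$clone_id == clones[k], , drop = FALSE]
    sides <- lapply(split(h, h$side), function(g)
      g[which.max(g$align_length), , drop = FALSE])
    matched <- Filter(function(g) {
      if (strict) g$align_length / g$input_length > minCoverage
      else g$align_length > minAlign && g$input_length > minInput
    }, sides)
    nm <- length(matched)
    if (nm == 0L) rec$category[k] <- "no-match"
    else if (nm == 1L) rec$category[k] <- "one-end"
    else {
      a <- matched[[1]]; b <- matched[[2]]
      if (a$chrom != b$chrom) rec$category[k] <- "different-chrom"
      else {
        rec$category[k] <- "same-chrom"
        rec$interlength[k] <- abs(b$position - a$position)
        rec$bin[k] <- interlength_bin(rec$interlength[k])
      }
    }
  }
  bins <- interlength_bin_labels()
  bc <- c(table(factor(rec$bin, levels = bins)),
          `different-chrom` = sum(rec$category == "different-chrom"),
          `one-end` = sum(rec$category == "one-end"),
          `no-match` = sum(rec$category == "no-match"))
  list(records = rec, bin_counts = bc)
}

interlength_bin_labels <- function() {
  c("<1", "1-10", "10-30", paste0(seq(30, 140, 10), "-",
                                  seq(40, 150, 10)), ">150")
}

interlength_bin <- function(x) {
  kb <- x / 1000
  if (kb < 1) "<1"
  else if (kb < 10) "1-10"
  else if (kb < 30) "10-30"
  else if (kb >= 150) ">150"
  else paste0(floor(kb / 10) * 10, "-", floor(kb / 10) * 10 + 10)
}

#' Zygosity summary of variant sites
#'
#' Classifies each variant site by the set of base types observed there:
#' exactly one base type means the site is homozygous (relative to the
#' sample's read pool), two or more mean heterozygous. Fractions are
#' reported as whole-number percentages (half-up).
#'
#' @param siteTypes per-site observed base types: a list of character
#'   vectors, or a character vector with comma-separated types
#'   (e.g. \code{"A,G"}).
#' @return list with \code{homozygous}, \code{heterozygous}, \code{skipped}
#'   (sites with an empty type set), \code{hom_pct} and \code{het_pct}.
#' @examples
#' zygositySummary(c("A", "A,G", "C"))
#' @export
zygositySummary <- function(siteTypes) {
  if (is.character(siteTypes)) {
    # count distinct types per unique key once; sites share few keys
    keys <- unique(siteTypes)
    kn <- vapply(strsplit(keys, ",", fixed = TRUE), function(x)
      length(unique(x[nzchar(x)])), integer(1))
    ntypes <- kn[match(siteTypes, keys)]
  } else {
    ntypes <- vapply(siteTypes, function(x)
      length(unique(x[nzchar(x)])), integer(1))
  }
  skipped <- sum(ntypes == 0L)
  hom <- sum(ntypes == 1L)
  het <- sum(ntypes >= 2L)
  tot <- hom + het
  list(homozygous = hom, heterozygous = het, skipped = skipped,
       hom_pct = if (tot) roundHalfUp(hom / tot * 100, 0) else 0,
       het_pct = if (tot) roundHalfUp(het / tot * 100, 0) else 0)
}

#' Zygosity summary from a VCF
#'
#' Genotype-based approximation of \code{\link{zygositySummary}}: a site is
#' heterozygous when the first sample's genotype carries two or more
#' distinct alleles. The read-level definition (base types observed across
#' reads) is the reference one; use the TSV/vector interface for it.
#'
#' @param path VCF path (vcfR must be installed).
#' @return as \code{\link{zygositySummary}}.
#' @export
zygosityFromVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("zygosityFromVcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  alleles <- strsplit(gt, "[/|]")
  types <- vapply(alleles, function(a)
    length(unique(a[!is.na(a) & a != "."])), integer(1))
  hom <- sum(types == 1L)
  het <- sum(types >= 2L)
  tot <- hom + het
  list(homozygous = hom, heterozygous = het, skipped = sum(types == 0L),
       hom_pct = if (tot) roundHalfUp(hom / tot * 100, 0) else 0,
       het_pct = if (tot) roundHalfUp(het / tot * 100, 0) else 0)
}
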