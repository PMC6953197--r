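#' Simulate a random genome
#'
#' I.i.d. bases at a stated GC fraction; a uniform-composition genome makes
#' the expected density of a 6-bp recognition site (L-5)/4^6 per sequence of
#' length L, i.e. a ~4 kb mean restriction fragment — the regime in which a
#' ~90 kb insert clone carries a handful of internal cut sites.
#'
#' @param nChrom number of chromosomes.
#' @param lengths chromosome lengths in bp (recycled to \code{nChrom}).
#' @param gc GC fraction in (0, 1), default 0.5.
#' @param seed RNG seed; identical seeds give identical genomes.
#' @return named \code{DNAStringSet} (chr1, chr2, ...).
#' @export
simulateGenome <- function(nChrom = 2L, lengths = 1e6, gc = 0.5, seed = 1L) {
  stopifnot(nChrom >= 1L, all(lengths >= 1), gc > 0, gc < 1)
  lengths <- rep_len(as.integer(lengths), nChrom)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withSeed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
  out <- DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(nChrom))
  out
}

#' Simulate a cloning vector with no enzyme site
#'
#' Random sequence rejected-resampled until it contains no recognition site
#' of the given enzyme — the enzyme-selection requirement for junction
#' libraries (digestion must leave the vector backbone intact).
#'
#' @param enz a \linkS4class{RestrictionEnzyme}.
#' @param length vector length in bp (default 8000).
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return a \code{DNAString}.
#' @export
simulateVector <- function(enz, length = 8000L, gc = 0.5, seed = 1L) {
  withSeed(seed, {
    for (i in 1:100) {
      v <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                 (1 - gc) / 2)), collapse = "")
      if (nrow(findSites(v, enz)) == 0L) return(DNAString(v))
    }
  })
  stop_input("could not sample a site-free vector; motif too permissive?")
}

#' Simulate BAC clones
#'
#' Uniform random placement of clone inserts on the genome (chromosome
#' chosen proportional to length); insert lengths are Normal(mean, sd)
#' truncated to [20 kb, 150 kb].
#'
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param nClones number of clones.
#' @param insertMean mean insert length in bp (default 90000, a typical
#'   large-insert BAC library).
#' @param insertSd insert length SD in bp (default 5000).
#' @param seed RNG seed.
#' @return data.frame of clones: \code{clone_id}, \code{chrom},
#'   \code{insert_start}, \code{insert_end} (1-based closed),
#'   \code{insert_length}.
#' @export
simulateClones <- function(genome, nClones, insertMean = 90000,
                           insertSd = 5000, seed = 1L) {
  genome <- as_genome(genome)
  lens <- width(genome)
  if (insertMean + 4 * insertSd >= min(lens))
    stop_input("genome too short for the insert distribution")
  withSeed(seed, {
    il <- round(stats::rnorm(nClones, insertMean, insertSd))
    il <- pmin(pmax(il, 20000), 150000)
    chrom_i <- sample(seq_along(genome), nClones, replace = TRUE,
                      prob = lens)
    start <- vapply(seq_len(nClones), function(k)
      sample.int(lens[chrom_i[k]] - il[k] + 1L, 1L), integer(1))
  })
  data.frame(clone_id = sprintf("clone%05d", seq_len(nClones)),
             chrom = names(genome)[chrom_i],
             insert_start = as.integer(start),
             insert_end = as.integer(start + il - 1L),
             insert_length = as.integer(il))
}

#' Build junction fragments from digested, self-ligated clones
#'
#' Complete digestion of a clone (vector + insert) cuts at every recognition
#' site lying fully inside the insert (the site-free vector is never cut).
#' With internal cut points c1 < ... < ck:
#' \itemize{
#' \item the vector-containing fragment (right terminal piece + vector +
#'   left terminal piece) self-ligates into one clone-end (\code{BAC_END})
#'   junction joining the sequence approaching c1 to the sequence leaving
#'   ck; its cut-to-cut gap is \code{ck - c1} (never more than the insert
#'   length);
#' \item each internal fragment [ci, ci+1) self-circularizes into an
#'   \code{INSERTION} junction joining its right end back to its left end —
#'   the flank order on the reference is therefore inverted — with
#'   cut-to-cut gap equal to the fragment length.
#' }
#' Sticky-end self-ligation restores the full recognition site across each
#' junction. Clones with no internal site yield no junction and are flagged
#' uncut. Because the classifier assigns the restored site's bases to
#' neither flank, the flank-to-flank distance it will measure
#' (\code{expected_inner_gap}) is the cut-to-cut gap plus the motif length
#' for BAC_END junctions and minus the motif length for INSERTION
#' junctions.
#'
#' @param clones clone data.frame from \code{\link{simulateClones}}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param enz a \linkS4class{RestrictionEnzyme}.
#' @param vector cloning vector (\code{DNAString} or character); must not
#'   contain a recognition site.
#' @return list with \code{junctions} (data.frame: \code{fragment_id},
#'   \code{clone_id}, \code{type}, \code{chrom}, \code{cut_left},
#'   \code{cut_right} (0-based cut points; the junction joins the sequence
#'   ending at \code{cut_left} to the sequence starting at
#'   \code{cut_right}), \code{left_lo}, \code{right_hi} (1-based bounds of
#'   usable flank context), \code{expected_gap}, \code{expected_inner_gap})
#'   and \code{uncut} (clone ids with no internal site).
#' @export
buildJunctionFragments <- function(clones, genome, enz, vector) {
  genome <- as_genome(genome)
  if (nrow(findSites(as.character(vector), enz)) > 0L)
    stop_input("vector contains a ", enzymeName(enz), " site")
  L <- motifLength(enz)
  off <- cutOffset(enz)
  # all genome sites once, per chromosome
  site_starts <- lapply(seq_along(genome), function(i)
    findSites(as.character(genome[[i]]), enz)$start)
  names(site_starts) <- names(genome)

  rows <- list()
  uncut <- character()
  for (k in seq_len(nrow(clones))) {
    cl <- clones[k, ]
    ss <- site_starts[[cl$chrom]]
    inside <- ss[ss >= cl$insert_start & ss + L - 1L <= cl$insert_end]
    if (length(inside) == 0L) { uncut <- c(uncut, cl$clone_id); next }
    cuts <- inside + off - 1L  # 0-based cut points (bases before the cut)
    kk <- length(cuts)
    # clone-end junction: ...-> c1 ligated to ck ->...
    rows[[length(rows) + 1L]] <- data.frame(
      fragment_id = paste0(cl$clone_id, ":BE"),
      clone_id = cl$clone_id, type = "BAC_END", chrom = cl$chrom,
      cut_left = cuts[1], cut_right = cuts[kk],
      left_lo = cl$insert_start, right_hi = cl$insert_end,
      expected_gap = cuts[kk] - cuts[1],
      expected_inner_gap = cuts[kk] - cuts[1] + L)
    if (kk > 1L) {
      # internal fragments [ci, ci+1): right end ligates back to left end
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = paste0(cl$clone_id, ":IN", seq_len(kk - 1L)),
        clone_id = cl$clone_id, type = "INSERTION", chrom = cl$chrom,
        cut_left = cuts[-1], cut_right = cuts[-kk],
        left_lo = cuts[-kk] + 1L, right_hi = cuts[-1],
        expected_gap = diff(cuts),
        expected_inner_gap = diff(cuts) - L)
    }
  }
  junctions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fragment_id = character(), clone_id = character(),
               type = character(), chrom = character(),
               cut_left = integer(), cut_right = integer(),
               left_lo = integer(), right_hi = integer(),
               expected_gap = integer(), expected_inner_gap = integer())
  rownames(junctions) <- NULL
  list(junctions = junctions, uncut = uncut)
}

#' Simulate junction-spanning reads
#'
#' Each read spans its junction with the restored recognition motif at a
#' uniform-random admissible offset (both flanks at least 1 bp and fully
#' inside the junction's source fragments); half the reads (in expectation)
#' are emitted as reverse complements; substitution errors are i.i.d. per
#' base. Junctions whose source fragments are too short to host a full-length
#' read are skipped. Optional negative controls: \code{chimeraRate} replaces
#' a read's right side with a cut from a random other locus
#' (inter-molecule ligation; truth type \code{CHIMERA}), and
#' \code{backgroundRate} adds plain genomic reads with no engineered
#' junction (truth type \code{BACKGROUND}).
#'
#' @param junctions junction data.frame from
#'   \code{\link{buildJunctionFragments}}.
#' @param genome \code{DNAStringSet} or FASTA path.
#' @param enz a \linkS4class{RestrictionEnzyme}.
#' @param readLength read length in bp (default 150).
#' @param errorRate per-base substitution probability (default 0).
#' @param readsPerJunction reads sequenced across each junction (default 1).
#' @param revcompFraction probability a read is emitted reverse-complemented
#'   (default 0.5).
#' @param chimeraRate,backgroundRate negative-control rates (default 0).
#' @param seed RNG seed.
#' @return list with \code{reads} (named \code{DNAStringSet}) and
#'   \code{truth} (data.frame: \code{read_id}, \code{fragment_id},
#'   \code{clone_id}, \code{type}, \code{chromL}, \code{chromR},
#'   \code{gL_true}, \code{gR_true} (expected inner flank coordinates,
#'   0-based junction offsets), \code{expected_gap},
#'   \code{expected_inner_gap}, \code{orientation}).
#' @export
simulateReads <- function(junctions, genome, enz, readLength = 150L,
                          errorRate = 0, readsPerJunction = 1L,
                          revcompFraction = 0.5, chimeraRate = 0,
                          backgroundRate = 0, seed = 1L) {
  genome <- as_genome(genome)
  L <- motifLength(enz)
  off <- cutOffset(enz)
  stopifnot(readLength > 2 * 1 + L)
  chr_chars <- lapply(seq_along(genome), function(i)
    as.character(genome[[i]]))
  names(chr_chars) <- names(genome)

  withSeed(seed, {
    jx <- junctions[rep(seq_len(nrow(junctions)), each = readsPerJunction), ,
                    drop = FALSE]
    n <- nrow(jx)
    is_chimera <- stats::runif(n) < chimeraRate
    chromR <- jx$chrom
    if (any(is_chimera)) {
      # replace the right side with a random cut on a random chromosome
      site_starts <- lapply(chr_chars, function(s)
        findSites(s, enz)$start)
      for (i in which(is_chimera)) {
        ch <- sample(names(genome), 1L)
        ss <- site_starts[[ch]]
        ss <- ss[ss + L - 1L <= nchar(chr_chars[[ch]]) - readLength]
        if (!length(ss)) { is_chimera[i] <- FALSE; next }
        s0 <- ss[sample.int(length(ss), 1L)]
        chromR[i] <- ch
        jx$cut_right[i] <- s0 + off - 1L
        jx$right_hi[i] <- nchar(chr_chars[[ch]])
        jx$type[i] <- "CHIMERA"
        jx$expected_gap[i] <- NA_integer_
        jx$expected_inner_gap[i] <- NA_integer_
      }
    }

    seqs <- character(n)
    keep <- logical(n)
    a_flank <- integer(n)
    for (i in seq_len(n)) {
      # left segment: ends at cut_left, within [left_lo, cut_left];
      # right segment: starts at cut_right + 1, within [.., right_hi]
      cL <- jx$cut_left[i]; cR <- jx$cut_right[i]
      avail_left <- cL - jx$left_lo[i] + 1L   # bases available left of cut
      avail_right <- jx$right_hi[i] - cR      # bases available right of cut
      # a = bases taken left of the cut (includes `off` motif bases)
      a_min <- max(off + 1L, readLength - avail_right)
      a_max <- min(readLength - (L - off) - 1L, avail_left)
      if (a_min > a_max) next
      a <- if (a_min == a_max) a_min else
        sample(seq.int(a_min, a_max), 1L)
      b <- readLength - a
      seqs[i] <- paste0(
        substr(chr_chars[[jx$chrom[i]]], cL - a + 1L, cL),
        substr(chr_chars[[chromR[i]]], cR + 1L, cR + b))
      a_flank[i] <- a - off
      keep[i] <- TRUE
    }

    jx <- jx[keep, , drop = FALSE]
    chromR <- chromR[keep]
    seqs <- seqs[keep]
    a_flank <- a_flank[keep]
    n <- nrow(jx)

    truth <- data.frame(
      read_id = sprintf("read%06d", seq_len(n)),
      fragment_id = jx$fragment_id, clone_id = jx$clone_id,
      type = jx$type, chromL = jx$chrom, chromR = chromR,
      gL_true = jx$cut_left - off,
      gR_true = jx$cut_right + (L - off),
      expected_gap = jx$expected_gap,
      expected_inner_gap = jx$expected_inner_gap,
      orientation = ifelse(stats::runif(n) < revcompFraction, "-", "+"))

    if (backgroundRate > 0) {
      nb <- stats::rpois(1, backgroundRate * n)
      if (nb > 0) {
        bch <- sample(names(genome), nb, replace = TRUE)
        bst <- vapply(bch, function(ch)
          sample.int(nchar(chr_chars[[ch]]) - readLength, 1L), integer(1))
        bseq <- substring(chr_chars[bch], bst, bst + readLength - 1L)
        seqs <- c(seqs, bseq)
        truth <- rbind(truth, data.frame(
          read_id = sprintf("bg%06d", seq_len(nb)),
          fragment_id = NA_character_, clone_id = NA_character_,
          type = "BACKGROUND", chromL = bch, chromR = bch,
          gL_true = NA_integer_, gR_true = NA_integer_,
          expected_gap = NA_integer_, expected_inner_gap = NA_integer_,
          orientation = "+"))
      }
    }

    reads <- DNAStringSet(seqs)
    names(reads) <- truth$read_id
    rc <- truth$orientation == "-"
    if (any(rc)) reads[rc] <- reverseComplement(reads[rc])
    if (errorRate > 0) reads <- add_substitutions(reads, errorRate)
  })
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

add_substitutions <- function(reads, rate) {
  chars <- as.character(reads)
  w <- nchar(chars)
  nmut <- stats::rbinom(length(chars), w, rate)
  for (i in which(nmut > 0L)) {
    pos <- sample.int(w[i], nmut[i])
    s <- strsplit(chars[i], "")[[1]]
    for (p in pos)
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    chars[i] <- paste(s, collapse = "")
  }
  out <- DNAStringSet(chars)
  names(out) <- names(reads)
  out
}

#' Write a simulation to disk
#'
#' Writes the genome FASTA, the reads as gzipped FASTQ (constant quality),
#' and the truth and clone tables as TSV.
#'
#' @param sim list from \code{\link{simulateReads}}.
#' @param genome \code{DNAStringSet}.
#' @param clones clone data.frame (optional).
#' @param dir output directory (created if needed).
#' @return invisibly, named vector of paths written.
#' @export
writeSimulation <- function(sim, genome, clones = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             reads = file.path(dir, "reads.fastq.gz"),
             truth = file.path(dir, "truth.tsv"))
  writeXStringSet(genome, paths["genome"])
  writeXStringSet(sim$reads, paths["reads"], format = "fastq",
                  compress = TRUE)
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(clones)) {
    paths["clones"] <- file.path(dir, "clones.tsv")
    utils::write.table(clones, paths["clones"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Evaluate junction calls against simulator ground truth
#'
#' Joins calls to the truth table by read id and tabulates predicted
#' category/subtype per true junction type. For calls whose subtype matches
#' a same-chromosome truth type, the gap error is the measured gap minus the
#' truth's expected flank-to-flank distance (\code{expected_inner_gap});
#' on error-free reads from single-copy loci it is exactly 0.
#'
#' @param calls calls data.frame or \code{JunctionCallSet}.
#' @param truth truth data.frame (or TSV path) from
#'   \code{\link{simulateReads}}.
#' @return list with \code{confusion} (table: true type x predicted label),
#'   \code{gap_errors} (data.frame read_id, type, gap, expected_inner_gap,
#'   error), \code{subtype_accuracy} (fraction of same-chromosome-truth
#'   reads among the calls with the correct subtype), and \code{unmatched}
#'   (read ids present in only one of the two tables).
#' @export
evaluateAgainstTruth <- function(calls, truth) {
  if (is(calls, "JunctionCallSet")) calls <- junctionCalls(calls)
  if (is.character(truth))
    truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  m <- merge(calls, truth, by = "read_id")
  unmatched <- c(setdiff(calls$read_id, truth$read_id),
                 setdiff(truth$read_id, calls$read_id))
  pred <- ifelse(m$category == "MATCH_SAME_CHR", m$subtype, m$category)
  confusion <- table(true = m$type, predicted = pred)
  same <- m$type %in% c("BAC_END", "INSERTION")
  ok <- same & pred == m$type
  ge <- data.frame(read_id = m$read_id[ok], type = m$type[ok],
                   gap = m$gap[ok],
                   expected_inner_gap = m$expected_inner_gap[ok])
  ge$error <- ge$gap - ge$expected_inner_gap
  list(confusion = confusion, gap_errors = ge,
       subtype_accuracy = if (any(same)) mean(ok[same]) else NA_real_,
       unmatched = unmatched)
}
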