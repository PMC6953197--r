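# shared fixtures: all built in code, nothing stored on disk

suppressPackageStartupMessages({
  library(Biostrings)
  library(IRanges)
})

ClaI <- enzyme("ClaI")
MluI <- enzyme("MluI")

# independent position-by-position IUPAC matcher (oracle for findSites)
naive_iupac_sites <- function(seq, motif) {
  seq <- toupper(seq)
  motif <- toupper(motif)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP[strsplit(motif, "")[[1]]], "")
  L <- length(sets)
  out <- integer()
  for (s in seq_len(nchar(seq) - L + 1L)) {
    win <- strsplit(substr(seq, s, s + L - 1L), "")[[1]]
    if (all(mapply(function(b, set) b %in% set, win, sets)))
      out <- c(out, s)
  }
  out
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a random sequence guaranteed free of the given motif
seq_without_motif <- function(n, enz, gc = 0.5) {
  repeat {
    s <- random_seq(n, gc)
    if (nrow(findSites(s, enz)) == 0L) return(s)
  }
}

# one alignment-table row (what alignFlanksToy / readFlankSam produce)
aln_row <- function(read_id, side, chrom = NA, start = NA, end = NA,
                    strand = NA, mapq = NA, secondary = FALSE,
                    mapped = !is.na(chrom)) {
  data.frame(read_id = read_id, side = side, mapped = mapped,
             chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             mapq = as.integer(mapq), has_secondary = secondary)
}

# minimal SAM writer for loader tests
write_sam <- function(records, path, sq = c(chr1 = 100000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, mapq, cigar,
                    seq = "ACGTACGTACGTACGTACGT") {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# small end-to-end simulation + pipeline, shared by several tests
run_sim_pipeline <- function(seed, n_chrom = 2L, chrom_length = 1e6,
                             n_clones = 500L, error_rate = 0,
                             enz = ClaI, ...) {
  genome <- simulateGenome(n_chrom, chrom_length, 0.5, seed = seed)
  vec <- simulateVector(enz, seed = seed + 1L)
  clones <- simulateClones(genome, n_clones, seed = seed + 2L)
  built <- buildJunctionFragments(clones, genome, enz, vec)
  sim <- simulateReads(built$junctions, genome, enz,
                       errorRate = error_rate, seed = seed + 3L, ...)
  scr <- screenReads(sim$reads, enz)
  al <- alignFlanksToy(splitReads(scr), genome)
  calls <- classifyJunctions(al)
  list(genome = genome, clones = clones, junctions = built$junctions,
       sim = sim, screen = scr, alignments = al, calls = calls)
}
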