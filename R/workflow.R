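#' Validate a run configuration
#'
#' Fills defaults and checks the configuration used by
#' \code{\link{runEndToEnd}}. A configuration either points at existing
#' inputs (\code{fastq}, plus \code{sam} or \code{genome_fasta} for the toy
#' aligner) or requests a simulation (\code{simulate = TRUE} with simulator
#' parameters).
#'
#' @param ... configuration fields; see Details.
#' @details Fields and defaults: \code{enzyme} ("ClaI"), \code{min_flank}
#'   (19), \code{mapq_min} (30), \code{gap_min} (1000), \code{gap_max}
#'   (150000), \code{bin_width} (10000), \code{anchor_gap_low} (60000),
#'   \code{anchor_gap_high} (100000), \code{adjacency} (100000),
#'   \code{seed} (1); simulation: \code{simulate} (FALSE), \code{n_chrom}
#'   (2), \code{chrom_length} (1e6), \code{gc} (0.5), \code{n_clones}
#'   (500), \code{insert_mean} (90000), \code{insert_sd} (5000),
#'   \code{error_rate} (0), \code{reads_per_junction} (1),
#'   \code{chimera_rate} (0), \code{background_rate} (0); inputs:
#'   \code{fastq}, \code{sam}, \code{genome_fasta}.
#' @return validated config list (class \code{RunConfig}).
#' @export
runConfig <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  defaults <- list(
    enzyme = "ClaI", min_flank = 19L, mapq_min = 30L,
    gap_min = 1000L, gap_max = 150000L, bin_width = 10000L,
    anchor_gap_low = 60000L, anchor_gap_high = 100000L,
    adjacency = 100000L, seed = 1L,
    simulate = FALSE, n_chrom = 2L, chrom_length = 1e6, gc = 0.5,
    n_clones = 500L, insert_mean = 90000, insert_sd = 5000,
    error_rate = 0, reads_per_junction = 1L, chimera_rate = 0,
    background_rate = 0,
    fastq = NULL, sam = NULL, genome_fasta = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop_input("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  thresholds <- c("min_flank", "mapq_min", "gap_min", "gap_max",
                  "bin_width", "anchor_gap_low", "anchor_gap_high",
                  "adjacency")
  for (t in thresholds)
    if (!is.numeric(cfg[[t]]) || cfg[[t]] <= 0)
      stop_input("config field '", t, "' must be a positive number")
  if (cfg$gap_min >= cfg$gap_max)
    stop_input("gap_min must be < gap_max")
  if (cfg$anchor_gap_low >= cfg$anchor_gap_high)
    stop_input("anchor_gap_low must be < anchor_gap_high")
  if (!cfg$simulate && is.null(cfg$fastq))
    stop_input("either set simulate = TRUE or provide 'fastq' input")
  if (!cfg$simulate && is.null(cfg$sam) && is.null(cfg$genome_fasta))
    stop_input("provide 'sam' alignments or 'genome_fasta' for the toy aligner")
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the whole junction-profiling pipeline
#'
#' Orchestrates simulate (optional) -> screen -> align (toy aligner or
#' external SAM) -> classify -> deduplicate -> report, writing every stage
#' artifact into \code{outDir}: split reads, junction calls, gap histogram,
#' per-chromosome anchor summary, anchors BED, a JSON report of ratios and
#' counts, an evaluation table when ground truth is available, a stage log
#' with read-count accounting, and a run manifest (package version, config,
#' config hash, seed). Cross-stage conservation (screen counts, category
#' partition, histogram totals, dense + sparse = unique) is asserted before
#' returning.
#'
#' @param config a \code{\link{runConfig}} (or list of fields).
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{screen}, \code{calls}, \code{histogram}, \code{anchors},
#'   \code{report}, and \code{evaluation} if truth was available).
#' @export
runEndToEnd <- function(config, outDir) {
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outDir, "run.log")
  cat("", file = logfile)
  logmsg <- function(...) cat(..., "\n", sep = "", file = logfile,
                              append = TRUE)
  enz <- enzyme(config$enzyme)
  truth <- NULL

  if (config$simulate) {
    logmsg("stage simulate: ", config$n_clones, " clones on ",
           config$n_chrom, " x ", config$chrom_length, " bp, enzyme ",
           config$enzyme, ", error rate ", config$error_rate)
    genome <- simulateGenome(config$n_chrom, config$chrom_length,
                             config$gc, seed = config$seed)
    vec <- simulateVector(enz, seed = config$seed + 1L)
    clones <- simulateClones(genome, config$n_clones, config$insert_mean,
                             config$insert_sd, seed = config$seed + 2L)
    built <- buildJunctionFragments(clones, genome, enz, vec)
    sim <- simulateReads(built$junctions, genome, enz,
                         errorRate = config$error_rate,
                         readsPerJunction = config$reads_per_junction,
                         chimeraRate = config$chimera_rate,
                         backgroundRate = config$background_rate,
                         seed = config$seed + 3L)
    writeSimulation(sim, genome, clones, outDir)
    reads <- sim$reads
    truth <- sim$truth
    logmsg("  junctions: ", nrow(built$junctions), " (uncut clones: ",
           length(built$uncut), "); reads: ", length(reads))
    scr <- screenReads(reads, enz, minFlank = config$min_flank)
  } else {
    if (!all(file.exists(config$fastq)))
      stop_input("FASTQ input not found")
    scr <- screenFastq(config$fastq, enz, minFlank = config$min_flank)
    genome <- if (!is.null(config$genome_fasta))
      as_genome(config$genome_fasta) else NULL
  }
  s <- screenStats(scr)
  logmsg("stage screen: ", s["total"], " reads; with site ", s["with_site"],
         "; emitted ", s["emitted"], "; flank-rejected ",
         s["rejected_flank"], "; skipped ", s["skipped"])

  dd <- dedupeBySequence(splitReads(scr))
  splits <- dd$splits
  logmsg("stage dedupe-by-sequence: ", dd$counts["input"], " -> ",
         dd$counts["unique"])
  writeSplitReads(splits, file.path(outDir, "split_reads.tsv"))

  if (!is.null(config$sam)) {
    al <- readFlankSam(config$sam)
    logmsg("stage align: loaded ", nrow(al), " flank records from SAM")
  } else {
    al <- alignFlanksToy(splits, genome)
    logmsg("stage align (toy): ", sum(al$mapped), "/", nrow(al),
           " flanks placed")
  }

  callset <- classifyJunctions(al, mapqMin = config$mapq_min,
                               gapMin = config$gap_min,
                               gapMax = config$gap_max)
  calls <- junctionCalls(callset)
  stopifnot(sum(table(calls$category)) == nrow(calls))
  logmsg("stage classify: ", nrow(calls), " reads; ",
         paste(names(table(calls$category)), table(calls$category),
               collapse = ", "))
  writeJunctionCalls(calls, file.path(outDir, "junction_calls.tsv"))

  pd <- dedupeByPosition(calls)
  logmsg("stage dedupe-by-position: ", pd$counts["input"], " -> ",
         pd$counts["unique"])

  hist <- binGapHistogram(calls, window = c(config$gap_min, config$gap_max),
                          binWidth = config$bin_width)
  inwin <- calls$in_gap_window & !is.na(calls$gap) &
    calls$subtype %in% c("BAC_END", "INSERTION") &
    calls$uniqueness %in% c("UNIQUE", "MULTI")
  stopifnot(sum(hist$bacend_unique, hist$bacend_multi,
                hist$insertion_unique, hist$insertion_multi) == sum(inwin))
  utils::write.table(hist, file.path(outDir, "gap_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  anch <- chromosomeAnchorSummary(calls, gapLow = config$anchor_gap_low,
                                  gapHigh = config$anchor_gap_high,
                                  adjacency = config$adjacency)
  stopifnot(anch$totals["dense"] + anch$totals["sparse"] ==
              anch$totals["unique"])
  utils::write.table(anch$per_chrom,
                     file.path(outDir, "chromosome_anchors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeAnchorsBed(calls, file.path(outDir, "anchors.bed"))
  logmsg("stage report: ", anch$totals["unique"], " unique anchors (",
         anch$totals["dense"], " dense / ", anch$totals["sparse"],
         " sparse)")

  cats <- table(factor(calls$category,
                       levels = c("MATCH_SAME_CHR", "MATCH_DIFF_CHR",
                                  "NO_MATCH")))
  nsame <- sum(calls$category == "MATCH_SAME_CHR" &
                 calls$subtype %in% "BAC_END")
  nins <- sum(calls$category == "MATCH_SAME_CHR" &
                calls$subtype %in% "INSERTION")
  ratios <- mappingRatioReport(nsame, nins,
                               as.integer(cats["MATCH_DIFF_CHR"]),
                               as.integer(cats["NO_MATCH"]), nrow(calls))
  report <- list(
    enzyme = config$enzyme,
    screen = as.list(s),
    dedupe_sequence = as.list(dd$counts),
    categories = as.list(cats),
    ratios = ratios[c("mapped_pct", "samechr_pct")],
    gap_histogram_totals = list(
      bacend_unique = sum(hist$bacend_unique),
      bacend_multi = sum(hist$bacend_multi),
      insertion_unique = sum(hist$insertion_unique),
      insertion_multi = sum(hist$insertion_multi)),
    bacend_unique_60_100_pct =
      gapWindowFraction(hist$bacend_unique, config$anchor_gap_low,
                        config$anchor_gap_high,
                        window = c(config$gap_min, config$gap_max),
                        binWidth = config$bin_width)$pct,
    anchors = as.list(anch$totals))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- list(screen = scr, calls = callset, histogram = hist,
              anchors = anch, report = report)
  if (!is.null(truth)) {
    ev <- evaluateAgainstTruth(calls, truth)
    utils::write.table(as.data.frame(ev$confusion),
                       file.path(outDir, "evaluation_confusion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logmsg("stage evaluate: subtype accuracy ",
           format(ev$subtype_accuracy, digits = 4), "; max |gap error| ",
           if (nrow(ev$gap_errors)) max(abs(ev$gap_errors$error)) else NA)
    out$evaluation <- ev
  }

  manifest <- list(
    package = "BACends",
    version = as.character(utils::packageVersion("BACends")),
    seed = config$seed,
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))])
  cfgfile <- tempfile()
  on.exit(unlink(cfgfile), add = TRUE)
  saveRDS(manifest$config, cfgfile)
  manifest$config_hash <- unname(tools::md5sum(cfgfile))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
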