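test_that("simulated genomes are deterministic and respect GC", {
  g1 <- simulateGenome(2, 50000, 0.5, seed = 5)
  g2 <- simulateGenome(2, 50000, 0.5, seed = 5)
  expect_identical(as.character(g1), as.character(g2))
  expect_false(identical(as.character(simulateGenome(2, 50000, 0.5, 6)),
                         as.character(g1)))
  g3 <- simulateGenome(1, 200000, 0.3, seed = 5)
  af <- alphabetFrequency(g3)[1, c("A", "C", "G", "T")]
  gc <- sum(af[c("C", "G")]) / sum(af)
  expect_lt(abs(gc - 0.3), 0.01)
})

test_that("random-genome site counts match the closed-form motif probability", {
  # uniform bases: P(6-mer site) = 4^-6 at each of L-5 offsets
  g <- simulateGenome(1, 1e6, 0.5, seed = 17)
  n <- nrow(findSites(as.character(g[[1]]), ClaI))
  expected <- (1e6 - 5) / 4^6
  sd <- sqrt(expected * (1 - 4^-6))
  expect_lt(abs(n - expected), 4 * sd)

  # GC 0.3: MluI (4 G/C bases) is rarer than ClaI (2 G/C bases),
  # in the ratio (0.15/0.35)^2 of per-base probabilities
  g2 <- simulateGenome(1, 1e6, 0.3, seed = 18)
  ncla <- nrow(findSites(as.character(g2[[1]]), ClaI))
  nmlu <- nrow(findSites(as.character(g2[[1]]), MluI))
  expect_lt(nmlu, ncla)
  p_cla <- 0.35^4 * 0.15^2
  p_mlu <- 0.35^2 * 0.15^4
  expect_lt(abs(ncla - (1e6 - 5) * p_cla), 4 * sqrt((1e6 - 5) * p_cla))
  expect_lt(abs(nmlu - (1e6 - 5) * p_mlu), 4 * sqrt((1e6 - 5) * p_mlu))
})

test_that("simulated vectors never contain the enzyme site", {
  v <- simulateVector(ClaI, length = 8000, seed = 3)
  expect_equal(nrow(findSites(as.character(v), ClaI)), 0L)
  expect_equal(length(v), 8000L)
})

test_that("clone placement and insert-length distribution behave", {
  g <- simulateGenome(2, 1e6, 0.5, seed = 8)
  cl0 <- simulateClones(g, 100, insertSd = 0, seed = 9)
  expect_true(all(cl0$insert_length == 90000L))
  expect_true(all(cl0$insert_end - cl0$insert_start + 1L ==
                    cl0$insert_length))
  expect_true(all(cl0$insert_start >= 1L))
  expect_true(all(cl0$insert_end <= 1e6))

  expect_identical(simulateClones(g, 50, seed = 10),
                   simulateClones(g, 50, seed = 10))

  cl <- simulateClones(g, 1000, insertMean = 90000, insertSd = 5000,
                       seed = 11)
  se <- 5000 / sqrt(1000)
  expect_lt(abs(mean(cl$insert_length) - 90000), 3 * se)

  small <- simulateGenome(1, 50000, 0.5, seed = 1)
  expect_error(simulateClones(small, 5), "too short")
})

test_that("junction geometry follows digestion and autoligation", {
  # genome with planted sites so cut coordinates are known exactly
  set.seed(23)
  # CC caps prevent spurious motifs across part/site boundaries
  parts <- vapply(1:4, function(i)
    paste0("CC", seq_without_motif(990, ClaI), "CC"), character(1))
  # sites at 1-based starts 995, 1995, 2995 (cuts at 0-based 996, 1996, 2996)
  chr <- paste0(parts[1], "ATCGAT", parts[2], "ATCGAT", parts[3], "ATCGAT",
                parts[4])
  g <- DNAStringSet(c(chr1 = chr))
  stopifnot(identical(findSites(chr, ClaI)$start, c(995L, 1995L, 2995L)))
  vec <- simulateVector(ClaI, length = 2000, seed = 2)

  # insert covering all three sites
  clones <- data.frame(clone_id = "cl1", chrom = "chr1",
                       insert_start = 501L, insert_end = 3500L,
                       insert_length = 3000L)
  built <- buildJunctionFragments(clones, g, ClaI, vec)
  j <- built$junctions
  be <- j[j$type == "BAC_END", ]
  expect_equal(nrow(be), 1L)
  expect_equal(be$expected_gap, 2996 - 996)
  expect_equal(be$expected_inner_gap, be$expected_gap + 6L)
  expect_lte(be$expected_gap, clones$insert_length)
  ins <- j[j$type == "INSERTION", ]
  expect_equal(ins$expected_gap, c(1000L, 1000L))
  expect_equal(ins$expected_inner_gap, c(994L, 994L))

  # geometry identity: clone-end gap = insert - terminal pieces
  left_piece <- 996 - (clones$insert_start - 1L)
  right_piece <- clones$insert_end - 2996
  expect_equal(be$expected_gap,
               clones$insert_length - left_piece - right_piece)

  # a site only partially inside the insert is not cut
  clip <- data.frame(clone_id = "cl2", chrom = "chr1",
                     insert_start = 998L, insert_end = 2200L,
                     insert_length = 1203L)
  j2 <- buildJunctionFragments(clip, g, ClaI, vec)$junctions
  expect_equal(j2$type, "BAC_END")  # only the site at 1995 is internal
  expect_equal(j2$cut_left, 1996L)

  # no internal site: clone flagged uncut, no junctions
  uncut <- data.frame(clone_id = "cl3", chrom = "chr1",
                      insert_start = 10L, insert_end = 900L,
                      insert_length = 891L)
  b3 <- buildJunctionFragments(uncut, g, ClaI, vec)
  expect_equal(nrow(b3$junctions), 0L)
  expect_equal(b3$uncut, "cl3")

  # vector carrying a site is a configuration error
  badvec <- paste0("AAAA", "ATCGAT", "TTTT")
  expect_error(buildJunctionFragments(clones, g, ClaI, badvec), "vector")
})

test_that("error-free junction reads contain the restored site and map back", {
  run <- run_sim_pipeline(seed = 41, n_chrom = 1, chrom_length = 2e5,
                          n_clones = 30)
  reads <- run$sim$reads
  expect_gt(length(reads), 0L)
  expect_true(all(vcountPattern("ATCGAT", reads) >= 1L))
  # count conservation with readsPerJunction
  sim3 <- simulateReads(run$junctions[1:10, ], run$genome, ClaI,
                        readsPerJunction = 3, seed = 1)
  expect_equal(nrow(sim3$truth), 30L)
  expect_equal(length(sim3$reads), 30L)
  # determinism: identical seeds give identical reads and truth
  sim_a <- simulateReads(run$junctions, run$genome, ClaI, seed = 7)
  sim_b <- simulateReads(run$junctions, run$genome, ClaI, seed = 7)
  expect_identical(as.character(sim_a$reads), as.character(sim_b$reads))
  expect_identical(sim_a$truth, sim_b$truth)
})

test_that("substitution errors appear at the stated rate", {
  run <- run_sim_pipeline(seed = 43, n_chrom = 1, chrom_length = 2e5,
                          n_clones = 20)
  clean <- simulateReads(run$junctions, run$genome, ClaI, errorRate = 0,
                         seed = 5)
  noisy <- simulateReads(run$junctions, run$genome, ClaI, errorRate = 0.01,
                         seed = 5)
  stopifnot(identical(clean$truth$read_id, noisy$truth$read_id))
  mism <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, as.character(clean$reads), as.character(noisy$reads))
  n_reads <- length(mism)
  expected <- 150 * 0.01
  se <- sqrt(150 * 0.01 * 0.99 / n_reads)
  expect_lt(abs(mean(mism) - expected), 4 * se)
})

test_that("the end-to-end oracle recovers every unique junction exactly", {
  run <- run_sim_pipeline(seed = 47, n_chrom = 1, chrom_length = 3e5,
                          n_clones = 40)
  ev <- evaluateAgainstTruth(run$calls, run$sim$truth)
  calls <- junctionCalls(run$calls)
  uq <- calls$uniqueness %in% "UNIQUE"
  m <- merge(calls[uq, ], run$sim$truth, by = "read_id")
  expect_true(all(m$subtype == m$type))
  expect_true(all(m$gap == m$expected_inner_gap))
  expect_equal(ev$subtype_accuracy, 1)
  expect_equal(nrow(ev$gap_errors), sum(calls$category == "MATCH_SAME_CHR"))
  expect_true(all(ev$gap_errors$error == 0))
  expect_equal(length(ev$unmatched),
               nrow(run$sim$truth) - nrow(calls))
})

test_that("permuted truth labels destroy the apparent accuracy", {
  run <- run_sim_pipeline(seed = 53, n_chrom = 1, chrom_length = 2e5,
                          n_clones = 20)
  truth <- run$sim$truth
  set.seed(1)
  truth$type <- sample(truth$type)
  ev <- evaluateAgainstTruth(run$calls, truth)
  expect_lt(ev$subtype_accuracy, 1)
  expect_gt(ev$subtype_accuracy, 0)
})

test_that("substitutions knock out flank mapping at the expected rate", {
  run <- run_sim_pipeline(seed = 59, n_chrom = 1, chrom_length = 3e5,
                          n_clones = 40, error_rate = 0.01)
  scr <- run$screen
  al <- run$alignments
  # each flank maps iff all its bases are error-free: P = 0.99^len
  lens <- c(nchar(splitReads(scr)$left_flank),
            nchar(splitReads(scr)$right_flank))
  p <- 0.99^lens
  expected <- mean(p)
  sd <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(al$mapped) - expected), 4 * sd + 0.01)
})

test_that("chimeric junctions are classified as different-chromosome", {
  run <- run_sim_pipeline(seed = 61, n_chrom = 2, chrom_length = 2e5,
                          n_clones = 30, chimeraRate = 0.3)
  m <- merge(junctionCalls(run$calls), run$sim$truth, by = "read_id")
  chim <- m[m$type == "CHIMERA" & m$chromL.y != m$chromR.y, ]
  expect_gt(nrow(chim), 0L)
  expect_true(all(chim$category == "MATCH_DIFF_CHR"))
})

test_that("background reads carry no junction and are filtered upstream", {
  run <- run_sim_pipeline(seed = 67, n_chrom = 1, chrom_length = 2e5,
                          n_clones = 10, backgroundRate = 0.5)
  truth <- run$sim$truth
  expect_gt(sum(truth$type == "BACKGROUND"), 0L)
  emitted <- splitReads(run$screen)$read_id
  bg_emitted <- intersect(emitted, truth$read_id[truth$type == "BACKGROUND"])
  # a random 150-mer rarely contains the 6-bp site with 19 bp flanks
  expect_lt(length(bg_emitted), sum(truth$type == "BACKGROUND") * 0.2)
})

test_that("simulation files are written and byte-deterministic", {
  run <- run_sim_pipeline(seed = 71, n_chrom = 1, chrom_length = 3e5,
                          n_clones = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sim1 <- simulateReads(run$junctions, run$genome, ClaI, seed = 2)
  sim2 <- simulateReads(run$junctions, run$genome, ClaI, seed = 2)
  writeSimulation(sim1, run$genome, run$clones, d1)
  writeSimulation(sim2, run$genome, run$clones, d2)
  # FASTQ written uncompressed for the byte comparison
  writeXStringSet(sim1$reads, file.path(d1, "reads.fastq"),
                  format = "fastq")
  writeXStringSet(sim2$reads, file.path(d2, "reads.fastq"),
                  format = "fastq")
  expect_identical(unname(tools::md5sum(file.path(d1, "reads.fastq"))),
                   unname(tools::md5sum(file.path(d2, "reads.fastq"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "truth.tsv"))),
                   unname(tools::md5sum(file.path(d2, "truth.tsv"))))
  expect_true(all(file.exists(file.path(d1, c("genome.fa",
                                              "reads.fastq.gz",
                                              "truth.tsv", "clones.tsv")))))
})
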