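test_that("mapping ratios reproduce the published library accounting", {
  # ClaI column of the category table
  cla <- mappingRatioReport(1549145, 445813, 2433257, 22046957, 9819130)
  expect_equal(cla$mapped_pct, 45.10)
  expect_equal(cla$samechr_pct, 20.32)
  # MluI column
  mlu <- mappingRatioReport(438688, 194327, 1061139, 18167773, 6228861)
  expect_equal(mlu$mapped_pct, 27.20)
  expect_equal(mlu$samechr_pct, 10.16)
  # degenerate inputs
  z <- mappingRatioReport(0, 0, 0, 0, 10)
  expect_equal(z$mapped_pct, 0)
  zz <- mappingRatioReport(0, 0, 0, 0, 0)
  expect_true(zz$degenerate)
  expect_error(mappingRatioReport(5, 0, 0, 0, 3), "smaller")
})

test_that("percentage rounding is half-up to the printed precision", {
  expect_equal(roundHalfUp(45.095, 2), 45.10)
  expect_equal(roundHalfUp(45.094, 2), 45.09)
  expect_equal(roundHalfUp(19.405, 0), 19)
  expect_equal(roundHalfUp(0.125, 2), 0.13)
})

fake_call <- function(id, gap, subtype = "BAC_END", uniq = "UNIQUE",
                      chrom = "chr1", innerL = 1000L) {
  data.frame(read_id = id, category = "MATCH_SAME_CHR", subtype = subtype,
             uniqueness = uniq, gap = as.integer(gap),
             in_gap_window = gap >= 1000 & gap <= 150000,
             chromL = chrom, innerL = as.integer(innerL), strandL = "+",
             chromR = chrom, innerR = as.integer(innerL + gap),
             strandR = "+")
}

test_that("gap histogram bins are lower-inclusive 10 kb bins over 1-150 kb", {
  calls <- rbind(fake_call("a", 5000), fake_call("b", 65000),
                 fake_call("c", 75000), fake_call("d", 75500),
                 fake_call("e", 149999),
                 fake_call("f", 500),      # below window: excluded
                 fake_call("g", 15000, subtype = "INSERTION"),
                 fake_call("h", 70000, uniq = "MULTI"))
  h <- binGapHistogram(calls)
  expect_equal(nrow(h), 15L)
  expect_equal(h$bacend_unique[h$label == "1-10"], 1L)
  expect_equal(h$bacend_unique[h$label == "60-70"], 1L)
  expect_equal(h$bacend_unique[h$label == "70-80"], 2L)
  expect_equal(h$bacend_unique[h$label == "140-150"], 1L)
  expect_equal(sum(h$bacend_unique), 5L)
  expect_equal(sum(h$insertion_unique), 1L)
  expect_equal(sum(h$bacend_multi), 1L)
  # conservation: histogram totals equal in-window call counts per stratum
  expect_equal(sum(h$bacend_unique),
               sum(calls$in_gap_window & calls$subtype == "BAC_END" &
                     calls$uniqueness == "UNIQUE"))
  # boundary: exactly 10 kb falls in the 10-20 bin
  h2 <- binGapHistogram(fake_call("x", 10000))
  expect_equal(h2$bacend_unique[h2$label == "10-20"], 1L)
  # empty input
  expect_equal(sum(colSums(binGapHistogram(fake_call("x", 1)[0, ])[, -(1:3)])),
               0L)
})

test_that("published gap-bin columns recompute their printed fractions", {
  # unique clone-end gap bins, ClaI then MluI
  cla_unique <- c(627506, 2848, 1306, 1231, 2957, 7679, 35264, 77251,
                  62421, 19425, 5388, 3585, 3602, 1295, 466)
  expect_equal(sum(cla_unique), 852224)
  expect_equal(gapWindowFraction(cla_unique)$pct, 22.81)
  mlu_unique <- c(131947, 5, 2732, 163, 44, 2180, 19262, 13816, 2179,
                  9643, 295, 24, 0, 536, 52)
  expect_equal(sum(mlu_unique), 182878)
  expect_equal(gapWindowFraction(mlu_unique)$pct, 24.55)
  expect_equal(gapWindowFraction(mlu_unique, 1000, 10000)$pct, 72.15)
  # unique internal-fragment circularizations, ClaI: 1-20 kb share
  cla_ins <- c(6519, 3779, 303, 65, 47, 26, 234, 7, 459, 9, 6, 12, 1, 5, 34)
  expect_equal(sum(cla_ins), 11506)
  expect_equal(gapWindowFraction(cla_ins, 1000, 20000)$pct, 89.50)
})

test_that("chromosome anchor summary filters, dedups and partitions", {
  calls <- rbind(
    fake_call("a", 70000, innerL = 10000),
    fake_call("b", 70000, innerL = 10000),    # positional duplicate of a
    fake_call("c", 150000, innerL = 40000),   # outside 60-100 kb window
    fake_call("d", 80000, chrom = "chr2", innerL = 500000))
  s <- chromosomeAnchorSummary(calls)
  expect_equal(s$per_chrom$chrom, c("chr1", "chr2"))
  expect_equal(s$per_chrom$total, c(2L, 1L))
  expect_equal(s$per_chrom$unique, c(1L, 1L))
  expect_equal(unname(s$totals["dense"] + s$totals["sparse"]),
               unname(s$totals["unique"]))
  # each chromosome has a lone anchor: both sparse
  expect_equal(unname(s$totals["sparse"]), 2L)

  empty <- chromosomeAnchorSummary(calls[0, ])
  expect_equal(unname(empty$totals["unique"]), 0L)
})

test_that("adjacency partition flags anchors with a close neighbour", {
  anchors <- data.frame(chrom = "chr1", pos = c(10000, 50000, 400000))
  p <- adjacencyPartition(anchors)
  expect_equal(p$dense, 2L)
  expect_equal(p$sparse, 1L)
  expect_equal(p$n, 3L)

  single <- adjacencyPartition(data.frame(chrom = "chr1", pos = 5000))
  expect_equal(single$sparse, 1L)
  expect_equal(single$dense, 0L)

  # conservation across chromosomes
  multi <- adjacencyPartition(data.frame(
    chrom = rep(c("chr1", "chr2"), c(3, 2)),
    pos = c(10000, 50000, 400000, 100, 90000)))
  expect_equal(sum(multi$dense + multi$sparse), 5L)
})

test_that("window density tiles chromosomes from zero", {
  anchors <- data.frame(chrom = "chr1", pos = c(10000, 20000, 150000))
  wd <- windowDensity(anchors)
  expect_equal(wd$tiles$count, c(2L, 1L))
  expect_equal(wd$tiles$tile_start, c(0L, 100000L))
  expect_equal(wd$max_count, 2L)
  expect_equal(windowDensity(anchors[0, ])$max_count, 0L)
  # dense fixture: seven anchors in one tile
  dense <- data.frame(chrom = "chr1", pos = seq(36400000, 36460000,
                                                by = 10000))
  expect_equal(windowDensity(dense)$max_count, 7L)
})

test_that("interlength categorization follows the long-read match rules", {
  hits <- rbind(
    data.frame(clone_id = "clone68", side = c(1, 2), chrom = "chr4",
               position = c(10000, 114960), align_length = 500,
               input_length = 1200),
    data.frame(clone_id = "cl_diff", side = c(1, 2),
               chrom = c("chr2", "chr7"), position = c(1, 2),
               align_length = 400, input_length = 1100),
    data.frame(clone_id = "cl_one", side = c(1, 2), chrom = "chr1",
               position = c(1, 2), align_length = c(400, 150),
               input_length = 1100),
    data.frame(clone_id = "cl_none", side = c(1, 2), chrom = "chr1",
               position = c(1, 2), align_length = 100, input_length = 500))
  res <- interlengthCategorize(hits)
  rec <- res$records
  rownames(rec) <- rec$clone_id
  expect_equal(rec["clone68", "category"], "same-chrom")
  expect_equal(rec["clone68", "interlength"], 104960)
  expect_equal(rec["clone68", "bin"], "100-110")
  expect_equal(rec["cl_diff", "category"], "different-chrom")
  expect_equal(rec["cl_one", "category"], "one-end")
  expect_equal(rec["cl_none", "category"], "no-match")
  expect_equal(unname(res$bin_counts["100-110"]), 1L)
  expect_equal(unname(res$bin_counts["different-chrom"]), 1L)

  # strict mode: coverage ratio > 0.8 required
  strict <- interlengthCategorize(hits, strict = TRUE)
  expect_equal(strict$records[strict$records$clone_id == "clone68",
                              "category"], "no-match")

  # more than two hits: best alignment per side wins
  multi <- rbind(
    data.frame(clone_id = "m", side = 1, chrom = c("chr1", "chr9"),
               position = c(5000, 99), align_length = c(600, 310),
               input_length = 1500),
    data.frame(clone_id = "m", side = 2, chrom = "chr1",
               position = 95000, align_length = 450, input_length = 1500))
  mrec <- interlengthCategorize(multi)$records
  expect_equal(mrec$category, "same-chrom")
  expect_equal(mrec$interlength, 90000)

  # boundary bins
  expect_equal(interlengthCategorize(rbind(
    data.frame(clone_id = "t", side = 1:2, chrom = "chr1",
               position = c(0, 900), align_length = 400,
               input_length = 1100)))$records$bin, "<1")
  expect_equal(interlengthCategorize(rbind(
    data.frame(clone_id = "t", side = 1:2, chrom = "chr1",
               position = c(0, 160000), align_length = 400,
               input_length = 1100)))$records$bin, ">150")
})

test_that("published long-read categories recompute their totals", {
  same_bins <- c(4, 4, 1, 1, 2, 3, 8, 10, 5, 2, 2, 0, 0, 0, 9)
  expect_equal(sum(same_bins), 51)
  total <- sum(same_bins) + 46 + 9 + 3
  expect_equal(total, 109)
  in60_100 <- sum(same_bins[6:9])  # 60-70 .. 90-100
  expect_equal(in60_100, 26)
  expect_equal(roundHalfUp(in60_100 / total * 100, 2), 23.85)
})

test_that("zygosity summary counts base types per site", {
  z <- zygositySummary(c("A", "A,G", "C", "C,T,G", ""))
  expect_equal(z$homozygous, 2L)
  expect_equal(z$heterozygous, 2L)
  expect_equal(z$skipped, 1L)
  expect_equal(z$hom_pct, 50)
  # published split: 556088 hom / 2309584 het -> 19% / 81%
  big <- zygositySummary(c(rep("A", 55609), rep("A,G", 230958)))
  expect_equal(big$hom_pct, 19)
  expect_equal(big$het_pct, 81)
  expect_equal(big$hom_pct + big$het_pct, 100)
})

test_that("VCF-based zygosity approximates the read-level rule", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "sites.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/1",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t1/1",
    "chr1\t300\t.\tG\tA\t50\tPASS\t.\tGT\t0/0"), vcf)
  z <- zygosityFromVcf(vcf)
  expect_equal(z$heterozygous, 1L)
  expect_equal(z$homozygous, 2L)
})
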