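test_that("read_fragments parses BED, BEDPE and SAM dialects into half-open intervals", {
  gt <- genome_table(c(chr2L = 1e6))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), bed)
  expect_equal(nrow(read_fragments(bed, "bed")), 0L)

  writeLines("chr2L\t100\t180", bed)
  fr <- read_fragments(bed, "bed", genome = gt)
  expect_equal(fr[, c("chrom", "start", "end")],
               data.frame(chrom = "chr2L", start = 100L, end = 180L))
  expect_equal(fragment_lengths(fr), 80L)

  # mate pair spanning 100-150 and 160-180 -> outermost coordinates;
  # hand parse: min(100,160)=100, max(150,180)=180
  bedpe <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr2L\t100\t150\tchr2L\t160\t180\tp1\t0\t+\t-", bedpe)
  fr2 <- read_fragments(bedpe, "bedpe", genome = gt)
  expect_equal(fr2$start, 100L)
  expect_equal(fr2$end, 180L)

  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:chr2L\tLN:1000000",
               "r1\t99\tchr2L\t101\t60\t50M\t=\t131\t80\t*\t*",
               "r1\t147\tchr2L\t131\t60\t50M\t=\t101\t-80\t*\t*"), sam)
  fr3 <- read_fragments(sam, "sam", genome = gt)
  expect_equal(nrow(fr3), 1L)  # pair counted once
  expect_equal(fr3$start, 100L)
  expect_equal(fr3$end, 180L)

  writeLines(c("chr2L\t100\t180", "chr2L\tnope\t300"), bed)
  expect_error(read_fragments(bed, "bed"), "line 2")
  writeLines("chrUnknown\t0\t50", bed)
  expect_error(read_fragments(bed, "bed", genome = gt), "chrUnknown")
})

test_that("partition_by_size uses a strict < threshold and keeps short fragments in 'all'", {
  fr <- fragments("c", c(0, 0, 0, 0), c(80, 119, 120, 150))
  parts <- partition_by_size(fr, threshold = 120)
  expect_setequal(fragment_lengths(parts$short), c(80L, 119L))
  expect_identical(parts$all, fr)
  expect_equal(fragment_lengths(parts$nucleosomal), c(120L, 150L))
  expect_equal(nrow(parts$short) + nrow(parts$nucleosomal), nrow(parts$all))

  empty <- fragments(character(0), integer(0), integer(0))
  pe <- partition_by_size(empty)
  expect_equal(nrow(pe$short), 0L)
  expect_equal(nrow(pe$all), 0L)

  big <- fragments("c", c(0, 0), c(150, 200))
  pb <- partition_by_size(big)
  expect_equal(nrow(pb$short), 0L)
  expect_identical(pb$all, big)
})

test_that("downsample_fragments is uniform, exact, and deterministic under a seed", {
  fr_a <- fragments(rep("c", 100), 0:99, 100:199, sample = "a")
  fr_b <- fragments(rep("c", 60), 0:59, 100:159, sample = "b")

  same <- downsample_fragments(list(a = fr_a[1:5, ]), target = 5, seed = 3)
  expect_identical(same$a, fr_a[1:5, ])

  ds <- downsample_fragments(list(a = fr_a, b = fr_b), target = "min", seed = 3)
  expect_equal(vapply(ds, nrow, integer(1)), c(a = 60L, b = 60L))

  d1 <- downsample_fragments(list(a = fr_a), target = 40, seed = 11)
  d2 <- downsample_fragments(list(a = fr_a), target = 40, seed = 11)
  expect_identical(d1, d2)
  # subset of the input
  expect_true(all(d1$a$start %in% fr_a$start))

  expect_error(downsample_fragments(list(b = fr_b), target = 100), "exceeds")
})

test_that("fragment_coverage bins mean per-base depth with full extension", {
  gt <- genome_table(c(c1 = 50))
  expect_equal(fragment_coverage(fragments("c1", 0, 50), gt, 25)$values$c1, c(1, 1))
  # hand count: fragment [10,20) overlaps bin [0,25) with 10 bases -> 10/25
  expect_equal(fragment_coverage(fragments("c1", 10, 20), gt, 25)$values$c1, c(0.4, 0))
  # linearity
  two <- fragment_coverage(fragments("c1", c(5, 5), c(40, 40)), gt, 25)
  one <- fragment_coverage(fragments("c1", 5, 40), gt, 25)
  expect_equal(two$values$c1, 2 * one$values$c1)

  expect_error(fragment_coverage(fragments("c1", 40, 60), gt, 25), "beyond")
})

test_that("raw coverage conserves fragment bases exactly over random inputs", {
  set.seed(7)
  gt <- genome_table(c(a = 3137, b = 911))
  for (i in 1:5) {
    n <- 200
    chrom <- sample(names(gt), n, replace = TRUE)
    start <- floor(runif(n, 0, gt[chrom] - 260))
    len <- sample(50:250, n, replace = TRUE)
    fr <- fragments(chrom, start, start + len, genome = gt)
    for (bs in c(10, 25, 100)) {
      track <- fragment_coverage(fr, gt, bs)
      expect_equal(sum(unlist(track$values)) * bs, sum(fragment_lengths(fr)))
    }
  }
})

test_that("write_bedgraph merges runs, omits zeros, and round-trips bin values", {
  gt <- genome_table(c(c1 = 75))
  path <- withr::local_tempfile(fileext = ".bedgraph")

  zero <- fragment_coverage(fragments(character(0), integer(0), integer(0)), gt, 25)
  write_bedgraph(zero, path)
  expect_equal(length(readLines(path)), 0L)

  track <- fragment_coverage(fragments("c1", 0, 50), gt, 25)  # bins 1,1,0
  write_bedgraph(track, path)
  lines <- readLines(path)
  expect_equal(length(lines), 1L)
  expect_equal(strsplit(lines, "\t")[[1]], c("c1", "0", "50", "1"))

  # round-trip: re-binning the imported intervals reproduces the bin values
  set.seed(21)
  gt2 <- genome_table(c(c1 = 1000))
  start <- sample(0:800, 40, replace = TRUE)
  fr <- fragments(rep("c1", 40), start, start + sample(50:190, 40, replace = TRUE))
  track2 <- fragment_coverage(fr, gt2, 25)
  write_bedgraph(track2, path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  rebinned <- numeric(length(track2$values$c1))
  for (i in seq_along(gr)) {
    b0 <- (BiocGenerics::start(gr[i]) - 1L) %/% 25L + 1L
    b1 <- (BiocGenerics::end(gr[i]) - 1L) %/% 25L + 1L
    rebinned[b0:b1] <- gr$score[i]
  }
  expect_equal(rebinned, track2$values$c1)
})
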