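test_that("flank_ratio is zero on symmetric or empty coverage and exact on known sums", {
  # symmetric coverage around the summit
  sym <- make_track(rep(2, 200), 25)
  expect_equal(flank_ratio(list(chrom = "c1", summit = 2500), sym, 1000), 0)

  # 5' sum 15, 3' sum 255 -> log2(256/16) = 4
  v2 <- rep(0, 200)
  v2[41:80] <- 15 / 1000    # [1000, 2000)
  v2[81:121] <- 255 / 1000  # [2000, 3025)
  track2 <- make_track(v2, 25)
  expect_equal(flank_ratio(list(chrom = "c1", summit = 2000), track2, 1000), 4)

  # zero coverage both sides -> pseudocount identity
  expect_equal(flank_ratio(list(chrom = "c1", summit = 2500),
                           make_track(rep(0, 200), 25), 1000), 0)

  expect_error(flank_ratio(list(chrom = "c1", summit = 100),
                           make_track(rep(1, 200), 25), 1000), "bounds")
})

test_that("flank_ratio is antisymmetric under coordinate mirroring", {
  set.seed(31)
  for (i in 1:10) {
    v <- runif(400)
    track <- make_track(v, 25)
    mirrored <- make_track(rev(v), 25)
    L <- 400 * 25
    s <- sample(2000:8000, 1)
    r1 <- flank_ratio(list(chrom = "c1", summit = s), track, 1000)
    r2 <- flank_ratio(list(chrom = "c1", summit = L - 1 - s), mirrored, 1000)
    expect_equal(r1, -r2, tolerance = 1e-6)
  }
})

test_that("classify_peaks labels border, internal and outside summits correctly", {
  doms <- data.frame(chrom = "c1", start = c(10000L, 50000L), end = c(20000L, 58000L))
  pk <- function(summit) data.frame(chrom = "c1", summit = summit)
  expect_equal(classify_peaks(pk(10000), doms)$label, "five_prime_border")
  expect_equal(classify_peaks(pk(15000), doms)$label, "internal")
  expect_equal(classify_peaks(pk(20100), doms)$label, "three_prime_border")
  expect_equal(classify_peaks(pk(30000), doms)$label, "outside")
  # lower edge wins on a narrow domain
  narrow <- data.frame(chrom = "c1", start = 1000L, end = 2500L)
  expect_equal(classify_peaks(pk(1800), narrow)$label, "five_prime_border")

  overlapping <- data.frame(chrom = "c1", start = c(0L, 500L), end = c(1000L, 1500L))
  expect_error(classify_peaks(pk(100), overlapping), "disjoint")
})

test_that("classification labels are exhaustive and match a reference rule", {
  set.seed(55)
  slack <- 1000L
  for (rep in 1:10) {
    n_dom <- sample(1:4, 1)
    edges <- sort(sample(seq(0, 2e5, by = 100), n_dom * 2))
    doms <- data.frame(chrom = "c1", start = edges[seq(1, by = 2, length.out = n_dom)],
                       end = edges[seq(2, by = 2, length.out = n_dom)])
    doms <- doms[doms$end - doms$start >= 1, , drop = FALSE]
    peaks <- data.frame(chrom = "c1", summit = sample(0:2e5, 50))
    got <- classify_peaks(peaks, doms, border_slack_bp = slack)$label
    ref <- vapply(peaks$summit, function(s) {
      for (k in seq_len(nrow(doms))) {
        if (abs(s - doms$start[k]) <= slack) return("five_prime_border")
        if (abs(s - doms$end[k]) <= slack) return("three_prime_border")
        if (s > doms$start[k] + slack && s < doms$end[k] - slack) return("internal")
      }
      "outside"
    }, character(1))
    expect_equal(got, ref)
    expect_true(all(got %in% c("five_prime_border", "three_prime_border",
                               "internal", "outside")))
  }
})

test_that("profile_matrix reproduces coverage rows and sorts by flank asymmetry", {
  cfg <- analysis_config()
  uniform <- make_track(rep(1, 400), 25)
  pk <- data.frame(chrom = "c1", summit = 5000L)
  pm <- profile_matrix(pk, uniform, cfg)
  expect_equal(dim(pm$matrix), c(1L, 2L * cfg$flank_bp %/% 25L))
  expect_true(all(pm$matrix == 1))

  # two peaks with opposite asymmetry: the 3'-skewed one sorts first
  v <- rep(0, 400)
  v[201:240] <- 5   # [5000, 6000) high: 3' flank of peak A, 5' flank of peak B
  track <- make_track(v, 25)
  pks <- data.frame(chrom = "c1", summit = c(4995L, 6005L))
  pm2 <- profile_matrix(pks, track, cfg)
  expect_equal(pm2$order, c(1L, 2L))
  expect_gt(pm2$flank_log2_ratio[1], 0)
  expect_lt(pm2$flank_log2_ratio[2], 0)

  # column means equal the mean of rows exactly, and label means split rows
  pm3 <- profile_matrix(pks, track, cfg, labels = c("a", "b"))
  expect_equal(pm3$colmeans, colMeans(rbind(pm3$matrix)))
  expect_equal(pm3$label_means$a + pm3$label_means$b, 2 * pm3$colmeans)
})

test_that("vplot bins midpoint offsets against lengths and conserves counts", {
  cfg <- analysis_config()
  fr <- short_frags_at(rep(5000L, 7), len = 80L)
  vp <- vplot(fr, data.frame(chrom = "c1", summit = 5000L), cfg)
  expect_equal(vp$total, 7L)
  expect_equal(sum(vp$counts), 7L)
  nz <- which(vp$counts > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1L)
  expect_equal(vp$counts[nz], 7L)
  # length 80 falls in the [80, 85) bin; offset 0 in the bin containing zero
  expect_equal(vp$y_mids[nz[1]], 82.5)
  expect_true(abs(vp$x_mids[nz[2]]) <= 5)

  # empty summit list -> empty matrix
  vp0 <- vplot(fr, data.frame(chrom = character(0), summit = integer(0)), cfg)
  expect_equal(vp0$total, 0L)
  expect_equal(sum(vp0$counts), 0L)

  # total equals in-window fragments over random data
  set.seed(77)
  mids <- sample(0:49999, 400, replace = TRUE)
  lens <- sample(50:250, 400, replace = TRUE)
  fr2 <- fragments(rep("c1", 400), mids - lens %/% 2L, mids - lens %/% 2L + lens)
  summits <- data.frame(chrom = "c1", summit = c(10000L, 30000L))
  vp2 <- vplot(fr2, summits, cfg)
  dmin <- pmin(abs(fragment_midpoints(fr2) - 10000L), abs(fragment_midpoints(fr2) - 30000L))
  expect_equal(vp2$total, sum(dmin <= cfg$flank_bp))
  expect_equal(sum(vp2$counts), vp2$total)
})

test_that("short fragments concentrate at element summits, nucleosomal ones flank them", {
  spec <- dhd_fixture()
  libs <- simulate_fragments(spec, seed = 6)
  fr <- libs$control.rep1
  summits <- data.frame(chrom = spec$elements$chrom, summit = spec$elements$center)
  vp <- vplot(fr, summits)
  short_rows <- vp$y_mids >= 50 & vp$y_mids <= 130
  nuc_rows <- vp$y_mids >= 150 & vp$y_mids <= 250
  near <- abs(vp$x_mids) <= 80
  far <- abs(vp$x_mids) >= 100
  short_counts <- vp$counts[short_rows, , drop = FALSE]
  nuc_counts <- vp$counts[nuc_rows, , drop = FALSE]
  # sub-nucleosomal mass is concentrated on the footprint
  expect_gt(sum(short_counts[, near]) / sum(short_counts), 0.8)
  # nucleosome-sized mass sits away from the footprint center
  expect_gt(sum(nuc_counts[, far]) / sum(nuc_counts), 0.75)
})
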