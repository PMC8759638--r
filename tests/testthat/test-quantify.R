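region <- function(name, start, end, chrom = "c1") {
  data.frame(name = name, chrom = chrom, start = start, end = end)
}

test_that("quantify_regions counts midpoints, normalizes per million, and contrasts", {
  # control: 200 of 10000 midpoints in the region; KD: 130 of 10000 -> -35%
  mk <- function(n_in, n_out, smp) {
    rbind(short_frags_at(seq(1000, 1999, length.out = n_in)),
          short_frags_at(seq(50000, 90000, length.out = n_out)))
  }
  sets <- list(control = mk(200, 9800), kd = mk(130, 9870))
  q <- quantify_regions(sets, region("r1", 960, 2040), control = "control")
  expect_equal(q$count, c(200L, 130L))
  expect_equal(q$cpm, c(200, 130) / 10000 * 1e6)
  expect_equal(q$percent_change[q$sample == "kd"], -35)
  expect_true(is.na(q$percent_change[q$sample == "control"]))

  # identical sets -> zero percent change
  q0 <- quantify_regions(list(control = sets$control, same = sets$control),
                         region("r1", 960, 2040), control = "control")
  expect_equal(q0$percent_change[q0$sample == "same"], 0)

  # empty region -> zero counts, flagged, undefined contrast
  qe <- quantify_regions(sets, region("empty", 200000, 201000), control = "control")
  expect_true(all(qe$count == 0L))
  expect_true(all(qe$control_zero))
  expect_true(all(is.na(qe$percent_change)))
})

test_that("quantify_regions is invariant under fragment order permutation", {
  set.seed(19)
  mids <- sample(0:99999, 3000, replace = TRUE)
  fr <- short_frags_at(mids)
  sets1 <- list(control = fr, kd = fr[sample(nrow(fr)), ])
  regs <- region(c("a", "b"), c(10000, 40000), c(20000, 70000))
  q <- quantify_regions(sets1, regs, control = "control")
  expect_equal(q$count[q$sample == "kd"], q$count[q$sample == "control"])
  expect_equal(q$percent_change[q$sample == "kd"], c(0, 0))
})

test_that("meta_domain_profile rescales bodies, keeps flanks native, and is linear", {
  cfg <- analysis_config()
  # 10kb uniform domain at value 4 on a zero background, bin-aligned
  v <- rep(0, 800)
  v[201:600] <- 4
  track <- make_track(v, 25)
  dom <- data.frame(chrom = "c1", start = 5000L, end = 15000L)
  mp <- meta_domain_profile(track, dom, cfg)
  expect_equal(length(mp$profile), 100 + 2 * cfg$meta_flank_bp / 100)
  body <- mp$profile[(mp$flank_bins + 1):(mp$flank_bins + 100)]
  flanks <- mp$profile[c(1:(mp$flank_bins - 1),
                         (mp$flank_bins + 102):length(mp$profile))]
  expect_equal(body[10:90], rep(4, 81), tolerance = 1e-8)
  expect_true(all(flanks[1:20] == 0))
  # linearity
  mp2 <- meta_domain_profile(make_track(2 * v, 25), dom, cfg)
  expect_equal(mp2$profile, 2 * mp$profile)
  # too-narrow domains are skipped with a warning
  expect_warning(
    meta_domain_profile(track, rbind(dom, data.frame(chrom = "c1", start = 0L,
                                                     end = 50L)), cfg),
    "skipped")
})

test_that("a planted global domain effect is recovered from meta-domain profiles", {
  gt <- genome_table(c(c1 = 5e5))
  dom <- planted_domain("d", "c1", 200000, 240000, 250)
  mk_spec <- function(scale) {
    synthetic_spec(gt, domains = dom, background_rate = 25,
                   short_background_rate = 0,
                   conditions = list(control = effect_profile(),
                                     kd = effect_profile(scale)),
                   replicates = 1L)
  }
  cfg <- analysis_config()
  spec <- mk_spec(0.65)
  ratios <- vapply(1:20, function(s) {
    libs <- simulate_fragments(spec, seed = s)
    trk_c <- fragment_coverage(libs$control.rep1, gt, 100)
    trk_k <- fragment_coverage(libs$kd.rep1, gt, 100)
    doms <- data.frame(chrom = "c1", start = 200000L, end = 240000L)
    body <- function(mp) mean(mp$profile[(mp$flank_bins + 1):(mp$flank_bins + 100)])
    body(meta_domain_profile(trk_k, doms, cfg)) /
      body(meta_domain_profile(trk_c, doms, cfg))
  }, numeric(1))
  expect_true(all(abs(ratios - 0.65) <= 0.05))
})

test_that("qPCR fold enrichment applies the double normalization exactly", {
  tab <- function(l_mn, l_cr, r_mn = 25, r_cr = 25) {
    data.frame(locus = c("dhd", "dhd", "Sas10", "Sas10"),
               assay = c("mnase", "cutrun", "mnase", "cutrun"),
               ct = c(l_mn, l_cr, r_mn, r_cr))
  }
  expect_equal(qpcr_fold_enrichment(tab(20, 20, 20, 20), "dhd"), 1)
  expect_equal(qpcr_fold_enrichment(tab(22, 20), "dhd"), 4)
  expect_equal(qpcr_fold_enrichment(tab(22, 20), "Sas10"), 1)  # reference identity
  # shift invariance: adding a constant to every Ct changes nothing
  t1 <- tab(23.5, 19.25, 26, 24.5)
  t2 <- t1; t2$ct <- t2$ct + 3.7
  expect_equal(qpcr_fold_enrichment(t1, "dhd"), qpcr_fold_enrichment(t2, "dhd"))
  # duplicates are averaged on the Ct scale
  dup <- rbind(tab(22, 20), tab(24, 20))
  expect_equal(qpcr_fold_enrichment(dup, "dhd"), 2^(23 - 20))
  expect_error(qpcr_fold_enrichment(tab(22, 20), "missing"), "missing Ct")
})

test_that("the shipped synthetic qPCR table yields mark enrichment over the reference", {
  path <- system.file("extdata", "synthetic_qpcr.tsv", package = "minidomain")
  tab <- utils::read.delim(path)
  expect_equal(qpcr_fold_enrichment(tab, "Sas10"), 1)
  expect_gt(qpcr_fold_enrichment(tab, "dhd"), 4)      # marked mini-domain locus
  expect_gt(qpcr_fold_enrichment(tab, "Ubx"),
            qpcr_fold_enrichment(tab, "dhd"))         # strong positive control
})
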