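# small handmade track: 8 fragments of 100 bp on a toy scheme
toy_scheme <- function() {
  region_scheme(chrom = "chrT", norm_region = c(1, 800),
                viewpoint = c(101, 200), boundary = 601,
                bxc = c(1, 800), viewpoint_margin = 100)
}
toy_track <- function(counts) {
  frags <- data.frame(chrom = "chrT", start = seq(0, 700, 100),
                      end = seq(100, 800, 100))
  fragment_track(frags, counts)
}

test_that("normalization equalizes in-region totals and keeps ranks", {
  cts <- cbind(a.1 = c(10, 20, 30, 5, 5, 10, 10, 10),
               b.1 = 2 * c(10, 20, 30, 5, 5, 10, 10, 10) + 10)
  tr <- normalize_track(toy_track(cts), toy_scheme(), constant = 1e6)
  expect_equal(colSums(tr$counts), c(a.1 = 1e6, b.1 = 1e6))
  expect_equal(order(tr$counts[, 1]), order(cts[, 1]))

  # two samples with totals 100 and 200 get scale factors 1e4 and 5e3
  cts2 <- cbind(x.1 = c(100, rep(0, 7)), y.1 = c(200, rep(0, 7)))
  tr2 <- normalize_track(toy_track(cts2), toy_scheme())
  expect_equal(tr2$counts[1, ], c(x.1 = 1e6, y.1 = 1e6))

  bad <- cbind(a.1 = rep(0, 8))
  expect_error(normalize_track(toy_track(bad), toy_scheme()), "zero reads")
})

test_that("running mean smooths in fragment space with truncated ends", {
  tr <- toy_track(cbind(s.1 = c(1, 2, 3, 4, 5, 6, 7, 8)))
  sm <- smooth_running_mean(tr, 3)
  expect_equal(sm$counts[2, 1], 2, ignore_attr = TRUE)
  expect_equal(sm$counts[1, 1], 1.5, ignore_attr = TRUE)  # truncated end
  expect_equal(sm$counts[8, 1], 7.5, ignore_attr = TRUE)

  const <- smooth_running_mean(toy_track(cbind(s.1 = rep(4, 8))), 3)
  expect_equal(const$counts[, 1], rep(4, 8))

  set.seed(31)
  v <- rpois(8, 20)
  sm2 <- smooth_running_mean(toy_track(cbind(s.1 = v)), 3)
  oracle <- vapply(1:8, function(i)
    mean(v[max(1, i - 1):min(8, i + 1)]), numeric(1))
  expect_equal(sm2$counts[, 1], oracle, ignore_attr = TRUE)
  expect_error(smooth_running_mean(tr, 2), "odd")
})

test_that("viewpoint masking uses the any-overlap rule", {
  tr <- mask_viewpoint(toy_track(cbind(s.1 = rep(1, 8))), toy_scheme())
  # viewpoint 100-200 (0-based) with 100 bp margin: mask spans 0-300,
  # so fragments 1-3 are excluded, including the straddling third one
  expect_equal(tr$excluded, c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
})

test_that("contact-change ratios behave at equality, doubling and zeros", {
  base <- cbind(S2 = c(10, 20, 30, 40, 0, 10, 10, 10))
  t_eq <- toy_track(base)
  t_eq$samples$condition <- "S2"
  t2 <- toy_track(cbind(ML = 2 * base[, 1]))
  t2$samples$condition <- "ML"

  r0 <- ratio_minus_one(t_eq, t_eq)
  expect_true(all(r0$ratio[base[, 1] > 0] == 0))
  r2 <- ratio_minus_one(t2, t_eq)
  expect_true(all(r2$ratio[base[, 1] > 0] == 1))
  expect_true(is.na(r0$ratio[5]))              # zero control: undefined
  expect_true(all(is.finite(r0$ratio) | is.na(r0$ratio)))

  other <- toy_track(base)
  other$fragments$start <- other$fragments$start + 1
  expect_error(ratio_minus_one(t2, other), "fragment map")
})

test_that("near/far summary handles identical tracks and planted effects", {
  sc <- toy_scheme()
  cts <- cbind(S2.1 = rpois(8, 50) + 1, S2.2 = rpois(8, 50) + 1,
               ML.1 = rpois(8, 50) + 1, ML.2 = rpois(8, 50) + 1)
  tr <- toy_track(cts)
  tr$counts[, 3:4] <- tr$counts[, 1:2]          # test == control
  rt <- fourc_ratio_track(tr, "ML", "S2", sc)
  nf <- near_far_summary(rt, sc)
  expect_equal(nf$means$mean, c(0, 0))
  expect_equal(nf$p_value, 1)

  # planted 40% far depletion at generator defaults
  g <- gen_4c_tracks(fourc_gen_params(depletion_factor = 0.6,
                                      peak_depletion_factor = 1, seed = 9))
  r <- fourc_ratio_track(g$track, "PhML", "S2", g$scheme)
  s <- near_far_summary(r, g$scheme)
  far_mean <- s$means$mean[s$means$region == "far"]
  near_mean <- s$means$mean[s$means$region == "near"]
  expect_lt(abs(far_mean - (-0.4)), 0.1)
  expect_gt(near_mean, far_mean)
  expect_lt(s$p_value, 0.05)
})

test_that("window flagging applies the symmetric >50% change rule", {
  sc <- region_scheme(chrom = "chrT", norm_region = c(1, 800),
                      viewpoint = c(101, 200), boundary = 401,
                      bxc = c(1, 600), viewpoint_margin = 10)
  ctl <- toy_track(cbind(S2.1 = rep(100, 8)))
  ctl$samples$condition <- "S2"
  tst <- toy_track(cbind(ML.1 = c(40, 60, 160, 100, 100, 100, 100, 100)))
  tst$samples$condition <- "ML"
  wins <- flag_changed_windows(tst, ctl, sc, window_bp = 100)
  expect_equal(wins$flag[1:4], c("decreased", "unchanged", "increased",
                                 "unchanged"))
  expect_true(all(table(wins$flag) >= 0))       # flags partition windows
  expect_equal(nrow(wins), 6)                   # BX-C tiled in 100-bp bins
})

test_that("nearest-peak distances match the exhaustive oracle", {
  peaks <- data.frame(chrom = "chrT", start = c(1400, 2900),
                      end = c(1600, 3100))
  wins <- data.frame(chrom = "chrT", start = c(900, 1450), end = c(1100, 1550),
                     mid = c(1000, 1500), ratio = c(0.3, 1),
                     flag = c("decreased", "unchanged"))
  expect_warning(d <- distance_to_nearest_peak(wins, peaks), "too few")
  expect_equal(d$distances$distance, c(500, 0))

  set.seed(13)
  centres <- sort(runif(15, 0, 1e5))
  pk <- data.frame(chrom = "chrT", start = centres - 50, end = centres + 50)
  mids <- runif(200, 0, 1e5)
  wn <- data.frame(chrom = "chrT", start = mids - 100, end = mids + 100,
                   mid = mids,
                   ratio = runif(200, 0, 2),
                   flag = sample(c("decreased", "unchanged"), 200, TRUE))
  d2 <- distance_to_nearest_peak(wn, pk)
  expect_equal(d2$distances$distance,
               oracle_nearest(mids, (pk$start + pk$end) / 2))
  expect_error(distance_to_nearest_peak(
    data.frame(chrom = "chrZ", start = 1, end = 2, mid = 1.5,
               ratio = 1, flag = "unchanged"), peaks), "no peaks")
})

test_that("contact-to-fragment conversion matches the naive overlap count", {
  frags <- data.frame(chrom = "chr3R", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100))
  ct <- data.frame(chrom = "chr3R", start = c(150, 420), end = c(380, 480))
  expect_equal(contacts_to_fragment_counts(ct, frags), c(3, 1))

  set.seed(17)
  s <- sort(sample(0:5e4, 40))
  rnd <- data.frame(chrom = "chr3R", start = s, end = s + sample(50:5000, 40))
  fm <- gen_fragment_map(6e4, seed = 3, chrom = "chr3R")
  expect_equal(contacts_to_fragment_counts(rnd, fm),
               oracle_overlap_counts(rnd, fm))

  sizes <- summarize_contact_sizes(list(S2 = ct, ML = rnd), fm)
  expect_equal(sizes$normalized[1], 1)
})

test_that("contacts partition into neighbourhood and distal zones", {
  sc <- region_scheme()
  ct <- data.frame(chrom = c("chr3R", "chr3R", "chr3R", "chr2L"),
                   start = c(12480478 - 1e6, 12821577 + 3e6, 12600000, 500),
                   end = c(12480478 - 1e6 + 5e3, 12821577 + 3e6 + 5e3,
                           12605000, 1500))
  z <- partition_contacts(ct, sc)
  expect_equal(z$zone, c("neighbourhood", "distal", "inside", "other"))
})

test_that("peak overlap fractions hit the planted rate", {
  sc <- region_scheme()
  peaks <- data.frame(chrom = "chr3R",
                      start = seq(12500000, 12800000, by = 30000))
  peaks$end <- peaks$start + 500
  on_pk <- data.frame(chrom = "chr3R", start = peaks$start[1:4] - 100,
                      end = peaks$start[1:4] + 600)
  expect_equal(peak_overlap_fraction(on_pk, peaks), 1)
  off <- data.frame(chrom = "chrX", start = 1:3 * 1000, end = 1:3 * 1000 + 100)
  expect_equal(peak_overlap_fraction(off, peaks), 0)

  ct <- gen_contacts(50, peaks, frac_on_peaks = 0.6,
                     span = c(12.4e6, 12.9e6), seed = 19)
  expect_lt(abs(peak_overlap_fraction(ct, peaks) - 0.6), 0.1)
  expect_error(peak_overlap_fraction(ct[0, ], peaks), "empty")
})

test_that("decreased windows sit closer to peaks on planted tracks", {
  # peak-proximal contact losses: flagged windows should be significantly
  # nearer to peak centres than unchanged windows
  pvals <- vapply(1:4, function(s) {
    g <- gen_4c_tracks(fourc_gen_params(depletion_factor = 1,
                                        peak_depletion_factor = 0.3,
                                        seed = s))
    sc <- g$scheme
    tr <- mask_viewpoint(normalize_track(g$track, sc), sc)
    pick <- function(cond) {
      keep <- tr$samples$condition == cond
      t2 <- tr
      t2$counts <- tr$counts[, keep, drop = FALSE]
      t2$samples <- tr$samples[keep, ]
      t2
    }
    wins <- flag_changed_windows(pick("PhML"), pick("S2"), sc)
    d <- distance_to_nearest_peak(wins, g$peaks, changed = "decreased",
                                  alternative = "less")
    d$p_value
  }, numeric(1))
  expect_true(all(pvals < 0.05))
})
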