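test_that("adaptive bin size follows the density rule with clamping", {
  expect_equal(adaptive_bin_size(1000, 1000), 15)
  expect_equal(adaptive_bin_size(9000, 1000), 10)   # raw 5 nm, floor 10
  expect_equal(adaptive_bin_size(1000, 9000), 30)   # raw 45 nm, ceiling 30
  expect_equal(adaptive_bin_size(2000, 1000), 15 / sqrt(2))
  expect_error(adaptive_bin_size(0, 10), "positive")
  expect_error(adaptive_bin_size(10, -1), "positive")
})

test_that("rasterization conserves localizations and uses half-open bins", {
  tab <- localization_table(c(0, 7.4, 15, 29.9), c(0, 0, 0, 0))
  g <- rasterize(tab, 15, origin = c(0, 0))
  expect_equal(sum(g$counts), 4)
  # the point exactly on the 15-nm boundary lands in the higher-index bin
  expect_equal(g$counts[, 1], c(2L, 2L))

  set.seed(42)
  n <- 1e4
  tab2 <- localization_table(runif(n, 0, 150), runif(n, 0, 150))
  g2 <- rasterize(tab2, 15, origin = c(0, 0), dims = c(10, 10))
  expect_equal(sum(g2$counts), n)
  chi <- suppressWarnings(chisq.test(as.vector(g2$counts)))
  expect_gt(chi$p.value, 0.001)
})

test_that("cluster calling is 8-connected and matches flood fill", {
  # two diagonal bins form one cluster
  occ <- matrix(0, 4, 4)
  occ[1, 1] <- 3
  occ[2, 2] <- 2
  g <- structure(list(counts = occ, bin_size = 15, origin = c(0, 0)),
                 class = "bin_grid")
  cs <- call_clusters(g)
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$n_localizations, 5)

  # empty grid
  g0 <- structure(list(counts = matrix(0, 3, 3), bin_size = 15,
                       origin = c(0, 0)), class = "bin_grid")
  expect_equal(nrow(call_clusters(g0)$clusters), 0)

  # random occupancy grids against the BFS oracle
  for (seed in 1:10) {
    occ <- random_grid(50, 50, 0.25, seed)
    g <- structure(list(counts = occ * 1L, bin_size = 15,
                        origin = c(0, 0)), class = "bin_grid")
    cs <- call_clusters(g)
    lab <- oracle_flood_fill(occ)
    expect_equal(nrow(cs$clusters), max(lab))
    # identical partitions of the non-empty bins
    got_sizes <- sort(as.integer(table(cs$membership)))
    expect_equal(got_sizes, sort(as.integer(table(lab[lab > 0]))))
    # co-membership agreement on a sample of bin pairs
    idx <- which(occ)
    set.seed(seed)
    pick <- sample(seq_along(idx), min(60, length(idx)))
    oracle_lab <- lab[idx][pick]
    mine <- cs$membership[pick]
    expect_identical(outer(mine, mine, "=="),
                     outer(oracle_lab, oracle_lab, "=="))
  }
})

test_that("diameters, weighted distributions and threshold counts agree", {
  expect_equal(cluster_diameter(1, 15), 15)
  expect_equal(cluster_diameter(4, 15), 30)
  expect_error(cluster_diameter(0, 15), "n_bins")

  cl <- data.frame(cluster_id = 1:2, n_bins = c(45, 2),
                   n_localizations = c(10L, 1L),
                   diameter = c(100, 20))
  expect_equal(weighted_size_distribution(cl)$weighted_median, 100)

  same <- data.frame(cluster_id = 1:3, n_bins = 1:3,
                     n_localizations = c(5L, 2L, 9L),
                     diameter = c(40, 40, 40))
  expect_equal(weighted_size_distribution(same)$weighted_median, 40)

  # expansion oracle: weighted median equals the plain median of diameters
  # repeated per localization
  set.seed(9)
  rnd <- data.frame(cluster_id = 1:40, n_bins = 1,
                    n_localizations = sample(1:50, 40, TRUE),
                    diameter = sort(runif(40, 10, 500)))
  wm <- weighted_size_distribution(rnd)$weighted_median
  expanded <- rep(rnd$diameter, rnd$n_localizations)
  expect_equal(wm, quantile(expanded, 0.5, type = 1)[[1]])

  # invariance to splitting one cluster into equal-diameter duplicates
  w7 <- rnd$n_localizations[7]
  halves <- rnd[c(7, 7), ]
  halves$n_localizations <- c(w7 %/% 2, w7 - w7 %/% 2)
  split_one <- rbind(rnd[-7, ], halves)
  expect_equal(weighted_size_distribution(split_one)$weighted_median, wm)

  expect_equal(count_clusters_above(cl, 30), 1)
  singles <- data.frame(cluster_id = 1:5, n_bins = 1,
                        n_localizations = 1L, diameter = 15)
  expect_equal(count_clusters_above(singles), 0)
  expect_error(weighted_size_distribution(cl[0, ]), "empty")
})

test_that("colocalization is exact on identical and disjoint channels", {
  set.seed(11)
  a <- localization_table(runif(500, 0, 800), runif(500, 0, 800), "chA")
  co <- colocalization(a, a)
  expect_equal(co$frac_a, 1)
  expect_equal(co$frac_b, 1)

  b <- localization_table(a$x_nm + 5000, a$y_nm, "chB")
  co2 <- colocalization(a, b)
  expect_equal(co2$frac_a, 0)
  expect_equal(co2$frac_b, 0)

  # a channel with only single-bin clusters is flagged undefined
  sparse <- localization_table(seq(0, 900, by = 100), rep(0, 10), "chB")
  expect_warning(co3 <- colocalization(a, sparse), "multi-bin")
  expect_true(is.na(co3$frac_b))
})

test_that("planted two-channel overlap is recovered within 0.1", {
  two <- gen_two_channel(loc_gen_params(n_clusters = 80,
                                        diameter_range_nm = c(60, 300),
                                        seed = 5))
  co <- colocalization(two$table_a, two$table_b)
  expect_lt(abs(co$frac_a - two$planted_fraction_a), 0.1)
  expect_lt(abs(co$frac_b - two$planted_fraction_b), 0.1)
})

test_that("per-cell pipeline adapts bins and keeps localization totals", {
  g1 <- gen_localizations(loc_gen_params(n_clusters = 40,
                                         diameter_range_nm = c(50, 200),
                                         seed = 2), cell_id = "c1")
  g2 <- gen_localizations(loc_gen_params(n_clusters = 40,
                                         diameter_range_nm = c(50, 200),
                                         seed = 4), cell_id = "c2")
  tab <- rbind(g1$table, g2$table)
  class(tab) <- class(g1$table)
  res <- storm_cluster_cells(tab)
  expect_setequal(names(res$per_cell), c("c1", "c2"))
  expect_true(all(res$bin_sizes >= 10 & res$bin_sizes <= 30))
  got <- sum(res$clusters$n_localizations)
  expect_equal(got, nrow(tab))
})

test_that("half-sampled data give a very similar weighted size spectrum", {
  g <- gen_localizations(loc_gen_params(seed = 6))
  sub <- subsample_robustness(g$table, seed = 7)
  expect_lt(sub$ks_half_vs_full, 0.15)
  expect_lt(sub$ks_between_halves, 0.15)

  tiny <- localization_table(c(0, 100), c(0, 100))
  expect_silent(sub2 <- subsample_robustness(tiny, seed = 1))
  expect_equal(length(sub2$half1$diameter), 1)
})
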