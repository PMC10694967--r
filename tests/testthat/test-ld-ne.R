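# LD binning, the Sved-type inversion, time mapping, chromosome pooling.

test_that("dosage r2 is the squared Pearson correlation of dosages", {
  x <- c(0L, 0L, 1L, 1L, 2L, 2L)
  expect_equal(dosage_r2(x, x), 1)
  expect_equal(dosage_r2(x, rev(x)), 1)  # perfect anticorrelation, squared
  a <- c(0L, 1L, 2L, 1L)
  b <- c(0L, 2L, 1L, 1L)
  # hand-computed: cov = 1/3, var(a) = var(b) = 2/3 -> r = 0.5
  expect_equal(dosage_r2(a, b), 0.25)
  expect_true(is.na(dosage_r2(c(1L, 1L, 1L, 1L), b)))
  expect_error(dosage_r2(1:2, 1:3), "equal length")
})

test_that("the bin-to-time mapping is t = 1/(2c)", {
  expect_equal(bin_to_time(0.05), 10)
  expect_equal(bin_to_time(0.001), 500)
  expect_equal(bin_to_time(0.5), 1)
  expect_error(bin_to_time(0), "c_mid")
  expect_error(bin_to_time(0.6), "c_mid")
})

test_that("pair selection respects the genetic-distance window", {
  # two SNPs 10 Mb apart at 1 cM/Mb: d = 0.1 M > c_max -> no pairs
  gm_far <- make_gm(matrix(c(0L, 1L, 2L, 0L, 2L, 1L, 1L, 0L), 4, 2),
                    c(0L, 10000000L), map_rate = 1e-8)
  expect_error(bin_pairs_by_distance(gm_far), "no SNP pairs")
  # 1 Mb apart: d = 0.01 M, exactly one pair, in the bin containing 0.01
  gm_near <- make_gm(matrix(c(0L, 1L, 2L, 0L, 2L, 1L, 1L, 0L), 4, 2),
                     c(0L, 1000000L), map_rate = 1e-8)
  bins <- bin_pairs_by_distance(gm_near)
  expect_identical(sum(bins$pair_count), 1L)
  hit <- bins[bins$pair_count == 1, ]
  expect_true(hit$c_lo <= 0.01 && hit$c_hi >= 0.01)
})

test_that("binned mean r2 equals the brute-force all-pairs computation exactly", {
  cfg <- estimator_config(max_pairs_per_bin = .Machine$integer.max)
  for (seed in c(31, 32)) {
    gm <- random_gm(15, 50, map_rate = 1e-8, L = 20e6, seed = seed)
    got <- bin_pairs_by_distance(gm, cfg)
    want <- brute_force_bins(gm, cfg)
    expect_identical(got$pair_count, want$pair_count)
    expect_equal(got$mean_r2, want$mean_r2, tolerance = 1e-12)
  }
  # multi-chromosome pooling agrees with the oracle too
  gm2 <- random_gm(12, 40, map_rate = 1e-8, L = 12e6, seed = 33)
  gm2 <- ldnesim:::new_genotype_matrix(gm2$dosages, gm2$positions_bp,
                                       rep(1:2, each = 20), 1e-8,
                                       gm2$sample_ids, gm2$deme_ids)
  got <- bin_pairs_by_distance(gm2, cfg)
  want <- brute_force_bins(gm2, cfg)
  expect_identical(got$pair_count, want$pair_count)
  expect_equal(got$mean_r2, want$mean_r2, tolerance = 1e-12)
})

test_that("total retained pairs equals the exhaustive pair count with the cap disabled", {
  cfg <- estimator_config(max_pairs_per_bin = .Machine$integer.max)
  gm <- random_gm(10, 60, map_rate = 1e-8, L = 30e6, seed = 34)
  bins <- bin_pairs_by_distance(gm, cfg)
  g <- gm$genetic_morgan
  d <- as.numeric(stats::dist(g))
  expect_identical(sum(bins$pair_count) + sum(bins$skipped),
                   sum(d >= cfg$c_min - 1e-12 & d <= cfg$c_max + 1e-12))
})

test_that("the pair cap subsamples deterministically under the config seed", {
  gm <- random_gm(10, 80, map_rate = 1e-8, L = 10e6, seed = 35)
  cfg <- estimator_config(max_pairs_per_bin = 5L, seed = 99L)
  b1 <- bin_pairs_by_distance(gm, cfg)
  b2 <- bin_pairs_by_distance(gm, cfg)
  expect_identical(b1, b2)
  expect_true(all(b1$pair_count <= 5L))
})

test_that("estimate_ne_curve inverts the defining formula exactly", {
  cfg <- estimator_config()
  bins <- data.frame(bin = 1L, c_lo = 0.009, c_hi = 0.011, c_mid = 0.01,
                     pair_count = 1000L,
                     mean_r2 = 1 / (2 + 4 * 1000 * 0.01) + 1 / 100,
                     skipped = 0L)
  traj <- estimate_ne_curve(bins, n_individuals = 100, cfg = cfg)
  expect_equal(traj$Ne_hat, 1000)
  expect_equal(traj$t, 50)
  # degenerate bin: r2_adj = 0 -> dropped
  bins$mean_r2 <- 1 / 100
  expect_error(estimate_ne_curve(bins, 100, cfg), "all bins dropped")
  # mixed usable/degenerate: degenerate flagged in the dropped attribute
  bins2 <- rbind(bins, within(bins, {
    c_mid <- 0.02; mean_r2 <- 1 / (2 + 4 * 500 * 0.02) + 1 / 100
  }))
  traj2 <- estimate_ne_curve(bins2, 100, cfg)
  expect_identical(nrow(traj2), 1L)
  expect_equal(traj2$Ne_hat, 500)
  expect_identical(nrow(attr(traj2, "dropped")), 1L)
})

test_that("chromosome pooling is the pair-count-weighted mean", {
  cfg <- estimator_config(n_bins = 3L)
  mk <- function(r2, n) {
    b <- data.frame(bin = 1:3,
                    c_lo = c(0.001, 0.004, 0.015),
                    c_hi = c(0.004, 0.015, 0.05),
                    c_mid = c(0.002, 0.008, 0.027),
                    pair_count = n, sum_r2 = r2 * n, skipped = 0L)
    ldnesim:::finish_bins(b, cfg)
  }
  one <- mk(c(0.3, 0.2, 0.1), c(10L, 10L, 10L))
  expect_identical(pool_chromosomes(list(one)), one)
  # equal counts -> simple average
  two <- pool_chromosomes(list(mk(c(0.3, 0.2, 0.1), rep(10L, 3)),
                               mk(c(0.1, 0.4, 0.3), rep(10L, 3))))
  expect_equal(two$mean_r2, c(0.2, 0.3, 0.2))
  # unequal counts 100/300 with r2 0.1/0.2 -> 0.175
  thr <- pool_chromosomes(list(mk(rep(0.1, 3), rep(100L, 3)),
                               mk(rep(0.2, 3), rep(300L, 3))))
  expect_equal(thr$mean_r2, rep(0.175, 3))
  # mismatched grids refuse to pool
  other <- mk(c(0.3, 0.2, 0.1), rep(10L, 3))
  other$c_mid <- other$c_mid * 2
  expect_error(pool_chromosomes(list(one, other)), "mismatched")
})

test_that("equilibrium r2 tracks 1/(alpha + 4Nc) + 1/n in shape over the window", {
  gm <- panmictic_gm()      # N = 200 desk panmictic
  n <- n_individuals(gm)
  bins <- bin_pairs_by_distance(gm)
  sel <- bins$pair_count > 100 & bins$c_mid >= 0.005
  expect_gt(sum(sel), 5)
  closed <- 1 / (2 + 4 * 200 * bins$c_mid[sel]) + 1 / n
  rel <- bins$mean_r2[sel] / closed - 1
  expect_lt(mean(abs(rel)), 0.30)
  # monotone: r2 non-increasing in c (strong negative rank correlation)
  expect_lt(stats::cor(bins$c_mid[bins$pair_count > 0],
                       bins$mean_r2[bins$pair_count > 0],
                       method = "spearman"), -0.9)
})

test_that("split-halves estimation averages two close estimates", {
  gm <- panmictic_gm()
  t_all <- estimate_ne(gm)
  t_split <- estimate_ne(gm, split_halves = TRUE)
  m_all <- median_ne(t_all, 10, 100)
  m_split <- median_ne(t_split, 10, 100)
  expect_lt(abs(log(m_all / m_split)), log(1.5))
})

test_that("trajectory tables are written bit-stably", {
  gm <- random_gm(20, 60, map_rate = 1e-7, L = 10e6, seed = 36)
  traj <- estimate_ne(gm)
  f1 <- file.path(tempdir(), "t1.tsv")
  f2 <- file.path(tempdir(), "t2.tsv")
  write_trajectory(traj, f1)
  write_trajectory(estimate_ne(gm), f2)
  expect_identical(readLines(f1), readLines(f2))
})
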