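test_that("site and individual heterozygosity count genotypes correctly", {
  s <- toy_sites(1L, rbind(c(1, 1, 0, 2)))   # 0/1, 0/1, 0/0, 1/1
  expect_equal(site_pop_heterozygosity(s, site_samples(s)), 0.5)
  expect_equal(site_pop_heterozygosity(toy_sites(1L, rbind(c(0, 0, 2))),
                                       c("S001", "S002", "S003")), 0)

  set.seed(4)
  d <- matrix(sample(c(0, 1, 2, NA), 80, replace = TRUE), 10, 8)
  s2 <- toy_sites(1:10, d)
  expected <- apply(d, 1, function(r) sum(r == 1, na.rm = TRUE) /
                      sum(!is.na(r)))
  expect_equal(site_pop_heterozygosity(s2, site_samples(s2)), expected)

  ih <- individual_heterozygosity(s2)
  expect_equal(ih$het,
               apply(d, 2, function(cl) sum(cl == 1, na.rm = TRUE) /
                       sum(!is.na(cl))))
  all_na <- individual_heterozygosity(toy_sites(1:3, matrix(NA_real_, 3, 2)))
  expect_true(all(is.nan(all_na$het)))
})

test_that("mean individual heterozygosity matches the HWE expectation", {
  set.seed(10)
  p <- 0.3
  n_sites <- 4000
  dos <- matrix(stats::rbinom(n_sites * 12, 2, p), n_sites, 12)
  s <- toy_sites(seq_len(n_sites), dos)
  ih <- individual_heterozygosity(s)
  expect_equal(mean(ih$het), 2 * p * (1 - p), tolerance = 0.02)
})

test_that("windowed heterozygosity tiles, averages and depth-filters", {
  # single site, het 0.25 --> window value 0.25
  s1 <- toy_sites(10L, rbind(c(1, 0, 0, 0)))
  w1 <- window_heterozygosity(s1, site_samples(s1), size = 40000,
                              step = 20000)
  expect_equal(w1$value, 0.25)

  # low-coverage window dropped
  s2 <- toy_sites(10L, rbind(c(1, 0, 0, 0)), dp = 0L)
  s2$dp[1, 1] <- 3L   # mean depth 0.75 < 1
  w2 <- window_heterozygosity(s2, site_samples(s2))
  expect_equal(nrow(w2), 0)

  # sliding boundaries and brute-force means on a 100-kb toy chromosome
  set.seed(6)
  pos <- sort(sample.int(100000L, 120))
  dos <- matrix(sample(c(0, 1, 2), 120 * 6, replace = TRUE), 120, 6)
  s3 <- toy_sites(pos, dos)
  w3 <- window_heterozygosity(s3, site_samples(s3), chrom_length = 1e5)
  starts <- seq(1L, 100000L, by = 20000L)
  expect_equal(w3$start, starts[starts %in% w3$start])
  expect_equal(w3$end, w3$start + 39999L)
  for (i in seq_len(nrow(w3))) {
    in_w <- pos >= w3$start[i] & pos <= w3$end[i]
    manual <- mean(apply(dos[in_w, , drop = FALSE], 1,
                         function(r) mean(r == 1)))
    expect_equal(w3$value[i], manual)
  }
})

test_that("windowed pi equals the allele-level pairwise-difference oracle", {
  # single site, 4 called alleles, alt count 2 --> per-site term 2/3
  s <- toy_sites(5L, rbind(c(1, 1)))
  p <- nucleotide_diversity_pi(s, c("S001", "S002"), size = 10,
                               step = 10, chrom_length = 10)
  expect_equal(p$value[1], (2 / 3) / 10)

  mono <- toy_sites(5L, rbind(c(0, 0, 0)))
  expect_equal(nucleotide_diversity_pi(mono, site_samples(mono), size = 10,
                                       step = 10)$value, 0)

  set.seed(8)
  n_sites <- 200
  dos <- matrix(sample(c(0, 1, 1, 2, NA), n_sites * 20, replace = TRUE),
                n_sites, 20)
  s2 <- toy_sites(sort(sample.int(50000L, n_sites)), dos)
  pop <- site_samples(s2)
  pw <- nucleotide_diversity_pi(s2, pop, size = 50000, step = 50000,
                                chrom_length = 5e4)
  expect_equal(pw$value[1], brute_force_pi(s2, pop, 1, 50000, 50000),
               tolerance = 1e-12)
})

test_that("subsampled pi is seeded, degenerate at k = n, and tightens with k", {
  cfg <- sim_config(n_samples = 16, n_sites = 1500, chrom_length = 3e5,
                    missing_rate = 0, seed = 13)
  sites <- simulate_neutral_population(cfg)
  pop <- site_samples(sites)
  a <- subsampled_pi(sites, pop, k = 8, reps = 3, seed = 5)
  b <- subsampled_pi(sites, pop, k = 8, reps = 3, seed = 5)
  expect_identical(a, b)
  expect_error(subsampled_pi(sites, pop[1:4], k = 8), "fewer than")

  full <- nucleotide_diversity_pi(sites, pop)
  degenerate <- subsampled_pi(sites, pop, k = length(pop), reps = 2,
                              seed = 1)
  expect_equal(degenerate$value[degenerate$rep == 1], full$value)
  expect_equal(degenerate$value[degenerate$rep == 2], full$value)

  var_by_k <- vapply(c(4, 8, 16), function(k) {
    sp <- subsampled_pi(sites, pop, k = k, reps = 12, seed = 2)
    mean(tapply(sp$value, paste(sp$chrom, sp$start), stats::var))
  }, numeric(1))
  expect_true(var_by_k[1] > var_by_k[2])
  expect_true(var_by_k[2] > var_by_k[3])
})

test_that("Tajima's D matches a direct textbook evaluation on a toy window", {
  # n = 10 alleles (5 diploids), S = 5 segregating sites, no missing data
  dos <- rbind(c(1, 0, 0, 0, 0),
               c(1, 1, 1, 0, 0),
               c(2, 2, 2, 2, 1),
               c(1, 1, 0, 0, 0),
               c(2, 1, 1, 0, 0))
  s <- toy_sites(c(10L, 20L, 30L, 40L, 50L), dos)
  got <- tajimas_d(s, site_samples(s), size = 100, step = 100,
                   chrom_length = 100)
  # independent evaluation from S and the mean pairwise differences
  n <- 10
  S <- 5
  na <- rowSums(dos)
  pi_sum <- sum(2 * na * (n - na) / (n * (n - 1)))
  a1 <- sum(1 / 1:9)
  a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(got$value[1], D, tolerance = 1e-12)
  expect_equal(got$n_sites[1], 5L)

  none <- tajimas_d(toy_sites(10L, rbind(c(0, 0, 0, 0, 0))),
                    sprintf("S%03d", 1:5), size = 100, step = 100)
  expect_true(is.na(none$value[1]))
})

test_that("Weir-Cockerham Fst hits its limits and matches the 1984 oracle", {
  # identical frequencies, many samples --> Fst ~ 0
  set.seed(14)
  dos <- matrix(stats::rbinom(200 * 40, 2, 0.4), 200, 40)
  s <- toy_sites(sort(sample.int(50000L, 200)), dos)
  pops <- split(site_samples(s), rep(1:2, each = 20))
  f0 <- weir_cockerham_fst(s, pops[[1]], pops[[2]], size = 5e4, step = 5e4,
                           chrom_length = 5e4)
  expect_lt(abs(f0$value[1]), 0.05)

  # fixed difference --> Fst ~ 1
  fixed <- toy_sites(1:20, cbind(matrix(0, 20, 10), matrix(2, 20, 10)))
  pf <- site_samples(fixed)
  f1 <- weir_cockerham_fst(fixed, pf[1:10], pf[11:20], size = 100,
                           step = 100, chrom_length = 100)
  expect_gt(f1$value[1], 0.95)

  # toy counts with missingness vs the independent implementation
  set.seed(15)
  dos2 <- matrix(sample(c(0, 0, 1, 2, NA), 50 * 24, replace = TRUE), 50, 24)
  s2 <- toy_sites(sort(sample.int(9000L, 50)), dos2)
  all_s <- site_samples(s2)
  pa <- all_s[1:12]
  pb <- all_s[13:24]
  got <- weir_cockerham_fst(s2, pa, pb, size = 1e4, step = 1e4,
                            chrom_length = 1e4)
  stats_of <- function(cols) {
    d <- dos2[, cols, drop = FALSE]
    list(n = rowSums(!is.na(d)),
         p = rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d))),
         h = rowSums(d == 1, na.rm = TRUE) / rowSums(!is.na(d)))
  }
  A <- stats_of(1:12)
  B <- stats_of(13:24)
  ok <- A$n >= 1 & B$n >= 1
  oracle <- wc_fst_oracle(list(A$p[ok], B$p[ok]), list(A$n[ok], B$n[ok]),
                          list(A$h[ok], B$h[ok]))
  expect_equal(got$value[1], oracle, tolerance = 1e-12)
})

test_that("LD decay reports r2 in [0,1], a noise floor, and decay recovery", {
  # duplicated signal --> r2 = 1 in the first bin
  set.seed(16)
  col <- sample(c(0, 1, 2), 30, replace = TRUE)
  dup <- toy_sites(c(100L, 150L), rbind(col, col))
  ld1 <- ld_decay(dup, max_dist = 1000, bin = 1000, maf_min = 0)
  expect_equal(ld1$mean_r2[1], 1)

  # independent sites: mean r2 near the 1/n floor and flat in distance
  cfg <- sim_config(n_samples = 25, n_sites = 800, chrom_length = 2e5,
                    missing_rate = 0, seed = 17)
  sites <- simulate_neutral_population(cfg)
  ld <- ld_decay(sites, max_dist = 5e4, bin = 1e4)
  expect_true(all(ld$mean_r2 >= 0 & ld$mean_r2 <= 1, na.rm = TRUE))
  expect_lt(abs(mean(ld$mean_r2) - 1 / 25), 0.01)
  expect_lt(diff(range(ld$mean_r2)), 0.02)

  # founder-mosaic haplotypes: half-decay within a factor 2 of the scale
  halves <- vapply(1:8, function(s) {
    cfgL <- sim_config(n_samples = 30, n_sites = 1200, chrom_length = 3e5,
                       ld_scale = 20000, missing_rate = 0, seed = 300 + s)
    ldL <- ld_decay(simulate_neutral_population(cfgL), max_dist = 1e5,
                    bin = 2000)
    half_decay_distance(ldL)
  }, numeric(1))
  expect_true(all(halves >= 10000 & halves <= 40000))
})

test_that("neutral calibration: D near zero, within-population Fst tiny", {
  cfg <- sim_config(n_samples = 20, n_sites = 4000, chrom_length = 8e5,
                    seed = 19)
  sites <- simulate_neutral_population(cfg)
  pop <- site_samples(sites)
  D <- tajimas_d(sites, pop, size = 50000, step = 50000)
  expect_gt(mean(D$value, na.rm = TRUE), -0.5)
  expect_lt(mean(D$value, na.rm = TRUE), 0.5)
  fst <- weir_cockerham_fst(sites, pop[1:10], pop[11:20],
                            size = 8e5, step = 8e5, chrom_length = 8e5)
  expect_lt(abs(fst$value[1]), 0.05)
})
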