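test_that("polarization assigns derived states and folds third alleles", {
  dos <- rbind(c(1, 1, 1, rep(0, 7)),   # alt count 3 of n = 20
               c(1, 1, 1, rep(0, 7)),
               c(rep(0, 10)),           # monomorphic: excluded
               c(rep(2, 10)))           # substitution when outgroup = ref
  s <- toy_sites(c(10L, 20L, 30L, 40L), dos)
  og <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                       allele = c("A", "C", "A", "A"))  # pos 20: 3rd state
  pol <- polarize(s, og)
  expect_equal(pol$pos, c(10L, 20L, 40L))
  expect_equal(pol$derived_count[pol$pos == 10], 3L)
  expect_false(pol$folded[pol$pos == 10])
  expect_true(pol$folded[pol$pos == 20])
  expect_equal(pol$derived_count[pol$pos == 20], 3L)  # min(3, 17)
  expect_true(pol$is_substitution[pol$pos == 40])
  expect_equal(pol$derived_count[pol$pos == 40], 20L)
})

test_that("background spectrum tallies classes and reduces to 1/k", {
  pol <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L),
                        derived_count = c(1L, 1L, 2L), n = 4L,
                        folded = FALSE, is_substitution = FALSE)
  sfs <- background_sfs(pol)
  expect_equal(unname(sfs$counts), c(2, 1, 0, 0))
  expect_equal(sfs$spectrum, c(2, 1, 0, 0) / 3)

  # all-folded input occupies only minor-allele classes in the tally
  polf <- dplyr::mutate(pol, folded = TRUE)
  sfsf <- background_sfs(polf)
  expect_true(all(which(sfsf$counts > 0) <= 2))

  # neutral simulation recovers the 1/k law
  cfg <- sim_config(n_samples = 10, n_sites = 8000, chrom_length = 5e5,
                    missing_rate = 0, seed = 23)
  sites <- simulate_neutral_population(cfg)
  pol2 <- polarize(sites, attr(sites, "outgroup"))
  sfs2 <- background_sfs(pol2)
  expected <- (1 / 1:19) / sum(1 / 1:19)
  expect_gt(stats::chisq.test(sfs2$counts[1:19],
                              p = expected)$p.value, 0.001)

  # with missing data the EM spectrum stays close to the plain law
  cfg3 <- sim_config(n_samples = 10, n_sites = 8000, chrom_length = 5e5,
                     missing_rate = 0.05, seed = 24)
  sites3 <- simulate_neutral_population(cfg3)
  sfs3 <- background_sfs(polarize(sites3, attr(sites3, "outgroup")))
  expect_equal(sfs3$n, 20L)
  expect_lt(max(abs(sfs3$spectrum[1:19] - expected)), 0.05)
})

test_that("CLR is nonnegative, translation invariant, and null-calibrated", {
  cfg <- sim_config(n_samples = 15, n_sites = 2500, chrom_length = 5e5,
                    seed = 25)
  sites <- simulate_neutral_population(cfg)
  pol <- polarize(sites, attr(sites, "outgroup"))
  bg <- background_sfs(pol)
  scan <- clr_scan(pol, bg, grid_spacing = 500)
  expect_true(all(scan$clr >= 0))
  expect_true(all(is.na(scan$alpha_hat) | scan$alpha_hat > 0))

  shifted <- dplyr::mutate(pol, pos = pos + 77777L)
  scan2 <- clr_scan(shifted, bg, grid_spacing = 500)
  expect_equal(scan2$clr, scan$clr, tolerance = 1e-9)

  thr <- clr_threshold(scan)
  expect_equal(mean(scan$clr > thr), 0.01, tolerance = 0.002)
  expect_equal(clr_threshold(scan, top_fraction = 1.0), min(scan$clr))
})

test_that("the scan localizes an implanted sweep", {
  cfg <- sim_config(n_samples = 15, n_sites = 2500, chrom_length = 5e5,
                    seed = 26)
  sites <- simulate_neutral_population(cfg)
  sw <- implant_sweep(sites, center = 2.5e5, alpha = 6.9e-5, seed = 27)
  pol <- polarize(sw, attr(sw, "outgroup"))
  scan <- clr_scan(pol, background_sfs(pol), grid_spacing = 200)
  peak <- scan$pos[which.max(scan$clr)]
  expect_lt(abs(peak - 2.5e5), 5000)
  # recovered sweep strength within an order of magnitude
  a_hat <- scan$alpha_hat[which.max(scan$clr)]
  expect_true(a_hat > 6.9e-6 && a_hat < 6.9e-4)
})

test_that("threshold quantile matches a brute-force percentile", {
  g <- tibble::tibble(chrom = "chr1", pos = seq_len(1000) * 100,
                      clr = as.numeric(1:1000), alpha_hat = NA_real_)
  expect_equal(clr_threshold(g), 1 + 0.99 * 999)   # type-7 interpolation
  tied <- dplyr::mutate(g, clr = 5)
  expect_equal(clr_threshold(tied), 5)
})

test_that("region building finds maximal above-threshold runs", {
  g <- tibble::tibble(chrom = "chr1", pos = c(100, 200, 300, 400),
                      clr = c(1, 10, 12, 2), alpha_hat = NA_real_)
  r <- build_regions(g, threshold = 5)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end, r$score, r$n_points), c(200, 300, 22, 2))

  expect_equal(nrow(build_regions(g, threshold = 100)), 0)
  all_hot <- build_regions(g, threshold = 0)
  expect_equal(nrow(all_hot), 1)
  expect_equal(all_hot$n_points, 4L)
})

test_that("gap merging follows the 50%-of-size rule and cascades", {
  two <- tibble::tibble(chrom = "chr1", start = c(1000, 2900),
                        end = c(1999, 5899), score = c(3, 7),
                        n_points = c(2L, 4L))
  # sizes 1000 and 3000, gap 900 <= 0.5 * mean(1000, 3000) = 1000
  m <- merge_regions(two)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end, m$score), c(1000, 5899, 10))

  apart <- two
  apart$start[2] <- 3100   # gap 1100 > 1000
  expect_equal(nrow(merge_regions(apart)), 2)

  # A-B merge enables B-C merge at the fixpoint
  chain <- tibble::tibble(chrom = "chr1",
                          start = c(1, 200, 1500),
                          end = c(100, 1000, 2500),
                          score = c(1, 1, 1), n_points = c(1L, 1L, 1L))
  fix <- merge_regions(chain)
  expect_equal(nrow(fix), 1)
  expect_equal(fix, brute_force_merge(chain, 0.5, "mean"),
               ignore_attr = TRUE)
})

test_that("merging agrees with the exhaustive oracle on random instances", {
  set.seed(31)
  for (i in 1:60) {
    reg <- random_region_set()
    for (rule in c("mean", "min", "max", "sum")) {
      got <- merge_regions(reg, gap_rule = 0.5, size_rule = rule)
      want <- brute_force_merge(reg, 0.5, rule)
      expect_equal(got, want, ignore_attr = TRUE,
                   info = paste("rule", rule, "instance", i))
    }
  }
})

test_that("size filtering is inclusive at 300 bp and conserves scores", {
  reg <- tibble::tibble(chrom = "chr1",
                        start = c(1000, 5000, 9000),
                        end = c(1298, 5299, 9500),   # 299, 300, 501 bp
                        score = c(5, 6, 7), n_points = c(1L, 2L, 3L))
  fin <- finalize_regions(reg)
  expect_equal(fin$start, c(5000, 9000))
  expect_equal(sum(fin$score), 13)
})

test_that("gene overlap requires at least one shared base pair", {
  genes <- tibble::tibble(chrom = "chr1", start = c(1000L, 1000L),
                          end = c(2000L, 2000L), strand = "+",
                          gene_id = c("g1", "g2"))
  genes$start[2] <- 6000L
  genes$end[2] <- 7000L
  reg <- tibble::tibble(chrom = "chr1", start = 1999, end = 5000,
                        score = 1, n_points = 1L)
  hit <- genes_in_regions(reg, genes)
  expect_equal(hit$genes[[1]], "g1")
  reg2 <- tibble::tibble(chrom = "chr1", start = 2001, end = 5000,
                         score = 1, n_points = 1L)
  expect_length(genes_in_regions(reg2, genes)$genes[[1]], 0)

  # tiled synthetic genes vs a brute-force interval intersection
  tiles <- simulate_genes(chrom_length = 1e5)
  set.seed(33)
  regs <- tibble::tibble(chrom = "chr1",
                         start = sort(sample.int(90000L, 5)),
                         end = 0, score = 1, n_points = 1L)
  regs$end <- regs$start + sample.int(5000L, 5)
  withg <- genes_in_regions(regs, tiles)
  for (i in 1:5) {
    brute <- tiles$gene_id[tiles$start <= regs$end[i] &
                             tiles$end >= regs$start[i]]
    expect_equal(withg$genes[[i]], brute)
  }
})

test_that("score conservation holds through build/merge/finalize", {
  cfg <- sim_config(n_samples = 15, n_sites = 2500, chrom_length = 5e5,
                    seed = 35)
  sites <- simulate_neutral_population(cfg)
  sw <- implant_sweep(sites, center = 2.5e5, alpha = 6.9e-5, seed = 36)
  pol <- polarize(sw, attr(sw, "outgroup"))
  scan <- clr_scan(pol, background_sfs(pol), grid_spacing = 200)
  thr <- clr_threshold(scan)
  built <- build_regions(scan, thr)
  merged <- merge_regions(built)
  final <- finalize_regions(merged)
  above <- sum(scan$clr[scan$clr >= thr])
  expect_equal(sum(built$score), above, tolerance = 1e-9)
  expect_equal(sum(merged$score), above, tolerance = 1e-9)
  expect_lte(sum(final$score), above + 1e-9)
})
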