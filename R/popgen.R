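#' Per-site population heterozygosity
#'
#' The fraction of heterozygous individuals among the individuals of the
#' population with a called genotype at the site.
#'
#' @param sites A biallelic site table.
#' @param pop Character vector of sample names, or a population table
#'   (see [read_pop_table()]) together with `population`.
#' @param population Population label when `pop` is a table.
#' @return Numeric vector, one value per site; `NaN` where no genotype is
#'   called (such sites are excluded from window means).
#' @export
site_pop_heterozygosity <- function(sites, pop, population = NULL) {
  pop <- resolve_pop(sites, pop, population)
  het <- gt_is_het(sites)[, pop, drop = FALSE]
  rowSums(het, na.rm = TRUE) / rowSums(!is.na(het))
}

# sliding-window skeleton: start positions by (size, step) spanning the
# positions present on each chromosome
window_frame <- function(sites, size, step, chrom_length = NULL) {
  if (size < step) warning("window size smaller than step leaves gaps")
  purrr::map_dfr(unique(sites$chrom), function(ch) {
    pos <- sites$pos[sites$chrom == ch]
    span <- if (is.null(chrom_length)) max(pos) else chrom_length
    starts <- seq(1L, as.integer(span), by = as.integer(step))
    tibble::tibble(chrom = ch, start = starts,
                   end = as.integer(starts + size - 1L))
  })
}

#' Sliding-window population heterozygosity
#'
#' Mean of the defined per-site heterozygosities in each window (default
#' 40-kb windows, 20-kb step). Windows whose average per-sample per-site
#' depth is below `min_depth` are filtered out, as are windows containing
#' no usable site.
#'
#' @inheritParams site_pop_heterozygosity
#' @param size,step Window size and step in bp (defaults 40000 / 20000).
#' @param min_depth Minimum mean depth for a window to be reported
#'   (default 1).
#' @param chrom_length Optional chromosome length; defaults to the last
#'   site position.
#' @return Tibble of window statistics: `chrom`, `start`, `end`, `value`,
#'   `n_sites`, `mean_depth`.
#' @export
window_heterozygosity <- function(sites, pop, population = NULL,
                                  size = 40000, step = 20000,
                                  min_depth = 1, chrom_length = NULL) {
  assert_sorted(sites)
  pop <- resolve_pop(sites, pop, population)
  het <- site_pop_heterozygosity(sites, pop)
  dp <- sites$dp[, pop, drop = FALSE]
  dp[is.na(dp)] <- 0L
  site_mean_dp <- rowMeans(dp)
  win <- window_frame(sites, size, step, chrom_length)
  out <- purrr::pmap_dfr(win, function(chrom, start, end) {
    in_w <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
    h <- het[in_w]
    defined <- !is.nan(h)
    tibble::tibble(chrom = chrom, start = start, end = end,
                   value = if (any(defined)) mean(h[defined]) else NaN,
                   n_sites = sum(defined),
                   mean_depth = if (any(in_w)) mean(site_mean_dp[in_w])
                                else 0)
  })
  out[out$n_sites > 0 & out$mean_depth >= min_depth, , drop = FALSE]
}

#' Individual heterozygosity
#'
#' Fraction of called loci at which each sample is heterozygous.
#'
#' @param sites A site table.
#' @param samples Samples to report (default all).
#' @return Tibble with `sample`, `n_called`, `het` (`NaN` when a sample
#'   has no called locus).
#' @export
individual_heterozygosity <- function(sites, samples = site_samples(sites)) {
  het <- gt_is_het(sites)[, samples, drop = FALSE]
  tibble::tibble(
    sample = samples,
    n_called = unname(colSums(!is.na(het))),
    het = unname(colSums(het, na.rm = TRUE) / colSums(!is.na(het)))
  )
}

# per-site unbiased pairwise-difference heterozygosity:
# 2 * n_alt * (n_tot - n_alt) / (n_tot * (n_tot - 1)); NaN when n_tot < 2
site_pi_terms <- function(sites, pop) {
  dos <- gt_dosage(sites)[, pop, drop = FALSE]
  n_tot <- 2 * rowSums(!is.na(dos))
  n_alt <- rowSums(dos, na.rm = TRUE)
  ifelse(n_tot >= 2, 2 * n_alt * (n_tot - n_alt) / (n_tot * (n_tot - 1)), NaN)
}

#' Windowed nucleotide diversity
#'
#' Per window (default 50 kb / 10 kb step), pi is the sum over sites of
#' the unbiased per-site pairwise difference
#' `2 * n_alt * (n_tot - n_alt) / (n_tot * (n_tot - 1))` divided by the
#' window length in bp.
#'
#' @inheritParams window_heterozygosity
#' @param size,step Window size and step in bp (defaults 50000 / 10000).
#' @return Tibble of window statistics (`value` = pi per bp).
#' @export
nucleotide_diversity_pi <- function(sites, pop, population = NULL,
                                    size = 50000, step = 10000,
                                    chrom_length = NULL) {
  assert_sorted(sites)
  pop <- resolve_pop(sites, pop, population)
  terms <- site_pi_terms(sites, pop)
  win <- window_frame(sites, size, step, chrom_length)
  purrr::pmap_dfr(win, function(chrom, start, end) {
    in_w <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
    t_w <- terms[in_w]
    t_w <- t_w[!is.nan(t_w)]
    tibble::tibble(chrom = chrom, start = start, end = end,
                   value = sum(t_w) / size, n_sites = length(t_w))
  })
}

#' Subsampled nucleotide diversity
#'
#' To remove the effect of unequal population sizes, draws `k` samples
#' without replacement from the population, recomputes windowed pi, and
#' repeats `reps` times (defaults: 8 samples, 20 repeats). The seed makes
#' the draws reproducible.
#'
#' @inheritParams nucleotide_diversity_pi
#' @param k Samples per draw (default 8).
#' @param reps Repeat draws (default 20).
#' @param seed Optional seed for the draws.
#' @return Tibble with a `rep` column ahead of the window-statistic
#'   columns, `reps * n_windows` rows per population.
#' @export
subsampled_pi <- function(sites, pop, population = NULL, k = 8, reps = 20,
                          size = 50000, step = 10000, seed = NULL,
                          chrom_length = NULL) {
  pop <- resolve_pop(sites, pop, population)
  if (length(pop) < k) {
    stop("population has fewer than k = ", k, " samples", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(reps), function(r) {
    sub <- sample(pop, k)
    out <- nucleotide_diversity_pi(sites, sub, size = size, step = step,
                                   chrom_length = chrom_length)
    dplyr::bind_cols(tibble::tibble(rep = r), out)
  })
}

# Tajima's D normalization from sample size n (haploid) and S
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(round(n) - 1))
  a2 <- sum(1 / seq_len(round(n) - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Standard Tajima's D per window from the segregating-site count S and
#' the summed pairwise differences, with the usual normalization
#' constants. Because missingness makes the called allele count vary by
#' site, the constants use a window-level sample size: the mean (default)
#' or minimum called allele count over the window's sites.
#'
#' @inheritParams nucleotide_diversity_pi
#' @param n_method `"mean"` (default) or `"min"` called-allele count used
#'   for the normalization constants.
#' @return Tibble of window statistics; `value` is D, `NA` for windows
#'   with no segregating site.
#' @export
tajimas_d <- function(sites, pop, population = NULL,
                      size = 50000, step = 10000, n_method = c("mean", "min"),
                      chrom_length = NULL) {
  n_method <- match.arg(n_method)
  assert_sorted(sites)
  pop <- resolve_pop(sites, pop, population)
  dos <- gt_dosage(sites)[, pop, drop = FALSE]
  n_tot <- 2 * rowSums(!is.na(dos))
  n_alt <- rowSums(dos, na.rm = TRUE)
  seg <- n_alt > 0 & n_alt < n_tot & n_tot >= 4
  terms <- site_pi_terms(sites, pop)
  win <- window_frame(sites, size, step, chrom_length)
  purrr::pmap_dfr(win, function(chrom, start, end) {
    in_w <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
    s_idx <- in_w & seg
    S <- sum(s_idx)
    if (S == 0) {
      return(tibble::tibble(chrom = chrom, start = start, end = end,
                            value = NA_real_, n_sites = 0L))
    }
    n <- switch(n_method, mean = mean(n_tot[s_idx]), min = min(n_tot[s_idx]))
    k <- tajima_constants(n)
    pi_sum <- sum(terms[s_idx])
    D <- (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    tibble::tibble(chrom = chrom, start = start, end = end,
                   value = D, n_sites = S)
  })
}

# Weir & Cockerham (1984) per-site variance components for two
# populations; returns a (numerator) and a+b+c (denominator)
wc_site_components <- function(p, n, h) {
  r <- 2
  n_bar <- mean(n)
  if (n_bar <= 1) return(c(NA_real_, NA_real_))
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a, a + b + cc)
}

#' Windowed Weir-Cockerham Fst
#'
#' The Weir & Cockerham (1984) variance-components estimator for two
#' populations; the windowed value is the ratio of summed numerator
#' (among-population) components to summed total components over the
#' window's usable sites.
#'
#' @param sites A biallelic site table, sorted.
#' @param pop_a,pop_b Sample name vectors of the two populations.
#' @param size,step Window size and step in bp (defaults 50000 / 10000).
#' @param chrom_length Optional chromosome length.
#' @return Tibble of window statistics; `value` is Fst, `NA` for windows
#'   with no usable site.
#' @export
weir_cockerham_fst <- function(sites, pop_a, pop_b,
                               size = 50000, step = 10000,
                               chrom_length = NULL) {
  assert_sorted(sites)
  pop_a <- resolve_pop(sites, pop_a)
  pop_b <- resolve_pop(sites, pop_b)
  dos <- gt_dosage(sites)
  het <- gt_is_het(sites)
  comp <- function(popv) {
    d <- dos[, popv, drop = FALSE]
    h <- het[, popv, drop = FALSE]
    n <- rowSums(!is.na(d))
    list(n = n, p = rowSums(d, na.rm = TRUE) / (2 * n),
         h = rowSums(h, na.rm = TRUE) / n)
  }
  A <- comp(pop_a)
  B <- comp(pop_b)
  ok <- A$n >= 1 & B$n >= 1 & (A$n + B$n) > 2
  ab <- matrix(NA_real_, nrow(sites), 2)
  for (i in which(ok)) {
    ab[i, ] <- wc_site_components(c(A$p[i], B$p[i]), c(A$n[i], B$n[i]),
                                  c(A$h[i], B$h[i]))
  }
  win <- window_frame(sites, size, step, chrom_length)
  purrr::pmap_dfr(win, function(chrom, start, end) {
    in_w <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end &
      !is.na(ab[, 1])
    num <- sum(ab[in_w, 1])
    den <- sum(ab[in_w, 2])
    tibble::tibble(chrom = chrom, start = start, end = end,
                   value = if (sum(in_w) > 0 && den != 0) num / den
                           else NA_real_,
                   n_sites = sum(in_w))
  })
}

#' Linkage-disequilibrium decay curve
#'
#' r2 between pairs of sites within `max_dist` bp, computed as the squared
#' Pearson correlation of unphased genotype dosages (0/1/2) over samples
#' called at both sites (Rogers-Huff style, appropriate for unphased
#' resequencing data). Pairs are binned by distance; the half-decay
#' distance is the smallest bin midpoint whose mean r2 has fallen to half
#' the maximum of the binned means.
#'
#' @param sites A biallelic filtered site table, sorted.
#' @param pop Optional sample subset (default all samples).
#' @param max_dist Maximum pair distance in bp (default 100000).
#' @param bin Distance bin width in bp (default 1000).
#' @param maf_min Sites below this minor allele frequency are excluded
#'   before pairing (default 0.05).
#' @return Tibble of class `ld_curve` with `bin_mid`, `mean_r2`,
#'   `n_pairs`; attribute `half_decay_distance` (also via `glance()`).
#' @export
ld_decay <- function(sites, pop = site_samples(sites), max_dist = 100000,
                     bin = 1000, maf_min = 0.05) {
  assert_sorted(sites)
  pop <- resolve_pop(sites, pop)
  keep <- maf_filter(sites, maf = maf_min)
  sites <- sites[keep, , drop = FALSE]
  dos <- gt_dosage(sites)[, pop, drop = FALSE]
  n_bins <- ceiling(max_dist / bin)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    for (ii in seq_along(idx)) {
      jj <- ii + 1L
      jmax <- length(idx)
      if (jj > jmax) next
      far <- which(pos[jj:jmax] - pos[ii] > max_dist)
      jend <- if (length(far)) jj + far[1] - 2L else jmax
      if (jend < jj) next
      x <- dos[idx[ii], ]
      Y <- dos[idx[jj:jend], , drop = FALSE]
      r <- suppressWarnings(
        stats::cor(x, t(Y), use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      d <- pos[jj:jend] - pos[ii]
      b <- pmin(pmax(ceiling(d / bin), 1L), n_bins)
      okp <- !is.na(r2)
      for (bb in unique(b[okp])) {
        sel <- okp & b == bb
        sum_r2[bb] <- sum_r2[bb] + sum(r2[sel])
        n_pairs[bb] <- n_pairs[bb] + sum(sel)
      }
    }
  }
  out <- tibble::tibble(
    bin_mid = (seq_len(n_bins) - 0.5) * bin,
    mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1L), NA_real_),
    n_pairs = n_pairs
  )
  filled <- !is.na(out$mean_r2)
  half <- NA_real_
  if (any(filled)) {
    peak <- max(out$mean_r2[filled])
    hit <- filled & out$mean_r2 <= 0.5 * peak
    if (any(hit)) half <- out$bin_mid[which(hit)[1]]
  }
  attr(out, "half_decay_distance") <- half
  class(out) <- c("ld_curve", class(out))
  out
}

#' Half-decay distance of an LD curve
#' @param x An `ld_curve` from [ld_decay()].
#' @return Distance in bp (`NA` if the curve never falls to half maximum).
#' @export
half_decay_distance <- function(x) attr(x, "half_decay_distance")

#' @export
glance.ld_curve <- function(x, ...) {
  tibble::tibble(half_decay_distance = attr(x, "half_decay_distance"),
                 max_mean_r2 = suppressWarnings(max(x$mean_r2, na.rm = TRUE)),
                 n_pairs = sum(x$n_pairs))
}
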