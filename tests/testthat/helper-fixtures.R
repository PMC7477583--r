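# small hand-built site tables used across test files

# biallelic SNP table from an alt-dosage matrix (rows = sites)
toy_sites <- function(pos, dosage, chrom = "chr1", qual = 100,
                      dp = 14L, ...) {
  dosage <- as.matrix(dosage)
  gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow(dosage))
  gt[is.na(dosage)] <- "./."
  colnames(gt) <- sprintf("S%03d", seq_len(ncol(gt)))
  dpm <- matrix(dp, nrow(dosage), ncol(dosage), dimnames = dimnames(gt))
  dpm[is.na(dosage)] <- NA_integer_
  site_table(chrom = rep(chrom, length(pos)), pos = pos,
             ref = rep("A", length(pos)), alt = rep("T", length(pos)),
             gt = gt, dp = dpm, qual = qual, ...)
}

# allele-level O(n^2) pairwise-difference oracle for windowed pi
brute_force_pi <- function(sites, pop, start, end, size) {
  in_w <- sites$pos >= start & sites$pos <= end
  total <- 0
  for (i in which(in_w)) {
    gts <- sites$gt[i, pop]
    alleles <- unlist(strsplit(gts[gts != "./."], "/"))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) if (alleles[a] != alleles[b]) diffs <- diffs + 1
    }
    total <- total + diffs / choose(n, 2)
  }
  total / size
}

# Weir & Cockerham (1984) estimator written directly from the published
# variance components, generalized to r populations (independent oracle)
wc_fst_oracle <- function(p_list, n_list, h_list) {
  r <- length(p_list)
  num <- den <- 0
  for (s in seq_along(p_list[[1]])) {
    n <- vapply(n_list, `[`, 0, s)
    p <- vapply(p_list, `[`, 0, s)
    h <- vapply(h_list, `[`, 0, s)
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# exhaustive region-merge oracle: applies eligible adjacent merges in
# every order; the merge rule is monotone so all orders reach the same
# fixpoint, which is returned (and uniqueness asserted)
brute_force_merge <- function(regions, gap_rule, size_rule) {
  combine <- switch(size_rule, mean = function(a, b) (a + b) / 2,
                    min = min, max = max, sum = function(a, b) a + b)
  terminal <- new.env()
  recurse <- function(reg) {
    eligible <- integer()
    if (nrow(reg) > 1) {
      for (i in seq_len(nrow(reg) - 1)) {
        gap <- reg$start[i + 1] - reg$end[i] - 1
        sz <- combine(reg$end[i] - reg$start[i] + 1,
                      reg$end[i + 1] - reg$start[i + 1] + 1)
        if (gap <= gap_rule * sz) eligible <- c(eligible, i)
      }
    }
    if (!length(eligible)) {
      key <- paste(reg$start, reg$end, reg$score, collapse = ";")
      assign(key, reg, envir = terminal)
      return()
    }
    for (i in eligible) {
      nxt <- reg
      nxt$end[i] <- nxt$end[i + 1]
      nxt$score[i] <- nxt$score[i] + nxt$score[i + 1]
      nxt$n_points[i] <- nxt$n_points[i] + nxt$n_points[i + 1]
      recurse(nxt[-(i + 1), , drop = FALSE])
    }
  }
  recurse(regions)
  states <- as.list(terminal)
  stopifnot(length(states) == 1)
  states[[1]]
}

random_region_set <- function(n_max = 6) {
  n <- sample.int(n_max, 1)
  sizes <- sample.int(3000, n)
  gaps <- sample.int(2500, n)
  starts <- cumsum(gaps) + cumsum(c(0, sizes[-n]))
  tibble::tibble(chrom = "chr1", start = as.numeric(starts),
                 end = as.numeric(starts + sizes - 1),
                 score = stats::runif(n, 1, 10),
                 n_points = rep(1L, n))
}
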