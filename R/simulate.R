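#' Simulation configuration
#'
#' Bundles the parameters of the synthetic resequencing-data generator.
#' Defaults describe the desk-scale conditions used throughout the
#' package: 30 diploids on a 2-Mb chromosome at 5 SNPs/kb, a neutral
#' frequency spectrum proportional to `1/k`, mean read depth 14 with
#' negative-binomial overdispersion, and 2% missing genotypes.
#'
#' @param n_samples Diploid samples to simulate.
#' @param n_sites Segregating sites to place on the chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @param theta_shape Exponent `xi` of the neutral spectrum `P(k) ~ 1/k^xi`;
#'   1 is the standard neutral expectation.
#' @param sweep_center Position (bp) of an implanted hard sweep, or `NULL`.
#' @param sweep_alpha Sweep strength: per-bp lineage escape rate (>0). The
#'   default gives an escape probability of 0.5 at 10 kb from the center.
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param depth_mean,depth_dispersion Mean and negative-binomial size of
#'   per-sample per-site read depth.
#' @param ld_scale When non-`NULL`, haplotypes are founder mosaics with
#'   this copying length scale (bp), producing r2 that decays with
#'   half-decay distance about `0.69 * ld_scale`; when `NULL` (default)
#'   sites are independent.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   bit-identical across runs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 30, n_sites = 10000,
                       chrom_length = 2e6, chrom = "chr1",
                       theta_shape = 1,
                       sweep_center = NULL, sweep_alpha = 6.9e-5,
                       missing_rate = 0.02,
                       depth_mean = 14, depth_dispersion = 8,
                       ld_scale = NULL, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            n_sites <= chrom_length, depth_mean > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a neutral multi-sample population
#'
#' Places `n_sites` biallelic SNPs uniformly without replacement on the
#' chromosome. The derived-allele count `k` among the `2 * n_samples`
#' haploid lineages is drawn with probability proportional to
#' `1/k^theta_shape` (k = 1..n-1), the derived allele is assigned to a
#' uniform random subset of lineages, and diploid genotypes are formed by
#' pairing consecutive lineages (Hardy-Weinberg). Genotypes are masked at
#' `missing_rate`; depths are negative-binomial with mean `depth_mean`.
#' The reference allele is the ancestral state, so an outgroup carrying the
#' reference allele everywhere polarizes the sample exactly.
#'
#' @param config A [sim_config()].
#' @return A site table (see [site_table()]) with attributes:
#'   `haplotypes` (0/1 matrix, lineages x sites), `truth` (tibble of
#'   per-site derived counts among all lineages) and `outgroup`
#'   (tibble chrom/pos/allele of ancestral alleles).
#' @export
simulate_neutral_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_sites > config$chrom_length) {
    stop("n_sites exceeds chrom_length", call. = FALSE)
  }
  set.seed(config$seed)
  n_hap <- 2L * config$n_samples
  m <- config$n_sites
  pos <- sort(sample.int(config$chrom_length, m))

  H <- matrix(0L, n_hap, m)
  if (is.null(config$ld_scale)) {
    kk <- seq_len(n_hap - 1L)
    k <- sample(kk, m, replace = TRUE, prob = 1 / kk^config$theta_shape)
    for (j in seq_len(m)) H[sample.int(n_hap, k[j]), j] <- 1L
  } else {
    # founder-mosaic mode: two founder haplotypes, each lineage switches
    # between them at rate 1/(2*ld_scale) per bp, giving ancestry
    # correlation exp(-d / ld_scale) between sites d apart
    founder <- matrix(0L, 2L, m)
    founder[cbind(sample.int(2L, m, replace = TRUE), seq_len(m))] <- 1L
    p_stay <- exp(-diff(c(pos[1], pos)) / (2 * config$ld_scale))
    for (l in seq_len(n_hap)) {
      z <- integer(m)
      z[1] <- sample.int(2L, 1L)
      sw <- stats::runif(m) > p_stay
      for (j in seq_len(m - 1L)) {
        z[j + 1L] <- if (sw[j + 1L]) sample.int(2L, 1L) else z[j]
      }
      H[l, ] <- founder[cbind(z, seq_len(m))]
    }
    # drop sites monomorphic in the sample
    poly <- colSums(H) > 0L & colSums(H) < n_hap
    H <- H[, poly, drop = FALSE]
    pos <- pos[poly]
    m <- length(pos)
  }

  sites <- genotypes_from_haplotypes(H, pos, config)
  attr(sites, "haplotypes") <- H
  attr(sites, "truth") <- tibble::tibble(
    chrom = config$chrom, pos = pos,
    derived_count = as.integer(colSums(H)), n = n_hap
  )
  attr(sites, "outgroup") <- tibble::tibble(
    chrom = config$chrom, pos = pos, allele = sites$ref
  )
  sites
}

# assemble a site table from a haplotype matrix; draws alleles, depths,
# QUAL/INFO annotations and the missingness mask (consumes RNG)
genotypes_from_haplotypes <- function(H, pos, config) {
  n_hap <- nrow(H)
  n_samp <- n_hap %/% 2L
  m <- length(pos)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), "")

  a1 <- t(H[seq(1L, n_hap, by = 2L), , drop = FALSE])  # sites x samples
  a2 <- t(H[seq(2L, n_hap, by = 2L), , drop = FALSE])
  gt <- matrix(paste0(pmin(a1, a2), "/", pmax(a1, a2)), m, n_samp)
  colnames(gt) <- sprintf("S%03d", seq_len(n_samp))

  dp <- matrix(stats::rnbinom(m * n_samp, mu = config$depth_mean,
                              size = config$depth_dispersion), m, n_samp)
  colnames(dp) <- colnames(gt)
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(m * n_samp) < config$missing_rate, m, n_samp)
    gt[miss] <- "./."
    dp[miss] <- NA_integer_
  }
  site_table(
    chrom = config$chrom, pos = pos, ref = ref, alt = alt, gt = gt, dp = dp,
    qual = round(stats::runif(m, 60, 600), 2),
    qd = round(stats::runif(m, 10, 30), 2),
    fs = round(stats::runif(m, 0, 10), 3),
    mq = round(stats::runif(m, 50, 60), 2),
    mq_rank_sum = round(stats::rnorm(m, 0, 1), 3),
    read_pos_rank_sum = round(stats::rnorm(m, 0, 1), 3)
  )
}

#' Implant a hard selective sweep
#'
#' Applies the deterministic-escape (star-like dragging) approximation of a
#' hard sweep to a simulated population: one sweeping haplotype is chosen;
#' at each site a lineage *escapes* the sweep independently with
#' probability `p_e = 1 - exp(-alpha * d)` where `d` is the distance to the
#' sweep center; every non-escaping lineage is coalesced onto the sweeping
#' haplotype. Near the center this pushes site frequencies to 0 or `n`,
#' erasing intermediate-frequency variation — exactly the signal class the
#' composite-likelihood scan models. Positions, sample count and site count
#' are never changed, only genotype values.
#'
#' @param sites A site table from [simulate_neutral_population()] (the
#'   haplotype matrix attribute is required).
#' @param center Sweep center (bp).
#' @param alpha Per-bp escape rate (> 0); smaller alpha = wider footprint.
#' @param seed Optional seed for the escape draws.
#' @return The modified site table; attribute `sweep_truth` holds
#'   `center`, `alpha` and the positions whose genotypes changed, and the
#'   `truth`/`haplotypes` attributes are updated.
#' @export
implant_sweep <- function(sites, center, alpha, seed = NULL) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  H <- attr(sites, "haplotypes")
  if (is.null(H)) {
    stop("site table lacks a haplotype matrix; use simulate_neutral_population()",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_hap <- nrow(H)
  m <- ncol(H)
  d <- abs(sites$pos - center)
  pe <- 1 - exp(-alpha * d)
  pe[d == 0] <- 0
  h_star <- sample.int(n_hap, 1L)
  H_new <- H
  for (j in seq_len(m)) {
    if (pe[j] >= 1) next
    dragged <- stats::runif(n_hap) >= pe[j]
    H_new[dragged, j] <- H[h_star, j]
  }
  changed <- which(colSums(H_new != H) > 0L)

  # re-pair genotypes, preserving the original missingness mask and all
  # site-level fields
  n_samp <- n_hap %/% 2L
  a1 <- t(H_new[seq(1L, n_hap, by = 2L), , drop = FALSE])
  a2 <- t(H_new[seq(2L, n_hap, by = 2L), , drop = FALSE])
  gt <- matrix(paste0(pmin(a1, a2), "/", pmax(a1, a2)), m, n_samp)
  colnames(gt) <- site_samples(sites)
  gt[sites$gt == "./."] <- "./."
  out <- sites
  out$gt <- gt
  attr(out, "haplotypes") <- H_new
  attr(out, "truth") <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    derived_count = as.integer(colSums(H_new)), n = n_hap
  )
  attr(out, "outgroup") <- attr(sites, "outgroup")
  attr(out, "sweep_truth") <- list(center = center, alpha = alpha,
                                   swept_sites = sites$pos[changed])
  out
}

#' Inject filter-fodder artifacts into a simulated site table
#'
#' Adds indel records, moves a fraction of SNPs to within 4 bp of an indel,
#' assigns QUAL values straddling 40, makes a fraction of sites triallelic,
#' breaks hard-filter annotations for a fraction, and perturbs total depths
#' to create outliers beyond the 2.5/97.5 depth percentiles. Ground-truth
#' labels stating which strict criterion each site fails are generated
#' alongside with simple site-by-site code (the same sequential set logic
#' as [filter_cascade()], but computed independently), so the cascade can
#' be checked against them exactly.
#'
#' @param sites A site table from the neutral simulator (sorted).
#' @param fraction_near_indel Fraction of SNPs placed within 4 bp of an
#'   injected indel (these must fail the proximity criterion).
#' @param fraction_triallelic Fraction of SNPs given a second ALT allele.
#' @param fraction_qual_straddle Fraction of SNPs whose QUAL is redrawn
#'   uniformly in \[35, 45\], straddling the 40 threshold.
#' @param fraction_hard_fail Fraction of SNPs given a failing hard-filter
#'   annotation (QD, FS, MQ, MQRankSum or ReadPosRankSum, cycled).
#' @param fraction_depth_outlier Fraction of SNPs whose depths are scaled
#'   far into a tail (alternately ~10x and ~0x).
#' @param seed Optional seed.
#' @return A site table containing the SNPs plus injected indel records,
#'   sorted by position, with attribute `artifact_labels`: a tibble with
#'   one row per record and logical columns `is_indel_record`,
#'   `fail_hard`, `fail_indel_proximity`, `fail_quality`,
#'   `fail_biallelic`, `fail_depth`, `fail_maf`, `pass`.
#' @export
inject_artifacts <- function(sites,
                             fraction_near_indel = 0.05,
                             fraction_triallelic = 0.02,
                             fraction_qual_straddle = 0.10,
                             fraction_hard_fail = 0.05,
                             fraction_depth_outlier = 0.02,
                             seed = NULL) {
  assert_sorted(sites)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(sites)
  out <- sites
  pick <- function(frac, avoid = integer()) {
    n <- round(frac * m)
    candidates <- setdiff(seq_len(m), avoid)
    sort(sample(candidates, min(n, length(candidates))))
  }

  # indels adjacent to a chosen fraction of SNPs (distance 1..4 bp), plus
  # an equal number of "far" indels at distance >= 5 that must not remove
  # anything
  near <- pick(fraction_near_indel)
  occupied <- sites$pos
  make_indels <- function(anchor_idx, dist_range) {
    pos <- integer(0)
    for (i in anchor_idx) {
      for (dlt in sample(c(dist_range, -dist_range))) {
        p <- sites$pos[i] + dlt
        if (p >= 1 && !(p %in% occupied) && !(p %in% pos)) {
          pos <- c(pos, p)
          break
        }
      }
    }
    pos
  }
  indel_near_pos <- make_indels(near, 1:4)
  far <- pick(length(indel_near_pos) / m)
  indel_far_pos <- make_indels(far, 5:9)
  # drop far indels that landed within 5 bp of any SNP other than intended
  keep_far <- vapply(indel_far_pos, function(p) {
    all(abs(sites$pos - p) >= 5)
  }, logical(1))
  indel_far_pos <- indel_far_pos[keep_far]
  indel_pos <- sort(c(indel_near_pos, indel_far_pos))
  if (length(indel_pos)) {
    gt0 <- matrix("0/1", length(indel_pos), length(site_samples(sites)),
                  dimnames = list(NULL, site_samples(sites)))
    dp0 <- matrix(round(mean(sites$dp, na.rm = TRUE)),
                  length(indel_pos), ncol(gt0),
                  dimnames = dimnames(gt0))
    indels <- site_table(
      chrom = rep(sites$chrom[1], length(indel_pos)), pos = indel_pos,
      ref = "AT", alt = "A", gt = gt0, dp = dp0,
      qual = 100, qd = 20, fs = 1, mq = 55
    )
    out <- bind_site_rows(out, indels)
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
  }

  snp_rows <- which(!out$is_indel)
  pick_out <- function(frac) {
    sort(sample(snp_rows, min(round(frac * length(snp_rows)),
                              length(snp_rows))))
  }
  tri <- pick_out(fraction_triallelic)
  if (length(tri)) {
    third <- vapply(seq_along(tri), function(i) {
      sample(setdiff(c("A", "C", "G", "T"),
                     c(out$ref[tri[i]], out$alt[tri[i]])), 1L)
    }, "")
    out$alt[tri] <- paste(out$alt[tri], third, sep = ",")
  }
  straddle <- pick_out(fraction_qual_straddle)
  out$qual[straddle] <- round(stats::runif(length(straddle), 35, 45), 2)
  hard <- pick_out(fraction_hard_fail)
  if (length(hard)) {
    which_anno <- rep_len(1:5, length(hard))
    out$qd[hard[which_anno == 1]] <- 1.0
    out$fs[hard[which_anno == 2]] <- 70
    out$mq[hard[which_anno == 3]] <- 30
    out$mq_rank_sum[hard[which_anno == 4]] <- -13
    out$read_pos_rank_sum[hard[which_anno == 5]] <- -9
  }
  outlier <- pick_out(fraction_depth_outlier)
  if (length(outlier)) {
    hi <- outlier[seq_along(outlier) %% 2L == 1L]
    lo <- setdiff(outlier, hi)
    out$dp[hi, ] <- out$dp[hi, , drop = FALSE] * 10L
    out$dp[lo, ] <- 0L
  }

  attr(out, "artifact_labels") <- artifact_truth_labels(out)
  attr(out, "haplotypes") <- NULL
  out
}

# independent site-by-site labelling of the strict-filter cascade,
# mirroring its sequential set logic with plain brute-force code
artifact_truth_labels <- function(sites) {
  m <- nrow(sites)
  fail_hard <- logical(m)
  for (i in seq_len(m)) {
    conds <- c(sites$qd[i] < 2.0, sites$fs[i] > 60.0, sites$mq[i] < 40.0,
               sites$mq_rank_sum[i] < -12.5,
               sites$read_pos_rank_sum[i] < -8.0)
    fail_hard[i] <- any(conds, na.rm = TRUE)   # absent => does not fail
  }
  indel_positions <- sites$pos[sites$is_indel & !fail_hard]
  fail_prox <- vapply(seq_len(m), function(i) {
    if (sites$is_indel[i]) return(FALSE)
    any(abs(indel_positions - sites$pos[i]) < 5)
  }, logical(1))
  fail_quality <- is.na(sites$qual) | sites$qual < 40
  n_alts <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  fail_biallelic <- sites$is_indel | n_alts != 1L

  alive <- !fail_hard & !sites$is_indel & !fail_prox & !fail_quality &
    !fail_biallelic
  depth <- site_total_depth(sites)
  bounds <- stats::quantile(depth[alive], c(0.025, 0.975), type = 7)
  fail_depth <- alive & (depth < bounds[1] | depth > bounds[2])
  alive <- alive & !fail_depth

  dos <- gt_dosage(sites)
  fail_maf <- vapply(seq_len(m), function(i) {
    if (!alive[i]) return(FALSE)
    d <- dos[i, ]
    d <- d[!is.na(d)]
    if (!length(d)) return(TRUE)
    p <- sum(d) / (2 * length(d))
    min(p, 1 - p) < 0.01
  }, logical(1))
  tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    is_indel_record = sites$is_indel,
    fail_hard = fail_hard, fail_indel_proximity = fail_prox,
    fail_quality = fail_quality, fail_biallelic = fail_biallelic,
    fail_depth = fail_depth, fail_maf = fail_maf,
    pass = alive & !fail_maf
  )
}

#' Simulate the two terminal repeats of an LTR element
#'
#' Evolves two copies of a random ancestral sequence under a Kimura
#' two-parameter substitution process, each branch accumulating
#' `mu * time` expected substitutions per site, for a total expected
#' divergence of `2 * mu * time` between the copies — the model underlying
#' terminal-repeat insertion dating.
#'
#' @param time Time since insertion (years, >= 0).
#' @param mu Substitution rate per site per year (> 0).
#' @param tstv Expected transition/transversion *count* ratio (0.5 means
#'   all six substitution rates equal; typical nuclear DNA ~2).
#' @param length Alignment length (bp).
#' @param seed Optional seed.
#' @return List of class `ltr_pair`: `seq_a`, `seq_b` (character strings),
#'   `true_time`, `mu`, `tstv`.
#' @export
simulate_ltr_pair <- function(time, mu = 6.5e-9, tstv = 2, length = 5000,
                              seed = NULL) {
  if (time < 0) stop("time must be >= 0", call. = FALSE)
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nt <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  anc <- sample(nt, length, replace = TRUE)
  kappa <- 2 * tstv
  d <- mu * time
  e1 <- exp(-4 * d / (kappa + 2))
  e2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
  p_ts <- 1 / 4 + e1 / 4 - e2 / 2
  p_tv_each <- 1 / 4 - e1 / 4
  evolve <- function(s) {
    u <- stats::runif(length(s))
    out <- s
    is_ts <- u < p_ts
    is_tv1 <- !is_ts & u < p_ts + p_tv_each
    is_tv2 <- !is_ts & !is_tv1 & u < p_ts + 2 * p_tv_each
    out[is_ts] <- ts_partner[s[is_ts]]
    tv_targets <- function(base) setdiff(nt, c(base, ts_partner[base]))
    for (b in nt) {
      tv <- tv_targets(b)
      out[is_tv1 & s == b] <- tv[1]
      out[is_tv2 & s == b] <- tv[2]
    }
    out
  }
  structure(list(seq_a = paste(evolve(anc), collapse = ""),
                 seq_b = paste(evolve(anc), collapse = ""),
                 true_time = time, mu = mu, tstv = tstv),
            class = "ltr_pair")
}

#' Tile synthetic gene features along a chromosome
#'
#' Emits one gene every `spacing` bp, used to exercise sweep-region gene
#' overlap without a real annotation.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length (bp).
#' @param spacing Distance between gene starts (bp).
#' @param width Gene width (bp).
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
simulate_genes <- function(chrom = "chr1", chrom_length = 2e6,
                           spacing = 10000, width = 2000) {
  start <- seq(1L, as.integer(chrom_length - width), by = as.integer(spacing))
  tibble::tibble(
    chrom = chrom, start = start, end = as.integer(start + width - 1L),
    strand = rep_len(c("+", "-"), length(start)),
    gene_id = sprintf("gene%04d", seq_along(start))
  )
}

#' Write gene features as GFF3
#' @param genes Tibble as returned by [simulate_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(paste(genes$chrom, "teapop", "gene", genes$start, genes$end,
                     ".", genes$strand, ".",
                     paste0("ID=", genes$gene_id), sep = "\t"), con)
  }
  invisible(path)
}
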