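#' GATK-style hard filter
#'
#' Evaluates the site-annotation hard filter
#' `QD >= 2.0 && FS <= 60.0 && MQ >= 40.0 && MQRankSum >= -12.5 &&
#' ReadPosRankSum >= -8.0`. All comparisons are inclusive exactly as
#' written. An annotation absent from a record (`NA`) does not fail its
#' condition — rank-sum annotations in particular are undefined at sites
#' without both ref and alt reads, and their absence is not evidence
#' against the site.
#'
#' @param sites A site table.
#' @return Tibble with `chrom`, `pos`, `pass` and `reasons` (comma-joined
#'   names of failing conditions, `""` when passing).
#' @export
hard_filter <- function(sites) {
  fails <- cbind(
    QD = !is.na(sites$qd) & sites$qd < 2.0,
    FS = !is.na(sites$fs) & sites$fs > 60.0,
    MQ = !is.na(sites$mq) & sites$mq < 40.0,
    MQRankSum = !is.na(sites$mq_rank_sum) & sites$mq_rank_sum < -12.5,
    ReadPosRankSum = !is.na(sites$read_pos_rank_sum) &
      sites$read_pos_rank_sum < -8.0
  )
  reasons <- apply(fails, 1, function(r) paste(colnames(fails)[r],
                                               collapse = ","))
  tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                 pass = rowSums(fails) == 0L, reasons = reasons)
}

#' Indel-proximity filter
#'
#' Keeps a SNP only when no indel record lies within `window` bp of it on
#' the same chromosome (`|snp.pos - indel.pos| < window` removes the SNP;
#' a distance of exactly `window` bp satisfies "at least `window` bp" and
#' is retained). Indel records themselves are dropped from the returned
#' stream. The indel anchor is its POS field, not its span end.
#'
#' @param sites Site table sorted by (chrom, pos).
#' @param window Minimum allowed SNP-indel distance (bp), default 5.
#' @return The surviving SNP site table.
#' @export
indel_proximity_filter <- function(sites, window = 5) {
  assert_sorted(sites)
  keep <- !sites$is_indel
  for (ch in unique(sites$chrom)) {
    in_ch <- sites$chrom == ch
    ipos <- sites$pos[in_ch & sites$is_indel]
    if (!length(ipos)) next
    spos <- sites$pos[in_ch & !sites$is_indel]
    if (!length(spos)) next
    # nearest indel via findInterval on the sorted indel positions
    idx <- findInterval(spos, ipos)
    d_left <- ifelse(idx >= 1, spos - ipos[pmax(idx, 1L)], Inf)
    d_right <- ifelse(idx < length(ipos), ipos[pmin(idx + 1L, length(ipos))] -
                        spos, Inf)
    near <- pmin(d_left, d_right) < window
    keep[in_ch & !sites$is_indel] <- !near
  }
  sites[keep, , drop = FALSE]
}

#' Consensus-quality filter
#'
#' A site passes iff `QUAL >= threshold` (inclusive). A missing QUAL fails:
#' quality is the subject of this criterion, so its absence is a failure,
#' unlike the evidence annotations of [hard_filter()].
#'
#' @param sites A site table.
#' @param threshold Minimum QUAL, default 40.
#' @return Logical vector, one element per site.
#' @export
quality_filter <- function(sites, threshold = 40) {
  !is.na(sites$qual) & sites$qual >= threshold
}

#' Biallelic-SNP filter
#'
#' A site passes iff it has exactly one alternate allele and every allele
#' has length 1 (no triallelic sites, no indels).
#'
#' @param sites A site table.
#' @return Logical vector, one element per site.
#' @export
biallelic_snp_filter <- function(sites) {
  n_alts <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  n_alts == 1L & !sites$is_indel
}

#' Depth-percentile filter
#'
#' Computes the empirical `lo` and `hi` percentiles (linear interpolation,
#' [stats::quantile()] type 7) of per-site total depth over the candidate
#' set, then keeps sites whose total depth lies within the bounds
#' (inclusive). The bounds are computed from exactly the sites passed in,
#' so the step must run after the per-site criteria in the cascade.
#'
#' @param sites Candidate site table (non-empty).
#' @param lo,hi Percentile bounds as fractions, defaults 0.025 and 0.975.
#' @return Surviving site table; attribute `depth_bounds` holds the
#'   numeric bounds `c(lo, hi)`.
#' @export
depth_percentile_filter <- function(sites, lo = 0.025, hi = 0.975) {
  if (nrow(sites) == 0) stop("empty candidate set", call. = FALSE)
  depth <- site_total_depth(sites)
  bounds <- unname(stats::quantile(depth, c(lo, hi), type = 7))
  out <- sites[depth >= bounds[1] & depth <= bounds[2], , drop = FALSE]
  attr(out, "depth_bounds") <- bounds
  out
}

#' Minor-allele-frequency filter
#'
#' The alternate-allele frequency `p` is the alt dosage sum over twice the
#' non-missing sample count; a site passes iff `min(p, 1-p) >= maf`
#' (inclusive). A site with all genotypes missing fails.
#'
#' @param sites A biallelic site table.
#' @param maf Minimum minor allele frequency, default 0.01.
#' @return Logical vector, one element per site.
#' @export
maf_filter <- function(sites, maf = 0.01) {
  dos <- gt_dosage(sites)
  called <- rowSums(!is.na(dos))
  p <- rowSums(dos, na.rm = TRUE) / (2 * called)
  !is.na(p) & called > 0 & pmin(p, 1 - p) >= maf
}

#' Strict SNP filter cascade
#'
#' Applies the hard filter followed by the five strict criteria in order:
#' (1) indel proximity, (2) consensus quality, (3) biallelic SNP,
#' (4) depth percentile, (5) minor allele frequency. Survivors of each
#' step are exactly the input of the next, so the per-step counts are
#' monotone non-increasing.
#'
#' @param sites Site table sorted by (chrom, pos).
#' @param indel_window,qual_threshold,depth_lo,depth_hi,maf Thresholds of
#'   the individual steps; see the step functions for semantics.
#' @return The surviving site table, classed `filtered_sites`, with
#'   attributes `filter_report` (tibble `step`, `n_in`, `n_out`) and
#'   `depth_bounds`. `tidy()` on the result returns the report.
#' @export
filter_cascade <- function(sites, indel_window = 5, qual_threshold = 40,
                           depth_lo = 0.025, depth_hi = 0.975, maf = 0.01) {
  assert_sorted(sites)
  report <- list()
  note <- function(step, n_in, n_out) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      step = step, n_in = n_in, n_out = n_out)
  }
  cur <- sites[hard_filter(sites)$pass, , drop = FALSE]
  note("hard_filter", nrow(sites), nrow(cur))

  n_in <- nrow(cur)
  cur <- indel_proximity_filter(cur, window = indel_window)
  note("indel_proximity", n_in, nrow(cur))

  n_in <- nrow(cur)
  cur <- cur[quality_filter(cur, qual_threshold), , drop = FALSE]
  note("quality", n_in, nrow(cur))

  n_in <- nrow(cur)
  cur <- cur[biallelic_snp_filter(cur), , drop = FALSE]
  note("biallelic_snp", n_in, nrow(cur))

  n_in <- nrow(cur)
  bounds <- c(NA_real_, NA_real_)
  if (n_in > 0) {
    cur <- depth_percentile_filter(cur, depth_lo, depth_hi)
    bounds <- attr(cur, "depth_bounds")
  }
  note("depth_percentile", n_in, nrow(cur))

  n_in <- nrow(cur)
  cur <- cur[maf_filter(cur, maf), , drop = FALSE]
  note("maf", n_in, nrow(cur))

  out <- cur
  attr(out, "filter_report") <- dplyr::bind_rows(report)
  attr(out, "depth_bounds") <- bounds
  class(out) <- c("filtered_sites", class(tibble::tibble()))
  out
}

#' Per-step report of a filter cascade
#' @param x Result of [filter_cascade()].
#' @return Tibble with columns `step`, `n_in`, `n_out`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.filtered_sites <- function(x, ...) filter_report(x)

#' @export
glance.filtered_sites <- function(x, ...) {
  rep <- filter_report(x)
  tibble::tibble(n_input = rep$n_in[1], n_pass = nrow(x),
                 prop_pass = nrow(x) / max(rep$n_in[1], 1L),
                 depth_lo = attr(x, "depth_bounds")[1],
                 depth_hi = attr(x, "depth_bounds")[2])
}

#' Select sites for structure-style analyses
#'
#' Drops sites whose missing-genotype fraction exceeds `max_missing`, then
#' thins by minimum spacing: the first site of each chromosome is kept and
#' every subsequent site at least `thin_bp` from the last kept site
#' (greedy left-to-right walk, deterministic). A fixed-bin alternative
#' (`mode = "bins"`: at most one site — the first — per
#' `[k*thin_bp, (k+1)*thin_bp)` bin) is provided since the sliding
#' interpretation of "no two sites within the same region" is not the
#' only one.
#'
#' @param sites Filtered site table, sorted.
#' @param max_missing Maximum missing-genotype fraction, default 0.2.
#' @param thin_bp Minimum spacing (or bin width) in bp, default 2000.
#' @param mode `"spacing"` (default) or `"bins"`.
#' @return The thinned site table.
#' @export
select_for_structure <- function(sites, max_missing = 0.2, thin_bp = 2000,
                                 mode = c("spacing", "bins")) {
  mode <- match.arg(mode)
  assert_sorted(sites)
  miss_frac <- rowMeans(sites$gt == "./.")
  sites <- sites[miss_frac <= max_missing, , drop = FALSE]
  if (nrow(sites) == 0) return(sites)
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (mode == "spacing") {
      last <- -Inf
      for (i in seq_along(pos)) {
        if (pos[i] - last >= thin_bp) {
          keep[idx[i]] <- TRUE
          last <- pos[i]
        }
      }
    } else {
      bin <- (pos - 1L) %/% as.integer(thin_bp)
      keep[idx[!duplicated(bin)]] <- TRUE
    }
  }
  sites[keep, , drop = FALSE]
}
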