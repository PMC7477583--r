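#' Polarize sites against an outgroup
#'
#' Assigns ancestral/derived states from an outgroup allele table. When
#' the outgroup carries one of the site's two alleles, that allele is
#' ancestral and `derived_count` counts the other; when the outgroup
#' allele matches neither allele, or no outgroup call exists at the
#' position, the site is *folded* and `derived_count` is the minor allele
#' count. Sites that are neither polymorphic nor substitutions
#' (`derived_count` 0 without a fixed difference) carry no information for
#' the scan and are excluded.
#'
#' @param sites A biallelic filtered site table.
#' @param outgroup Tibble with columns `chrom`, `pos`, `allele`.
#' @return Tibble with `chrom`, `pos`, `derived_count`, `n` (called allele
#'   count), `folded`, `is_substitution`.
#' @export
polarize <- function(sites, outgroup) {
  dos <- gt_dosage(sites)
  n <- 2L * rowSums(!is.na(dos))
  alt_count <- as.integer(rowSums(dos, na.rm = TRUE))
  key <- paste(sites$chrom, sites$pos)
  og <- outgroup$allele[match(key, paste(outgroup$chrom, outgroup$pos))]
  anc_is_ref <- !is.na(og) & og == sites$ref
  anc_is_alt <- !is.na(og) & og == sites$alt
  folded <- !(anc_is_ref | anc_is_alt)
  derived <- ifelse(anc_is_ref, alt_count,
                    ifelse(anc_is_alt, n - alt_count,
                           pmin(alt_count, n - alt_count)))
  out <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    derived_count = as.integer(derived), n = as.integer(n),
    folded = folded,
    is_substitution = !folded & derived == n & n > 0L
  )
  out[out$derived_count > 0L & out$n > 0L, , drop = FALSE]
}

#' Background site frequency spectrum
#'
#' Tallies polarized sites into frequency classes (substitutions fall in
#' class `n`). When every site has the same called allele count the
#' spectrum is the plain tally. With missing data the called count varies
#' by site; the full-size spectrum is then estimated by a short EM in
#' which each observation contributes through its hypergeometric
#' downsampling likelihood (a folded site contributes through both of its
#' candidate classes). With complete data the EM reduces exactly to the
#' tally.
#'
#' @param polarized Output of [polarize()] for one chromosome and
#'   population.
#' @param n_ref Spectrum sample size; default the maximum called allele
#'   count observed.
#' @param em_iter EM iterations (default 40).
#' @return Object of class `teapop_sfs`: list with `counts` (named tally
#'   of observed derived counts), `n`, `spectrum` (normalized estimate
#'   over classes `1..n`), `n_sites`.
#' @export
background_sfs <- function(polarized, n_ref = NULL, em_iter = 40) {
  if (nrow(polarized) == 0) stop("no usable sites", call. = FALSE)
  N <- as.integer(n_ref %||% max(polarized$n))
  tally <- table(factor(polarized$derived_count, levels = seq_len(N)))
  counts <- stats::setNames(as.numeric(tally), names(tally))

  if (all(polarized$n == N & !polarized$folded)) {
    spectrum <- counts / sum(counts)
  } else {
    p <- (1 / seq_len(N)) / sum(1 / seq_len(N))
    groups <- split(polarized, list(polarized$n, polarized$folded),
                    drop = TRUE)
    lik <- lapply(groups, function(g) {
      m <- g$n[1]
      # L[site, k] = P(observe g$derived_count | true class k of N)
      D <- outer(g$derived_count, seq_len(N), function(j, k) {
        stats::dhyper(j, k, N - k, m)
      })
      if (g$folded[1]) {
        D2 <- outer(g$derived_count, seq_len(N), function(j, k) {
          stats::dhyper(m - j, k, N - k, m)
        })
        same <- g$derived_count == m - g$derived_count
        D <- D + D2 * (1 - same)  # avoid double-counting n/2 class
      }
      D
    })
    for (it in seq_len(em_iter)) {
      acc <- numeric(N)
      for (D in lik) {
        W <- sweep(D, 2, p, `*`)
        rs <- rowSums(W)
        rs[rs == 0] <- 1
        acc <- acc + colSums(W / rs)
      }
      p_new <- acc / sum(acc)
      if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
      p <- p_new
    }
    spectrum <- p
  }
  structure(list(counts = counts, n = N,
                 spectrum = as.numeric(spectrum),
                 n_sites = nrow(polarized)),
            class = "teapop_sfs")
}

#' @export
tidy.teapop_sfs <- function(x, ...) {
  tibble::tibble(derived_count = seq_len(x$n),
                 count = as.numeric(x$counts),
                 proportion = x$spectrum)
}

# hypergeometric projection matrix from sample size N to m:
# P[i+1, j+1] = P(i derived of m | j derived of N), i = 0..m, j = 0..N
sfs_projection <- function(N, m) {
  outer(0:m, 0:N, function(i, j) stats::dhyper(i, j, N - j, m))
}

# Probability tables of the sweep model.
#
# Post-sweep sampling model at escape probability pe: of N lineages,
# e ~ Binomial(N, pe) escape the sweep and represent an (e+1)-draw from
# the background spectrum (the extra draw being the sweeping haplotype,
# whose allele all N-e dragged lineages copy). At pe = 1 the model is the
# background itself, so the likelihood ratio is nonnegative with equality
# attainable. Tables are projected to each observed called-allele count m
# and conditioned on the observable classes.
build_clr_tables <- function(spectrum, N, n_values, pe_grid,
                             include_substitutions = TRUE) {
  qfull <- c(0, spectrum)                      # classes 0..N
  B <- matrix(0, N + 1, N + 1)                 # rows e = 0..N, cols j = 0..N
  for (e in 0:(N - 1)) {
    psi <- as.numeric(sfs_projection(N, e + 1) %*% qfull)  # 0..e+1
    row <- numeric(N + 1)
    for (i in 0:(e + 1)) {
      w <- psi[i + 1]
      if (w == 0) next
      p_hap_derived <- i / (e + 1)
      if (p_hap_derived > 0) {
        j <- i - 1 + (N - e)
        row[j + 1] <- row[j + 1] + w * p_hap_derived
      }
      if (p_hap_derived < 1) {
        row[i + 1] <- row[i + 1] + w * (1 - p_hap_derived)
      }
    }
    B[e + 1, ] <- row
  }
  B[N + 1, ] <- qfull
  W <- outer(pe_grid, 0:N, function(pe, e) stats::dbinom(e, N, pe))
  T_N <- W %*% B                               # n_pe x (N+1)

  lapply(n_values, function(m) {
    P <- sfs_projection(N, m)
    Tm <- T_N %*% t(P)                         # n_pe x (m+1)
    qm <- as.numeric(P %*% qfull)
    allowed <- rep(TRUE, m + 1)
    allowed[1] <- FALSE                        # class 0 unobservable
    if (!include_substitutions) allowed[m + 1] <- FALSE
    qm[!allowed] <- 0
    qm <- qm / sum(qm)
    Tm[, !allowed] <- 0
    rs <- rowSums(Tm)
    rs[rs < 1e-300] <- 1e-300
    Tm <- Tm / rs
    list(m = m, table = Tm, null = qm)
  })
}

#' Composite-likelihood-ratio sweep scan
#'
#' At every test position (default spacing 100 bp across the chromosome
#' span) the composite likelihood of a hard sweep is maximized over the
#' sweep-strength parameter `alpha` and compared against the background
#' frequency spectrum. A site at distance `d` from the test position
#' escapes the sweep with probability `1 - exp(-alpha * d)`; escaping
#' lineages sample the background spectrum while non-escaping lineages
#' copy the sweeping haplotype, displacing frequency-class mass toward the
#' extremes. `clr = 2 * (max_alpha log CL(alpha) - log CL(background))`,
#' zero when the background maximizes. Folded sites contribute the sum of
#' their two candidate class probabilities under both models.
#'
#' @param polarized Output of [polarize()] for one chromosome/population.
#' @param background A `teapop_sfs` from [background_sfs()] of the same
#'   chromosome and population.
#' @param grid_spacing Test-position spacing in bp (default 100).
#' @param alpha_grid Log-spaced candidate sweep strengths (per bp).
#' @param max_span Sites farther than this from the test position are
#'   treated as unaffected (their likelihood ratio is ~0 there); bounds
#'   work, not the model.
#' @param include_substitutions Keep fixed-derived sites (class `n`) in
#'   the spectra (default TRUE, the recommended setting when an outgroup
#'   is available).
#' @param refine Golden-section refinement of alpha around the best grid
#'   value (default TRUE).
#' @param span Optional `c(start, end)` range for test positions; default
#'   the site position range.
#' @return Tibble of class `clr_scan`: `chrom`, `pos`, `clr`, `alpha_hat`
#'   (`NA` where `clr` = 0).
#' @export
clr_scan <- function(polarized, background, grid_spacing = 100,
                     alpha_grid = 10^seq(-7, -2, length.out = 21),
                     max_span = 5e4, include_substitutions = TRUE,
                     refine = TRUE, span = NULL) {
  stopifnot(inherits(background, "teapop_sfs"))
  pol <- polarized
  if (!include_substitutions) pol <- pol[!pol$is_substitution, , drop = FALSE]
  if (nrow(pol) < 2) {
    return(structure(tibble::tibble(chrom = character(), pos = numeric(),
                                    clr = numeric(), alpha_hat = numeric()),
                     class = c("clr_scan", class(tibble::tibble()))))
  }
  stopifnot(length(unique(pol$chrom)) == 1)
  pol <- dplyr::arrange(pol, .data$pos)
  N <- background$n

  pe_grid <- sort(unique(c(0, 10^seq(-6, -2, length.out = 25),
                           seq(0.01, 1, by = 0.01))))
  n_values <- sort(unique(pol$n))
  tabs <- build_clr_tables(background$spectrum, N, n_values, pe_grid,
                           include_substitutions)
  tab_of_n <- match(pol$n, n_values)
  # class indices are 0-based columns of the m-specific table (class j at
  # column j); folded sites get their complementary class as j2
  j1 <- pol$derived_count
  j2 <- ifelse(pol$folded & pol$derived_count != pol$n - pol$derived_count,
               pol$n - pol$derived_count, -1L)
  null_ll <- vapply(seq_len(nrow(pol)), function(i) {
    q <- tabs[[tab_of_n[i]]]$null
    p <- q[j1[i] + 1]
    if (j2[i] >= 0) p <- p + q[j2[i] + 1]
    log(max(p, 1e-300))
  }, numeric(1))

  span <- span %||% range(pol$pos)
  test_pos <- seq(span[1], span[2], by = grid_spacing)
  res <- clr_scan_cpp(as.numeric(test_pos), as.numeric(pol$pos),
                      as.integer(tab_of_n - 1L), as.integer(j1),
                      as.integer(j2), null_ll,
                      lapply(tabs, `[[`, "table"), pe_grid,
                      as.numeric(alpha_grid), max_span, refine)
  out <- tibble::tibble(chrom = pol$chrom[1], pos = test_pos,
                        clr = pmax(res[, 1], 0),
                        alpha_hat = ifelse(res[, 1] > 0, res[, 2], NA_real_))
  class(out) <- c("clr_scan", class(out))
  out
}

#' Top-fraction CLR threshold
#'
#' Empirical `(1 - top_fraction)` quantile (linear interpolation) of the
#' CLR values, pooled across whatever scans are supplied — conventionally, in this
#' design, all chromosomes of one population.
#'
#' @param grid_points A `clr_scan` tibble (or row-bound scans).
#' @param top_fraction Upper tail fraction, default 0.01 (top 1%).
#' @return Threshold value.
#' @export
clr_threshold <- function(grid_points, top_fraction = 0.01) {
  stopifnot(nrow(grid_points) > 0)
  unname(stats::quantile(grid_points$clr, 1 - top_fraction, type = 7))
}

#' Build initial sweep regions from above-threshold grid points
#'
#' Maximal runs of consecutive grid points with `clr >= threshold` become
#' regions spanning the first to last member position, scored by the sum
#' of member CLR values.
#'
#' @param grid_points A `clr_scan` tibble, sorted by position.
#' @param threshold CLR threshold (see [clr_threshold()]).
#' @return Tibble with `chrom`, `start`, `end`, `score`, `n_points`.
#' @export
build_regions <- function(grid_points, threshold) {
  purrr::map_dfr(split(grid_points, grid_points$chrom), function(g) {
    g <- dplyr::arrange(g, .data$pos)
    hot <- g$clr >= threshold
    if (!any(hot)) {
      return(tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), score = numeric(),
                            n_points = integer()))
    }
    r <- rle(hot)
    grp <- rep(seq_along(r$lengths), r$lengths)
    hot_groups <- unique(grp[hot])
    purrr::map_dfr(hot_groups, function(h) {
      sel <- grp == h
      tibble::tibble(chrom = g$chrom[1], start = min(g$pos[sel]),
                     end = max(g$pos[sel]), score = sum(g$clr[sel]),
                     n_points = sum(sel))
    })
  })
}

#' Gap-merge adjacent sweep regions
#'
#' Two neighbouring regions are merged when the gap between them is at
#' most `gap_rule` times the size of the adjacent regions, where "size"
#' is the `size_rule` combination (mean by default; min, max and sum are
#' the other defensible readings) of the two spans. Merging is iterated
#' left-to-right until a fixpoint, so a merge can enable further merges.
#' Scores are summed; spans are unioned.
#'
#' @param regions Sorted, non-overlapping regions from [build_regions()].
#' @param gap_rule Gap threshold as a fraction of the adjacent-region
#'   size, default 0.5.
#' @param size_rule How the two adjacent sizes combine: `"mean"`
#'   (default), `"min"`, `"max"` or `"sum"`.
#' @return Merged region tibble.
#' @export
merge_regions <- function(regions, gap_rule = 0.5,
                          size_rule = c("mean", "min", "max", "sum")) {
  size_rule <- match.arg(size_rule)
  combine <- switch(size_rule, mean = function(a, b) (a + b) / 2,
                    min = min, max = max, sum = function(a, b) a + b)
  purrr::map_dfr(split(regions, regions$chrom), function(g) {
    g <- dplyr::arrange(g, .data$start)
    repeat {
      merged_any <- FALSE
      i <- 1L
      while (i < nrow(g)) {
        gap <- g$start[i + 1] - g$end[i] - 1
        sz_a <- g$end[i] - g$start[i] + 1
        sz_b <- g$end[i + 1] - g$start[i + 1] + 1
        if (gap <= gap_rule * combine(sz_a, sz_b)) {
          g$end[i] <- g$end[i + 1]
          g$score[i] <- g$score[i] + g$score[i + 1]
          g$n_points[i] <- g$n_points[i] + g$n_points[i + 1]
          g <- g[-(i + 1), , drop = FALSE]
          merged_any <- TRUE
        } else {
          i <- i + 1L
        }
      }
      if (!merged_any) break
    }
    g
  })
}

#' Final size filter for sweep regions
#'
#' Drops merged regions spanning fewer than `min_size` bp (span =
#' `end - start + 1`, inclusive: a region of exactly `min_size` is kept).
#'
#' @param regions Merged region tibble.
#' @param min_size Minimum span in bp, default 300.
#' @return Filtered region tibble with summed scores retained.
#' @export
finalize_regions <- function(regions, min_size = 300) {
  regions[regions$end - regions$start + 1 >= min_size, , drop = FALSE]
}

#' Candidate genes overlapping sweep regions
#'
#' A gene is a candidate iff its interval overlaps a final sweep region by
#' at least 1 bp (adjacency is not overlap).
#'
#' @param regions Final region tibble.
#' @param genes Gene features (see [read_gff_genes()]).
#' @return `regions` with a `genes` list-column of overlapping gene ids.
#' @export
genes_in_regions <- function(regions, genes) {
  regions$genes <- purrr::map2(regions$chrom, seq_len(nrow(regions)),
    function(ch, i) {
      hit <- genes$chrom == ch & genes$start <= regions$end[i] &
        genes$end >= regions$start[i]
      genes$gene_id[hit]
    })
  regions
}

#' Full selective-sweep scan pipeline
#'
#' Runs polarization, per-chromosome background spectra and CLR scans, a
#' pooled top-fraction threshold, region building, gap merging, the final
#' size filter and (optionally) gene overlap.
#'
#' @param sites Filtered biallelic site table of one population.
#' @param outgroup Outgroup allele table (`chrom`, `pos`, `allele`).
#' @param genes Optional gene features for candidate extraction.
#' @param grid_spacing,alpha_grid,max_span,include_substitutions,refine
#'   Passed to [clr_scan()].
#' @param top_fraction Threshold tail fraction (default 0.01).
#' @param gap_rule,size_rule Passed to [merge_regions()].
#' @param min_size Minimum final region span (default 300 bp).
#' @return List of class `sweep_scan_result`: `grid` (all grid points),
#'   `threshold`, `regions` (final regions, with `genes` when supplied),
#'   `candidate_genes` (character vector). `tidy()` returns the regions,
#'   `glance()` a one-row summary.
#' @export
sweep_scan <- function(sites, outgroup, genes = NULL,
                       grid_spacing = 100, top_fraction = 0.01,
                       gap_rule = 0.5, size_rule = "mean", min_size = 300,
                       alpha_grid = 10^seq(-7, -2, length.out = 21),
                       max_span = 5e4, include_substitutions = TRUE,
                       refine = TRUE) {
  pol <- polarize(sites, outgroup)
  grid <- purrr::map_dfr(split(pol, pol$chrom), function(p) {
    bg <- background_sfs(p)
    clr_scan(p, bg, grid_spacing = grid_spacing, alpha_grid = alpha_grid,
             max_span = max_span,
             include_substitutions = include_substitutions, refine = refine)
  })
  class(grid) <- c("clr_scan", class(tibble::tibble()))
  thr <- clr_threshold(grid, top_fraction)
  regions <- build_regions(grid, thr)
  regions <- merge_regions(regions, gap_rule = gap_rule,
                           size_rule = size_rule)
  regions <- finalize_regions(regions, min_size = min_size)
  cand <- character()
  if (!is.null(genes)) {
    regions <- genes_in_regions(regions, genes)
    cand <- unique(unlist(regions$genes))
  }
  structure(list(grid = grid, threshold = thr, regions = regions,
                 candidate_genes = cand),
            class = "sweep_scan_result")
}

#' @export
tidy.sweep_scan_result <- function(x, ...) x$regions

#' @export
glance.sweep_scan_result <- function(x, ...) {
  tibble::tibble(n_grid_points = nrow(x$grid), threshold = x$threshold,
                 n_regions = nrow(x$regions),
                 total_score = sum(x$regions$score),
                 max_clr = max(x$grid$clr),
                 n_candidate_genes = length(x$candidate_genes))
}

#' @export
print.sweep_scan_result <- function(x, ...) {
  cat("CLR sweep scan:", nrow(x$grid), "grid points, threshold",
      format(x$threshold, digits = 4), "\n")
  cat(nrow(x$regions), "final sweep regions;",
      length(x$candidate_genes), "candidate genes\n")
  invisible(x)
}
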