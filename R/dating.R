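#' Count transitions and transversions in a pairwise alignment
#'
#' Classifies each alignment column: columns containing a gap (`-`) or `N`
#' in either sequence are skipped pairwise; differing columns are
#' transitions (A<->G, C<->T) or transversions. Proportions are relative
#' to the compared (ungapped, unambiguous) columns.
#'
#' @param pair An `ltr_pair`/aligned pair (list with `seq_a`, `seq_b`), or
#'   a character string when `seq_b` is supplied.
#' @param seq_b Second sequence when `pair` is a string.
#' @return List with `p_transition`, `q_transversion`, `sites_compared`.
#' @export
count_substitutions <- function(pair, seq_b = NULL) {
  if (is.list(pair)) {
    a <- pair$seq_a
    b <- pair$seq_b
  } else {
    a <- pair
    b <- seq_b
  }
  stopifnot(nchar(a) == nchar(b))
  av <- toupper(strsplit(a, "", fixed = TRUE)[[1]])
  bv <- toupper(strsplit(b, "", fixed = TRUE)[[1]])
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites in alignment", call. = FALSE)
  av <- av[ok]
  bv <- bv[ok]
  diff <- av != bv
  purine <- c("A", "G")
  is_ts <- diff & ((av %in% purine) == (bv %in% purine))
  n <- length(av)
  list(p_transition = sum(is_ts) / n,
       q_transversion = sum(diff & !is_ts) / n,
       sites_compared = n)
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)` for transition
#' proportion `P` and transversion proportion `Q`. Outside the domain
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is undefined
#' (saturation) and an error is raised.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return Distance in substitutions per site.
#' @export
k2p_distance <- function(P, Q) {
  if (any(1 - 2 * P - Q <= 0) || any(1 - 2 * Q <= 0)) {
    stop("K2P distance undefined: alignment saturated (log argument <= 0)",
         call. = FALSE)
  }
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Molecular-clock conversion of Ks to time
#'
#' `time = Ks / (2 * mu)` years: the divergence accumulates on both
#' branches, hence the factor 2. Vectorized and exactly linear in `ks`.
#'
#' @param ks Substitutions per site (>= 0). For terminal-repeat dating
#'   this is the K2P distance of the repeat alignment; for gene pairs an
#'   externally computed synonymous-site Ks.
#' @param mu Substitution rate per site per year (> 0); 6.5e-9 is the
#'   conventional rate for LTR insertion dating, 6.1e-9 for dicot gene
#'   pair divergence.
#' @return Time in years.
#' @export
ks_to_time <- function(ks, mu) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(ks < 0)) stop("ks must be >= 0", call. = FALSE)
  ks / (2 * mu)
}

#' Date an LTR element from its terminal repeats
#'
#' Chains [count_substitutions()], [k2p_distance()] and [ks_to_time()]:
#' the K2P distance of the 5'/3' terminal-repeat alignment serves as the
#' neutral divergence ("Ks") accumulated since insertion, when both
#' repeats were identical.
#'
#' @param pair An aligned pair (list with `seq_a`, `seq_b`).
#' @param mu Substitution rate per site per year (default 6.5e-9).
#' @return One-row tibble: `p_transition`, `q_transversion`,
#'   `sites_compared`, `k2p`, `mu`, `time_years`.
#' @export
date_ltr_pair <- function(pair, mu = 6.5e-9) {
  cnt <- count_substitutions(pair)
  d <- k2p_distance(cnt$p_transition, cnt$q_transversion)
  tibble::tibble(p_transition = cnt$p_transition,
                 q_transversion = cnt$q_transversion,
                 sites_compared = cnt$sites_compared,
                 k2p = d, mu = mu, time_years = ks_to_time(d, mu))
}

#' Date gene pairs from a Ks table
#'
#' Applies the molecular clock to externally computed synonymous-site Ks
#' values (codon-aware Ks estimation is out of scope here; supply the
#' values).
#'
#' @param ks_table Data frame with columns `pair_id` and `ks`.
#' @param mu Substitution rate per site per year (default 6.1e-9).
#' @return `ks_table` with `mu` and `time_years` columns appended.
#' @export
date_ks_table <- function(ks_table, mu = 6.1e-9) {
  dplyr::mutate(tibble::as_tibble(ks_table), mu = mu,
                time_years = ks_to_time(.data$ks, mu))
}

#' Read a pairwise alignment from FASTA
#'
#' Expects exactly two records of equal length (gaps allowed).
#'
#' @param path FASTA file path.
#' @return List with `seq_a`, `seq_b` and record `labels`.
#' @export
read_alignment_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  if (length(x) != 2) stop("expected exactly 2 FASTA records", call. = FALSE)
  chars <- lapply(as.character(x), function(s) toupper(paste(s, collapse = "")))
  if (nchar(chars[[1]]) != nchar(chars[[2]])) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  list(seq_a = chars[[1]], seq_b = chars[[2]], labels = names(x))
}

#' Write a pairwise alignment as FASTA
#' @param pair List with `seq_a`, `seq_b`.
#' @param path Output path.
#' @param labels Record names.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(pair, path, labels = c("ltr5", "ltr3")) {
  writeLines(c(paste0(">", labels[1]), pair$seq_a,
               paste0(">", labels[2]), pair$seq_b), path)
  invisible(path)
}
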