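#' Variant site tables
#'
#' The central container in teapop is a *site table*: a [tibble::tibble] with
#' one row per VCF record and matrix columns for per-sample data. Columns:
#'
#' * `chrom`, `pos` — chromosome and 1-based position (bp);
#' * `ref`, `alt` — reference allele and comma-separated alternate alleles;
#' * `qual` — site consensus quality (phred-like), `NA` when missing;
#' * `qd`, `fs`, `mq`, `mq_rank_sum`, `read_pos_rank_sum` — INFO annotations,
#'   `NA` when absent from the record (absence is meaningful: see
#'   [hard_filter()]);
#' * `is_indel` — `TRUE` when any allele has length != 1;
#' * `gt` — character matrix (sites x samples) of unphased genotype strings
#'   (`"0/1"`, `"./."`; phase separators are normalised to `/`);
#' * `dp` — integer matrix (sites x samples) of read depths, `NA` missing.
#'
#' Sample names are the column names of `gt`/`dp`. All coordinates are
#' 1-based inclusive throughout the package; conversion to BED's 0-based
#' half-open convention happens only in [write_bed()].
#'
#' @param chrom,pos,ref,alt,qual Per-site vectors as described above.
#' @param gt Character matrix of genotype strings, one column per sample.
#' @param dp Integer matrix of per-sample depths (optional).
#' @param qd,fs,mq,mq_rank_sum,read_pos_rank_sum Optional INFO annotations.
#' @return A site table (tibble) as described above.
#' @export
site_table <- function(chrom, pos, ref, alt, gt,
                       qual = NA_real_, dp = NULL,
                       qd = NA_real_, fs = NA_real_, mq = NA_real_,
                       mq_rank_sum = NA_real_, read_pos_rank_sum = NA_real_) {
  gt <- as.matrix(gt)
  n <- length(pos)
  stopifnot(nrow(gt) == n, all(pos >= 1), all(nzchar(ref)))
  if (is.null(dp)) {
    dp <- matrix(NA_integer_, n, ncol(gt), dimnames = dimnames(gt))
  }
  dp <- as.matrix(dp)
  storage.mode(dp) <- "integer"
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  is_indel <- nchar(ref) != 1L |
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(a) any(nchar(a) != 1L), logical(1))
  tibble::tibble(
    chrom = unname(as.character(chrom)), pos = unname(as.integer(pos)),
    ref = unname(as.character(ref)), alt = unname(as.character(alt)),
    qual = rep_len(unname(as.numeric(qual)), n),
    qd = rep_len(unname(as.numeric(qd)), n),
    fs = rep_len(unname(as.numeric(fs)), n),
    mq = rep_len(unname(as.numeric(mq)), n),
    mq_rank_sum = rep_len(unname(as.numeric(mq_rank_sum)), n),
    read_pos_rank_sum = rep_len(unname(as.numeric(read_pos_rank_sum)), n),
    is_indel = unname(is_indel), gt = gt, dp = dp
  )
}

#' Sample identifiers of a site table
#' @param sites A site table.
#' @return Character vector of sample names.
#' @export
site_samples <- function(sites) colnames(sites$gt)

#' Alternate-allele dosage matrix
#'
#' Converts genotype strings to alternate-allele dosages 0/1/2 (diploid).
#' Genotypes containing a missing allele are `NA`; at multiallelic sites any
#' non-reference allele counts towards the dosage.
#'
#' @param sites A site table.
#' @return Numeric matrix (sites x samples), `NA` for missing genotypes.
#' @export
gt_dosage <- function(sites) {
  gt <- sites$gt
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- (a1 != "0") + (a2 != "0")
  d[a1 == "." | a2 == "."] <- NA
  dim(d) <- dim(gt)
  dimnames(d) <- dimnames(gt)
  d
}

# heterozygote indicator: TRUE where the two alleles differ, NA when missing
gt_is_het <- function(sites) {
  gt <- sites$gt
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  h <- a1 != a2
  h[a1 == "." | a2 == "."] <- NA
  dim(h) <- dim(gt)
  dimnames(h) <- dimnames(gt)
  h
}

# per-site total depth (sum over samples, missing depths count 0)
site_total_depth <- function(sites) {
  rowSums(sites$dp, na.rm = TRUE)
}

# row-bind two site tables (bind_rows drops matrix-column names)
bind_site_rows <- function(a, b) {
  stopifnot(identical(site_samples(a), site_samples(b)))
  cols <- lapply(names(a), function(col) {
    if (is.matrix(a[[col]])) rbind(a[[col]], b[[col]])
    else c(a[[col]], b[[col]])
  })
  names(cols) <- names(a)
  tibble::as_tibble(cols)
}

assert_sorted <- function(sites, what = "sites") {
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    stop(what, " must be sorted by (chrom, pos)", call. = FALSE)
  }
  invisible(sites)
}

#' Read a population assignment table
#'
#' Two-column tab-separated text, no header: sample identifier, population
#' label.
#'
#' @param path File path.
#' @return Tibble with columns `sample`, `population`.
#' @export
read_pop_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("sample", "population"),
                         colClasses = "character")
  tibble::as_tibble(x)
}

# resolve a population argument (character vector of samples, or a
# data.frame with sample/population) to sample names present in `sites`
resolve_pop <- function(sites, pop, population = NULL) {
  if (is.data.frame(pop)) {
    stopifnot(!is.null(population))
    pop <- pop$sample[pop$population == population]
  }
  pop <- as.character(pop)
  if (anyDuplicated(pop)) stop("duplicate sample in population", call. = FALSE)
  missing <- setdiff(pop, site_samples(sites))
  if (length(missing)) {
    stop("samples not in site table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pop
}
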