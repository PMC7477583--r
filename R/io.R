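#' Read a VCF file into a site table
#'
#' Parses a VCF 4.x file (GT and DP FORMAT fields expected) into the
#' package's site-table representation. INFO annotations QD, FS, MQ,
#' MQRankSum and ReadPosRankSum are extracted when present; an annotation
#' absent from a record is `NA`, never zero — the distinction matters for
#' the hard filter, where absent annotations do not fail their condition.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param sample_subset Optional character vector restricting the samples
#'   (and their column order); an unknown sample is an error.
#' @return A site table in file order; see [site_table()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    samples <- colnames(v@gt)[-1]
    if (is.null(samples)) samples <- character()
    gt <- matrix(character(), 0, length(samples),
                 dimnames = list(NULL, samples))
    return(site_table(character(), integer(), character(), character(), gt))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record at data line ", which(is.na(pos))[1],
         ": non-numeric POS", call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, samples)
    if (length(unknown)) {
      stop("requested sample(s) not in VCF header: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    samples <- sample_subset
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  gt[is.na(gt)] <- "./."
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  )[, samples, drop = FALSE]
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  site_table(
    chrom = fix[, "CHROM"], pos = pos, ref = fix[, "REF"],
    alt = ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
    gt = unname_dim(gt, samples), dp = unname_dim(dp, samples),
    qual = qual,
    qd = info_num("QD"), fs = info_num("FS"), mq = info_num("MQ"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum")
  )
}

unname_dim <- function(m, samples) {
  rownames(m) <- NULL
  colnames(m) <- samples
  m
}

#' Write a site table as VCF
#'
#' Emits an uncompressed VCF 4.2 file with GT:DP FORMAT columns and the
#' five INFO annotations the filter cascade reads. Reading the file back
#' with [read_vcf()] reproduces the table field-for-field for the
#' supported fields.
#'
#' @param sites A site table sorted by (chrom, pos).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path) {
  assert_sorted(sites)
  samples <- site_samples(sites)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    paste0("##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,",
           "Description=\"Read position rank sum\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (nrow(sites) > 0) {
    fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g",
                                                        digits = 15))
    info_keys <- c(QD = "qd", FS = "fs", MQ = "mq",
                   MQRankSum = "mq_rank_sum",
                   ReadPosRankSum = "read_pos_rank_sum")
    info_cols <- lapply(seq_along(info_keys), function(i) {
      v <- fmt_num(sites[[info_keys[i]]])
      ifelse(is.na(v), NA, paste0(names(info_keys)[i], "=", v))
    })
    info <- apply(do.call(cbind, info_cols), 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) paste(r, collapse = ";") else "."
    })
    dp_chr <- sites$dp
    dp_chr <- ifelse(is.na(dp_chr), ".", as.character(dp_chr))
    dim(dp_chr) <- dim(sites$dp)
    cells <- matrix(paste(sites$gt, dp_chr, sep = ":"),
                    nrow = nrow(sites))
    lines <- paste(
      sites$chrom, sites$pos, ".", sites$ref,
      ifelse(nzchar(sites$alt), sites$alt, "."),
      ifelse(is.na(sites$qual), ".", fmt_num(sites$qual)),
      ".", info, "GT:DP",
      apply(cells, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Only rows of type `gene` are retained; the gene identifier is taken from
#' the `ID=` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   sorted by (chrom, start). Coordinates are 1-based inclusive.
#' @export
read_gff_genes <- function(path) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          gene_id = character())
  raw <- readLines(path)
  if (!any(nzchar(raw) & !startsWith(raw, "#"))) return(empty)
  g <- ape::read.gff(path)
  bad <- which(g$end < g$start)
  if (length(bad)) {
    stop("GFF record with end < start at data row ", bad[1], call. = FALSE)
  }
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  gene_id <- sub(".*ID=([^;]+).*", "\\1", as.character(g$attributes))
  out <- tibble::tibble(chrom = as.character(g$seqid),
                        start = as.integer(g$start),
                        end = as.integer(g$end),
                        strand = as.character(g$strand),
                        gene_id = gene_id)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write scored intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' the written start is `start - 1` and the end is unchanged. Input row
#' order is preserved.
#'
#' @param regions Data frame with columns `chrom`, `start`, `end` and
#'   optionally `score`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(regions) > 0) {
    lines <- paste(regions$chrom, regions$start - 1L, regions$end,
                   sep = "\t")
    if (!is.null(regions[["score"]])) {
      lines <- paste(lines, regions[["name"]] %||% ".", regions[["score"]],
                     sep = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BED file of scored intervals
#'
#' Inverse of [write_bed()]: BED's 0-based half-open coordinates are
#' converted back to the package's 1-based inclusive convention
#' (`start + 1`, end unchanged), making the round trip an exact bijection.
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`
#'   and `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble::tibble(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)) + 1L,
    end = as.integer(vapply(parts, `[`, "", 3L))
  )
  if (all(lengths(parts) >= 5L)) {
    out$name <- vapply(parts, `[`, "", 4L)
    out$score <- as.numeric(vapply(parts, `[`, "", 5L))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
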