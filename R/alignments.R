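#' @importFrom tibble tibble as_tibble
NULL

SEGMENT_COLS <- c("read_id", "chrom", "ref_start", "ref_end", "strand",
                  "mapq", "read_start", "read_end", "read_length",
                  "n_match", "n_mismatch", "n_ins", "n_del", "is_primary")

#' Construct/validate a segment table
#'
#' The package's central container is a plain tibble with one row per aligned
#' segment. Coordinates are 1-based inclusive on both the reference
#' (`ref_start`, `ref_end`) and the read in its original sequencer
#' orientation (`read_start`, `read_end`).
#'
#' @param df A data frame with the segment columns.
#' @param contigs Optional named vector of contig lengths, kept as an
#'   attribute.
#' @return A tibble of class `bnd_segments`.
#' @export
as_segments <- function(df, contigs = NULL) {
  missing_cols <- setdiff(SEGMENT_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("segment table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- as_tibble(df)[, SEGMENT_COLS]
  bad <- df$ref_start > df$ref_end | df$read_start > df$read_end
  if (any(bad))
    stop("segment table has inverted intervals at rows ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  span <- df$ref_end - df$ref_start + 1
  tal <- df$n_match + df$n_mismatch + df$n_del
  if (any(tal != span))
    stop("match/mismatch/del tallies do not sum to the reference span",
         call. = FALSE)
  df <- df[order(df$read_id, df$read_start), ]
  if (!is.null(contigs)) attr(df, "contigs") <- contigs
  class(df) <- unique(c("bnd_segments", class(df)))
  df
}

#' Contig lengths recorded with a segment table
#' @param x A `bnd_segments` tibble.
#' @return Named numeric vector of contig lengths (possibly `NULL`).
#' @export
contigs <- function(x) attr(x, "contigs")

# Convert a SAM to a sorted, indexed BAM in the session temp dir; pass BAMs
# through (indexing them next to a temp copy if no index is present).
prepare_bam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = TRUE))
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    dest <- tempfile(fileext = "")
    srt <- Rsamtools::sortBam(path, dest)
    Rsamtools::indexBam(srt)
    return(srt)
  }
  path
}

#' Read long-read alignments into a segment table
#'
#' Parses a SAM or BAM file into one row per aligned segment, grouping
#' primary and SA-linked supplementary records by read name. Unmapped and
#' secondary records are excluded. Read-orientation coordinates are derived
#' from the CIGAR including soft/hard clips, so that supplementary segments
#' of a chimeric read can be ordered along the read. Match/mismatch/indel
#' tallies come from `=`/`X` CIGAR operators when present, otherwise from the
#' `NM` tag.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param cfg A [bnd_config()]; only used for validation here — filtering
#'   happens downstream so that QC sees everything.
#' @param region Optional `GRanges` restricting the scan (BAM only).
#' @return A `bnd_segments` tibble (see [as_segments()]) carrying contig
#'   lengths from the header as an attribute.
#' @export
read_alignments <- function(path, cfg = bnd_config(), region = NULL) {
  cfg <- as_bnd_config(cfg)
  bam <- prepare_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  ctg <- hdr$targets
  if (is.null(ctg) || length(ctg) == 0L)
    stop("alignment file has no @SQ header lines: ", path, call. = FALSE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(flag = flag, what = what, tag = "NM")
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = what, tag = "NM",
                            which = region)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  rec <- list(
    qname = unlist(lapply(res, `[[`, "qname"), use.names = FALSE),
    flag = unlist(lapply(res, `[[`, "flag"), use.names = FALSE),
    rname = as.character(unlist(lapply(res, function(x)
      as.character(x$rname)), use.names = FALSE)),
    strand = as.character(unlist(lapply(res, function(x)
      as.character(x$strand)), use.names = FALSE)),
    pos = unlist(lapply(res, `[[`, "pos"), use.names = FALSE),
    mapq = unlist(lapply(res, `[[`, "mapq"), use.names = FALSE),
    cigar = unlist(lapply(res, `[[`, "cigar"), use.names = FALSE),
    nm = unlist(lapply(res, function(x) {
      v <- x$tag$NM
      if (is.null(v)) rep(NA_integer_, length(x$qname)) else v
    }), use.names = FALSE)
  )
  n <- length(rec$qname)
  if (n == 0L) {
    empty <- tibble(read_id = character(), chrom = character(),
                    ref_start = numeric(), ref_end = numeric(),
                    strand = character(), mapq = integer(),
                    read_start = numeric(), read_end = numeric(),
                    read_length = numeric(), n_match = numeric(),
                    n_mismatch = numeric(), n_ins = numeric(),
                    n_del = numeric(), is_primary = logical())
    return(as_segments(empty, contigs = ctg))
  }
  if (!all(rec$rname %in% names(ctg)))
    stop("record references a chromosome absent from the header",
         call. = FALSE)

  ops <- GenomicAlignments::explodeCigarOps(rec$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(rec$cigar)
  per <- function(f) vapply(seq_len(n), f, numeric(1))
  sum_ops <- function(which_ops) {
    per(function(i) sum(lens[[i]][ops[[i]] %in% which_ops]))
  }
  lead_clip <- per(function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    k <- 0L; tot <- 0
    while (k < length(o) && o[k + 1L] %in% c("H", "S")) {
      k <- k + 1L; tot <- tot + l[k]
    }
    tot
  })
  trail_clip <- per(function(i) {
    o <- rev(ops[[i]]); l <- rev(lens[[i]])
    k <- 0L; tot <- 0
    while (k < length(o) && o[k + 1L] %in% c("H", "S")) {
      k <- k + 1L; tot <- tot + l[k]
    }
    tot
  })
  qw <- sum_ops(c("M", "I", "=", "X"))
  ref_w <- sum_ops(c("M", "D", "N", "=", "X"))
  n_ins <- sum_ops("I")
  n_del <- sum_ops(c("D", "N"))
  n_eq <- sum_ops("=")
  n_x <- sum_ops("X")
  n_m <- sum_ops("M")

  has_eqx <- vapply(seq_len(n), function(i) any(ops[[i]] %in% c("=", "X")),
                    logical(1))
  nm <- ifelse(is.na(rec$nm), n_ins + n_del, rec$nm)
  mism <- ifelse(has_eqx, n_x, pmax(0, nm - n_ins - n_del))
  mism <- pmin(mism, n_m + n_x)
  match <- n_m + n_eq + n_x - mism

  read_length <- lead_clip + qw + trail_clip
  fwd <- rec$strand != "-"
  read_start <- ifelse(fwd, lead_clip + 1, trail_clip + 1)
  read_end <- read_start + qw - 1

  seg <- tibble(
    read_id = rec$qname,
    chrom = rec$rname,
    ref_start = as.numeric(rec$pos),
    ref_end = as.numeric(rec$pos) + ref_w - 1,
    strand = ifelse(fwd, "+", "-"),
    mapq = as.integer(rec$mapq),
    read_start = read_start,
    read_end = read_end,
    read_length = read_length,
    n_match = match,
    n_mismatch = mism,
    n_ins = n_ins,
    n_del = n_del,
    is_primary = !bitwAnd(rec$flag, 2048L)
  )
  as_segments(seg, contigs = ctg)
}

#' BLAST-style alignment identity of a segment
#'
#' Identity is matches over all alignment columns, counting gap columns in
#' the denominator: `n_match / (n_match + n_mismatch + n_ins + n_del)`.
#'
#' @param n_match,n_mismatch,n_ins,n_del Base tallies (vectorized). A
#'   `bnd_segments` tibble may be given as the first argument instead.
#' @return Numeric vector of identities in `[0, 1]`.
#' @examples
#' segment_identity(85, 5, 5, 5)
#' @export
segment_identity <- function(n_match, n_mismatch = NULL, n_ins = NULL,
                             n_del = NULL) {
  if (is.data.frame(n_match)) {
    df <- n_match
    return(segment_identity(df$n_match, df$n_mismatch, df$n_ins, df$n_del))
  }
  denom <- n_match + n_mismatch + n_ins + n_del
  if (any(denom == 0))
    stop("identity undefined: all tallies are zero", call. = FALSE)
  n_match / denom
}

#' Read-length N50
#'
#' The length at which the descending cumulative sum of read lengths first
#' reaches half the total: reads at least this long comprise at least half
#' of the sequenced bases.
#'
#' @param lengths Numeric vector of read lengths (bases), all positive.
#' @return A single length (bases).
#' @examples
#' read_length_n50(c(10, 20, 30))
#' @export
read_length_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("read lengths must be positive", call. = FALSE)
  ls <- sort(lengths, decreasing = TRUE)
  ls[which(cumsum(ls) >= sum(ls) / 2)[1]]
}

# IRanges of N-runs per contig of a DNAStringSet.
n_run_ranges <- function(ref) {
  lapply(seq_along(ref), function(i) {
    m <- Biostrings::matchPattern("N", ref[[i]], fixed = TRUE)
    IRanges::reduce(methods::as(m, "IRanges"))
  }) |> stats::setNames(names(ref))
}

#' Per-sample quality-control summary
#'
#' Computes read-count, length, identity, depth and breadth-of-coverage
#' statistics from a segment table. Depth and coverage rate use the non-N
#' reference length as denominator, since assembly gaps cannot be covered.
#'
#' @param segments A `bnd_segments` tibble.
#' @param ref Reference genome as a `DNAStringSet` (used for contig lengths
#'   and N-run masking). Alternatively a named vector of contig lengths, in
#'   which case the genome is assumed N-free.
#' @return A list of class `bnd_qc` with fields `n_reads`, `n_mapped_bases`,
#'   `mean_len`, `median_len`, `n50`, `mean_identity`, `median_identity`,
#'   `depth`, `coverage_rate`, and `no_reads` (warning flag).
#' @export
qc_summary <- function(segments, ref) {
  if (methods::is(ref, "DNAStringSet")) {
    ctg <- stats::setNames(Biostrings::width(ref), names(ref))
    nruns <- n_run_ranges(ref)
    n_bases_N <- sum(vapply(nruns, function(r) sum(IRanges::width(r)),
                            numeric(1)))
  } else {
    ctg <- ref
    nruns <- NULL
    n_bases_N <- 0
  }
  non_n <- sum(ctg) - n_bases_N
  if (non_n <= 0) stop("non-N reference length must be positive",
                       call. = FALSE)
  if (nrow(segments) == 0L) {
    out <- list(n_reads = 0L, n_mapped_bases = 0, mean_len = 0,
                median_len = 0, n50 = 0, mean_identity = NA_real_,
                median_identity = NA_real_, depth = 0, coverage_rate = 0,
                no_reads = TRUE)
    class(out) <- "bnd_qc"
    warning("qc_summary: zero mapped reads", call. = FALSE)
    return(out)
  }
  per_read <- segments[!duplicated(segments$read_id), ]
  lens <- per_read$read_length
  prim <- segments[segments$is_primary, ]
  idents <- segment_identity(prim)
  aligned <- sum(segments$ref_end - segments$ref_start + 1)

  gr <- GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(segments$ref_start, segments$ref_end),
    seqlengths = ctg)
  red <- GenomicRanges::reduce(gr)
  if (!is.null(nruns)) {
    ngr <- GenomicRanges::GRanges(
      rep(names(nruns), vapply(nruns, length, integer(1))),
      unlist(IRanges::IRangesList(nruns), use.names = FALSE),
      seqlengths = ctg)
    red <- GenomicRanges::setdiff(red, ngr)
  }
  covered <- sum(GenomicRanges::width(red))

  out <- list(
    n_reads = length(lens),
    n_mapped_bases = sum(lens),
    mean_len = mean(lens),
    median_len = stats::median(lens),
    n50 = read_length_n50(lens),
    mean_identity = mean(idents),
    median_identity = stats::median(idents),
    depth = aligned / non_n,
    coverage_rate = covered / non_n,
    no_reads = FALSE
  )
  class(out) <- "bnd_qc"
  out
}

#' @export
print.bnd_qc <- function(x, ...) {
  cat("QC summary\n")
  cat(sprintf("  reads             %d\n", x$n_reads))
  cat(sprintf("  mapped bases      %.0f\n", x$n_mapped_bases))
  cat(sprintf("  mean / median len %.0f / %.0f bases\n", x$mean_len,
              x$median_len))
  cat(sprintf("  read N50          %.0f bases\n", x$n50))
  cat(sprintf("  identity (mean)   %.3f\n", x$mean_identity))
  cat(sprintf("  depth             %.2fx (non-N denominator)\n", x$depth))
  cat(sprintf("  coverage rate     %.2f%% of non-N genome\n",
              100 * x$coverage_rate))
  invisible(x)
}

#' One-row QC table
#'
#' @param qc A `bnd_qc` object from [qc_summary()].
#' @param sample Sample label for the first column.
#' @return A one-row tibble with depth, read counts, mapped bases, and
#'   coverage rate (percent, non-N denominator).
#' @export
qc_table <- function(qc, sample = "sample") {
  tibble(sample = sample,
         depth_x = round(qc$depth, 2),
         n_mapped_reads = qc$n_reads,
         n_mapped_bases = qc$n_mapped_bases,
         coverage_rate_pct = round(100 * qc$coverage_rate, 2),
         mean_len = round(qc$mean_len),
         median_len = round(qc$median_len),
         read_n50 = qc$n50,
         mean_identity = round(qc$mean_identity, 4),
         median_identity = round(qc$median_identity, 4))
}
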