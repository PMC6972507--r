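#' @importFrom stats median setNames
NULL

# Orientation encoding: each breakend carries a side. "end" means the retained
# sequence runs up to and including the breakend base (partner joins after
# it); "start" means the retained sequence resumes at the breakend base
# (partner joins before it). In the two-character orientation string an "end"
# side prints '+' and a "start" side prints '-'. A canonical reciprocal
# translocation therefore yields one "+-" and one "-+" junction; an inversion
# yields "++" and "--".
side_to_char <- function(side) ifelse(side == "end", "+", "-")

EVIDENCE_COLS <- c("read_id", "chrom1", "pos1", "side1", "chrom2", "pos2",
                   "side2", "orientation", "svclass", "read_gap",
                   "min_mapq", "min_identity")

#' Candidate split pairs of one read
#'
#' Filters a read's segments by mapping quality and aligned length, then
#' emits every pair of segments adjacent in read order. Reads with more than
#' two segments yield one pair per adjacency. Segments may overlap on the
#' read by up to half the shorter segment, absorbing aligner jitter at
#' junctions; larger overlaps break the adjacency.
#'
#' @param ra Segment table rows of a single read (ordered or not).
#' @param cfg A [bnd_config()].
#' @return A list of two-row tibbles (`seg_a`, `seg_b` stacked); empty list
#'   when no pair survives.
#' @export
split_candidates <- function(ra, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  if (length(unique(ra$read_id)) > 1L)
    stop("split_candidates expects segments of a single read", call. = FALSE)
  len <- ra$read_end - ra$read_start + 1
  keep <- ra$mapq >= cfg$min_mapq & len >= cfg$min_segment_len
  ra <- ra[keep, , drop = FALSE]
  if (nrow(ra) < 2L) return(list())
  ra <- ra[order(ra$read_start, ra$read_end), ]
  out <- list()
  for (i in seq_len(nrow(ra) - 1L)) {
    a <- ra[i, ]
    b <- ra[i + 1L, ]
    overlap <- a$read_end - b$read_start + 1
    shorter <- min(a$read_end - a$read_start, b$read_end - b$read_start) + 1
    if (overlap <= 0.5 * shorter) out[[length(out) + 1L]] <- rbind(a, b)
  }
  out
}

#' Junction evidence from one split pair
#'
#' The breakend contributed by the read-proximal segment (`seg_a`) sits at
#' its read-distal reference end: `ref_end` on the plus strand, `ref_start`
#' on the minus strand. The read-distal segment (`seg_b`) contributes its
#' read-proximal reference end. Unaligned read bases between the two segments
#' (`read_gap`) measure inserted sequence at the junction. Breakends are
#' canonicalized so that breakend 1 sorts before breakend 2 by (chrom, pos).
#'
#' @param sp A two-row segment tibble from [split_candidates()].
#' @return One-row evidence tibble with columns
#'   `r paste(EVIDENCE_COLS, collapse = ", ")`.
#' @export
junction_from_pair <- function(sp) {
  stopifnot(nrow(sp) == 2L)
  a <- sp[1, ]
  b <- sp[2, ]
  if (a$read_start > b$read_start) { tmp <- a; a <- b; b <- tmp }
  pos_a <- if (a$strand == "+") a$ref_end else a$ref_start
  side_a <- if (a$strand == "+") "end" else "start"
  pos_b <- if (b$strand == "+") b$ref_start else b$ref_end
  side_b <- if (b$strand == "+") "start" else "end"
  read_gap <- max(0, b$read_start - a$read_end - 1)
  svclass <- if (a$chrom != b$chrom) {
    "translocation"
  } else if (a$strand != b$strand) {
    "inversion"
  } else {
    "intra_other"
  }
  ev <- tibble::tibble(
    read_id = a$read_id,
    chrom1 = a$chrom, pos1 = pos_a, side1 = side_a,
    chrom2 = b$chrom, pos2 = pos_b, side2 = side_b,
    orientation = paste0(side_to_char(side_a), side_to_char(side_b)),
    svclass = svclass,
    read_gap = read_gap,
    min_mapq = min(a$mapq, b$mapq),
    min_identity = min(segment_identity(a), segment_identity(b))
  )
  canonicalize_evidence(ev)
}

canonicalize_evidence <- function(ev) {
  flip <- ev$chrom2 < ev$chrom1 |
    (ev$chrom2 == ev$chrom1 & ev$pos2 < ev$pos1)
  if (any(flip)) {
    sw <- ev[flip, ]
    ev[flip, c("chrom1", "pos1", "side1")] <-
      sw[, c("chrom2", "pos2", "side2")]
    ev[flip, c("chrom2", "pos2", "side2")] <-
      sw[, c("chrom1", "pos1", "side1")]
    ev$orientation[flip] <- paste0(side_to_char(ev$side1[flip]),
                                   side_to_char(ev$side2[flip]))
  }
  ev
}

#' Extract all split-read evidence from a segment table
#'
#' Runs [split_candidates()] and [junction_from_pair()] over every read.
#'
#' @param segments A `bnd_segments` tibble.
#' @param cfg A [bnd_config()].
#' @return Evidence tibble, zero rows when no read is split.
#' @export
split_read_evidence <- function(segments, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  empty <- tibble::tibble(
    read_id = character(), chrom1 = character(), pos1 = numeric(),
    side1 = character(), chrom2 = character(), pos2 = numeric(),
    side2 = character(), orientation = character(), svclass = character(),
    read_gap = numeric(), min_mapq = numeric(), min_identity = numeric())
  if (nrow(segments) == 0L) return(empty)
  # restrict to reads with >= 2 segments before the per-read loop
  tab <- table(segments$read_id)
  multi <- names(tab)[tab >= 2L]
  if (length(multi) == 0L) return(empty)
  segments <- segments[segments$read_id %in% multi, ]
  by_read <- split(segments, segments$read_id)
  pieces <- lapply(by_read, function(ra) {
    pairs <- split_candidates(ra, cfg)
    if (length(pairs) == 0L) return(NULL)
    do.call(rbind, lapply(pairs, junction_from_pair))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Filter junction evidence by event class
#'
#' Translocation evidence always passes. Intra-chromosomal evidence must span
#' at least `min_sv_len` bases: same-strand pairs below that are typical
#' alignment artifacts at indels, and tiny inversions are unresolvable at
#' nanopore error rates.
#'
#' @param evidence Evidence tibble from [split_read_evidence()].
#' @param cfg A [bnd_config()].
#' @return The tibble with a logical `pass` column added.
#' @export
classify_evidence <- function(evidence, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  span <- ifelse(evidence$chrom1 == evidence$chrom2,
                 abs(evidence$pos2 - evidence$pos1), Inf)
  evidence$pass <- evidence$svclass == "translocation" | span >= cfg$min_sv_len
  evidence
}

#' Write evidence as a debugging TSV
#' @param evidence Evidence tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_evidence_tsv <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
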