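#' Windowed read counts
#'
#' Partitions each contig into consecutive non-overlapping windows of
#' `cnv_window` bases (the last window of a contig may be shorter) and counts
#' each read once, in the window containing the alignment start of its
#' primary segment — a partition, so window counts sum to the number of
#' reads. Windows with less than half non-N sequence are masked.
#'
#' @param segments A `bnd_segments` tibble.
#' @param ref Reference `DNAStringSet`, or a named vector of contig lengths
#'   (then assumed N-free).
#' @param cfg A [bnd_config()].
#' @return Tibble with `chrom`, `window_index`, `start`, `end` (1-based
#'   inclusive), `n_reads`, `n_frac`, `masked`.
#' @export
window_counts <- function(segments, ref, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  w <- cfg$cnv_window
  if (methods::is(ref, "DNAStringSet")) {
    ctg <- stats::setNames(as.numeric(Biostrings::width(ref)), names(ref))
  } else {
    ctg <- ref
  }
  prim <- segments[segments$is_primary, ]
  out <- list()
  for (ch in names(ctg)) {
    len <- ctg[[ch]]
    n_win <- ceiling(len / w)
    starts <- (seq_len(n_win) - 1) * w + 1
    ends <- pmin(starts + w - 1, len)
    pos <- prim$ref_start[prim$chrom == ch]
    counts <- tabulate(pmin(floor((pos - 1) / w) + 1, n_win), nbins = n_win)
    if (methods::is(ref, "DNAStringSet")) {
      v <- Biostrings::Views(ref[[ch]], start = starts, end = ends)
      n_N <- Biostrings::letterFrequency(v, "N")[, 1]
      n_frac <- 1 - n_N / (ends - starts + 1)
    } else {
      n_frac <- rep(1, n_win)
    }
    out[[ch]] <- tibble::tibble(chrom = ch, window_index = seq_len(n_win),
                                start = starts, end = ends, n_reads = counts,
                                n_frac = n_frac, masked = n_frac < 0.5)
  }
  do.call(rbind, out)
}

#' No-control log2 normalization of window counts
#'
#' Each unmasked window's count is expressed as a log2 ratio to the
#' sample-wide median count, with a 0.5 pseudo-count on both sides so sparse
#' windows stay finite: `log2((count + 0.5) / (median + 0.5))`.
#'
#' @param counts Tibble from [window_counts()].
#' @return The tibble with a `log2_ratio` column (`NA` for masked windows).
#' @export
normalize_log2 <- function(counts) {
  ok <- !counts$masked
  if (!any(ok)) stop("all windows are masked", call. = FALSE)
  med <- stats::median(counts$n_reads[ok])
  counts$log2_ratio <- ifelse(ok, log2((counts$n_reads + 0.5) / (med + 0.5)),
                              NA_real_)
  counts
}

# Local changepoint polish on raw window counts: the split index (first
# window of the right stretch) maximizing the two-rate Poisson likelihood
# over [lo, hi], with rates estimated from the segment cores.
refine_boundary <- function(counts, lo, hi, b, lam_l, lam_r, radius = 20L) {
  lo <- max(lo, b - radius)
  hi <- min(hi, b + radius)
  if (lo >= hi || lam_l == lam_r) return(b)
  cand <- lo:hi
  ll <- vapply(cand, function(c) {
    left <- counts[lo:(c - 1)][seq_len(max(0, c - lo))]
    right <- counts[c:hi]
    sum(stats::dpois(left, lam_l, log = TRUE), na.rm = TRUE) +
      sum(stats::dpois(right, lam_r, log = TRUE), na.rm = TRUE)
  }, numeric(1))
  cand[which.max(ll)]
}

#' Greedy segmentation of window log2 ratios
#'
#' The per-window log2 track is first smoothed with a running median of
#' `smooth_windows` windows, which suppresses the Poisson jitter of ~10-read
#' window counts. Consecutive windows on the same side of the
#' `cnv_log2_thresh` band then merge into runs; non-neutral runs shorter than
#' `cnv_min_windows` fold into the neutral background, and neutral gaps
#' between two runs of the same sign are bridged when shorter than
#' `cnv_min_windows` or than a quarter of the shorter flanking run. Finally
#' the boundaries of non-neutral segments are polished against the raw
#' (unsmoothed) ratios with a local least-squares changepoint fit, undoing
#' the edge blur of the median filter.
#'
#' @param counts Tibble from [normalize_log2()].
#' @param cfg A [bnd_config()].
#' @param smooth_windows Running-median width (odd; 1 disables smoothing).
#'   Default 15.
#' @return Tibble of segments: `chrom`, `first_window`, `last_window`,
#'   `n_windows`, `start`, `end`, `mean_log2` (of the raw ratios), `state`
#'   (gain/loss/neutral).
#' @export
segment_ratios <- function(counts, cfg = bnd_config(), smooth_windows = 15L) {
  cfg <- as_bnd_config(cfg)
  th <- cfg$cnv_log2_thresh
  out <- list()
  for (chdf in split(counts, counts$chrom)) {
    chdf <- chdf[order(chdf$window_index), ]
    raw <- chdf$log2_ratio
    sm <- raw
    ok <- !is.na(sm)
    if (smooth_windows > 1L && sum(ok) >= 3L) {
      k <- min(smooth_windows, sum(ok))
      if (k %% 2L == 0L) k <- k - 1L
      sm[ok] <- stats::runmed(sm[ok], k, endrule = "median")
    }
    state <- ifelse(is.na(sm), 0L,
                    ifelse(sm > th, 1L, ifelse(sm < -th, -1L, 0L)))
    r <- rle(state)
    # fold short non-neutral runs into the background
    r$values[r$values != 0L & r$lengths < cfg$cnv_min_windows] <- 0L
    # bridge neutral gaps flanked by runs of the same sign, but only when
    # the combined stretch still clears the threshold on average — genuine
    # events keep their amplitude across a noisy gap, chance runs do not
    repeat {
      merged <- FALSE
      if (length(r$values) >= 3L) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k2 in 2:(length(r$values) - 1L)) {
          flank <- min(r$lengths[k2 - 1L], r$lengths[k2 + 1L])
          if (r$values[k2] != 0L ||
              r$values[k2 - 1L] != r$values[k2 + 1L] ||
              r$values[k2 - 1L] == 0L) next
          if (r$lengths[k2] >= cfg$cnv_min_windows &&
              r$lengths[k2] > flank / 4) next
          comb <- mean(raw[starts[k2 - 1L]:ends[k2 + 1L]], na.rm = TRUE)
          if (r$values[k2 - 1L] * comb > th) {
            r$values[k2] <- r$values[k2 - 1L]
            merged <- TRUE
          }
        }
      }
      if (!merged) break
      r <- rle(inverse.rle(r))
    }
    r2 <- r
    idx_end <- cumsum(r2$lengths)
    idx_start <- idx_end - r2$lengths + 1
    # polish non-neutral segment edges on the raw counts; Poisson rates are
    # estimated from segment cores, excluding the polish radius around the
    # boundary, so a misplaced smoothed edge cannot contaminate them
    cts <- ifelse(chdf$masked, NA_real_, as.numeric(chdf$n_reads))
    radius <- 20L
    # neutral rate = the sample median count (the definition of neutral in
    # no-control mode); CNV rates come from the segment core
    lam_neutral <- max(stats::median(cts, na.rm = TRUE), 0.1)
    core_lam <- function(s, e) {
      if (e < s) return(NA_real_)
      max(mean(cts[s:e], na.rm = TRUE), 0.1)
    }
    seg_lam_at <- function(k, b, side) {
      if (r2$values[k] == 0L) return(lam_neutral)
      lam <- if (side == "left")
        core_lam(idx_start[k], min(idx_end[k], b - radius - 1L))
      else
        core_lam(max(idx_start[k], b + radius), idx_end[k])
      if (is.na(lam) || is.nan(lam)) lam <- core_lam(idx_start[k], idx_end[k])
      lam
    }
    n_seg <- length(r2$values)
    if (n_seg >= 2L) {
      for (k in seq_len(n_seg)) {
        if (r2$values[k] == 0L) next
        if (k > 1L && r2$values[k - 1L] == 0L) {
          b0 <- idx_start[k]
          b <- refine_boundary(cts, idx_start[k - 1L] + 1L, idx_end[k],
                               b0, seg_lam_at(k - 1L, b0, "left"),
                               seg_lam_at(k, b0, "right"), radius)
          idx_end[k - 1L] <- b - 1L
          idx_start[k] <- b
        }
        if (k < n_seg && r2$values[k + 1L] == 0L) {
          b0 <- idx_end[k] + 1L
          b <- refine_boundary(cts, idx_start[k] + 1L, idx_end[k + 1L],
                               b0, seg_lam_at(k, b0, "left"),
                               seg_lam_at(k + 1L, b0, "right"), radius)
          idx_end[k] <- b - 1L
          idx_start[k + 1L] <- b
        }
      }
      # polish can shrink a spurious run below the minimum; fold it back
      r2$values[r2$values != 0L &
                  (idx_end - idx_start + 1L) < cfg$cnv_min_windows] <- 0L
    }
    seg <- tibble::tibble(
      chrom = chdf$chrom[1],
      first_window = chdf$window_index[idx_start],
      last_window = chdf$window_index[idx_end],
      n_windows = idx_end - idx_start + 1L,
      start = chdf$start[idx_start],
      end = chdf$end[idx_end],
      mean_log2 = vapply(seq_along(idx_start), function(k)
        mean(raw[idx_start[k]:idx_end[k]], na.rm = TRUE), numeric(1)),
      state = c("loss", "neutral", "gain")[r2$values + 2L])
    out[[length(out) + 1L]] <- seg
  }
  do.call(rbind, out)
}

#' Copy-number calls from segments
#'
#' Non-neutral segments meeting the minimum size become calls, with direction
#' from the sign of the mean log2 ratio.
#'
#' @param segments Tibble from [segment_ratios()].
#' @param cfg A [bnd_config()].
#' @param min_size Minimum call size in bases; defaults to
#'   `cnv_min_windows * cnv_window`.
#' @return Tibble: `chrom`, `start`, `end`, `direction`, `mean_log2`, `size`.
#' @export
call_cnvs <- function(segments, cfg = bnd_config(), min_size = NULL) {
  cfg <- as_bnd_config(cfg)
  if (is.null(min_size)) min_size <- cfg$cnv_min_windows * cfg$cnv_window
  sel <- segments$state != "neutral" &
    (segments$end - segments$start + 1) >= min_size
  seg <- segments[sel, ]
  tibble::tibble(chrom = seg$chrom, start = seg$start, end = seg$end,
                 direction = ifelse(seg$state == "gain", "gain", "loss"),
                 mean_log2 = seg$mean_log2,
                 size = seg$end - seg$start + 1)
}

#' Run the read-depth CNV stage
#'
#' @param segments A `bnd_segments` tibble.
#' @param ref Reference `DNAStringSet` or named contig lengths.
#' @param cfg A [bnd_config()].
#' @return List with `windows` (normalized counts), `segments`, `calls`.
#' @export
run_cnv <- function(segments, ref, cfg = bnd_config()) {
  counts <- normalize_log2(window_counts(segments, ref, cfg))
  seg <- segment_ratios(counts, cfg)
  list(windows = counts, segments = seg, calls = call_cnvs(seg, cfg))
}
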