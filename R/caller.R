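CALL_COLS <- c("call_id", "chrom1", "pos1", "ci1_lo", "ci1_hi", "side1",
               "chrom2", "pos2", "ci2_lo", "ci2_hi", "side2", "orientation",
               "svclass", "support", "read_ids", "median_insertion",
               "imprecise", "low_support", "source")

# lower-middle median: deterministic tie-break on even counts
lomedian <- function(x, w = NULL) {
  if (!is.null(w)) x <- rep(x, times = w)
  sort(x)[ceiling(length(x) / 2)]
}

empty_calls <- function() {
  tibble::tibble(call_id = character(), chrom1 = character(),
                 pos1 = numeric(), ci1_lo = numeric(), ci1_hi = numeric(),
                 side1 = character(), chrom2 = character(), pos2 = numeric(),
                 ci2_lo = numeric(), ci2_hi = numeric(), side2 = character(),
                 orientation = character(), svclass = character(),
                 support = integer(), read_ids = character(),
                 median_insertion = numeric(), imprecise = logical(),
                 low_support = logical(), source = character())
}

#' Single-linkage clustering of junction evidence
#'
#' Evidence is stratified by (chrom pair, orientation); within a stratum two
#' pieces of evidence link when *both* breakends lie within `cluster_tol` of
#' each other, and clusters are the connected components of that relation.
#' Opposite orientations are never merged, keeping the two junctions of a
#' reciprocal event separate even when their breakends are close.
#'
#' @param evidence Evidence tibble (see [split_read_evidence()]).
#' @param cfg A [bnd_config()].
#' @return List of evidence tibbles, one per cluster.
#' @export
cluster_evidence <- function(evidence, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  if (nrow(evidence) == 0L) return(list())
  tol <- cfg$cluster_tol
  strata <- paste(evidence$chrom1, evidence$chrom2, evidence$orientation,
                  sep = "\r")
  out <- list()
  for (str_ev in split(evidence, strata)) {
    n <- nrow(str_ev)
    ord <- order(str_ev$pos1)
    str_ev <- str_ev[ord, ]
    # union-find over pos1-sorted members; only a sliding window of
    # candidates can satisfy |dpos1| <= tol
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    if (n > 1L) {
      for (i in 2:n) {
        j <- i - 1L
        while (j >= 1L && str_ev$pos1[i] - str_ev$pos1[j] <= tol) {
          if (abs(str_ev$pos2[i] - str_ev$pos2[j]) <= tol) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
          }
          j <- j - 1L
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    out <- c(out, unname(split(str_ev, comp)))
  }
  out
}

#' Consensus breakend call from one evidence cluster
#'
#' The consensus position of each breakend is the (lower-middle) median of
#' the member breakends; the confidence interval spans the members' min/max
#' offsets. Support counts distinct reads. Calls below `min_support` are
#' flagged, not dropped.
#'
#' @param cluster One evidence tibble from [cluster_evidence()].
#' @param cfg A [bnd_config()].
#' @param call_id Identifier for the call.
#' @return One-row calls tibble.
#' @export
consensus_breakpoint <- function(cluster, cfg = bnd_config(),
                                 call_id = "BND1") {
  cfg <- as_bnd_config(cfg)
  stopifnot(nrow(cluster) >= 1L)
  p1 <- lomedian(cluster$pos1)
  p2 <- lomedian(cluster$pos2)
  reads <- unique(cluster$read_id)
  support <- length(reads)
  ci1 <- c(min(cluster$pos1) - p1, max(cluster$pos1) - p1)
  ci2 <- c(min(cluster$pos2) - p2, max(cluster$pos2) - p2)
  low <- support < cfg$min_support
  wide <- (ci1[2] - ci1[1]) > cfg$cluster_tol |
    (ci2[2] - ci2[1]) > cfg$cluster_tol
  tibble::tibble(
    call_id = call_id,
    chrom1 = cluster$chrom1[1], pos1 = p1, ci1_lo = ci1[1], ci1_hi = ci1[2],
    side1 = cluster$side1[which(cluster$pos1 == p1)[1]],
    chrom2 = cluster$chrom2[1], pos2 = p2, ci2_lo = ci2[1], ci2_hi = ci2[2],
    side2 = cluster$side2[which(cluster$pos2 == p2)[1]],
    orientation = cluster$orientation[1],
    svclass = names(sort(table(cluster$svclass), decreasing = TRUE))[1],
    support = support,
    read_ids = paste(reads, collapse = ","),
    median_insertion = lomedian(cluster$read_gap),
    imprecise = low | wide,
    low_support = low,
    source = "nanobnd"
  )
}

#' Call breakends from split-read evidence
#'
#' Convenience wrapper: filters evidence with [classify_evidence()], clusters
#' it, and builds one consensus call per cluster.
#'
#' @param evidence Evidence tibble.
#' @param cfg A [bnd_config()].
#' @return Calls tibble sorted by (chrom1, pos1), ids `BND0001`, ...
#' @export
call_breakpoints <- function(evidence, cfg = bnd_config()) {
  cfg <- as_bnd_config(cfg)
  evidence <- classify_evidence(evidence, cfg)
  evidence <- evidence[evidence$pass, ]
  clusters <- cluster_evidence(evidence, cfg)
  if (length(clusters) == 0L) return(empty_calls())
  calls <- do.call(rbind, lapply(seq_along(clusters), function(i)
    consensus_breakpoint(clusters[[i]], cfg, call_id = sprintf("BND%04d", i))))
  calls <- calls[order(calls$chrom1, calls$pos1, calls$chrom2, calls$pos2), ]
  calls$call_id <- sprintf("BND%04d", seq_len(nrow(calls)))
  calls
}

complementary_orientation <- c("+-" = "-+", "-+" = "+-",
                               "++" = "--", "--" = "++")

#' Pair reciprocal junctions and size the junction micro-indels
#'
#' Two junctions on the same chromosome pair with complementary orientations
#' and nearby breakends are the two derivatives of one reciprocal event. On
#' each chromosome, one junction carries the "stop" breakend (side `end`) and
#' the other the "resume" breakend (side `start`); the reciprocal gap
#' `(resume - 1) - stop` is the number of bases present in neither derivative
#' (positive: micro-deletion) or in both (negative: duplication).
#'
#' @param calls Calls tibble.
#' @param max_gap Maximum breakend distance (bases) for pairing. Default 1e6.
#' @return Tibble with one row per event: paired events carry both call ids,
#'   per-chromosome stop/resume positions and signed gaps; unpaired junctions
#'   are returned as singleton rows (`paired = FALSE`, gaps `NA`).
#'   `support_total` sums the spanning reads of the two derivative junctions:
#'   every chromosomal breakpoint of a reciprocal event participates in both
#'   derivatives, so this is the per-breakpoint spanning-read count reported
#'   for heterozygous carriers.
#' @export
pair_reciprocal <- function(calls, max_gap = 1e6) {
  n <- nrow(calls)
  if (n == 0L) {
    return(tibble::tibble(event_id = character(), call_id_1 = character(),
                          call_id_2 = character(), paired = logical(),
                          svclass = character(), chromA = character(),
                          stopA = numeric(), resumeA = numeric(),
                          gapA = numeric(), chromB = character(),
                          stopB = numeric(), resumeB = numeric(),
                          gapB = numeric(), support_total = numeric()))
  }
  used <- rep(FALSE, n)
  rows <- list()
  eid <- 0L
  # candidate partners, nearest first
  for (i in seq_len(n)) {
    if (used[i]) next
    comp <- complementary_orientation[[calls$orientation[i]]]
    cand <- which(!used & seq_len(n) != i &
                    calls$chrom1 == calls$chrom1[i] &
                    calls$chrom2 == calls$chrom2[i] &
                    calls$orientation == comp &
                    abs(calls$pos1 - calls$pos1[i]) <= max_gap &
                    abs(calls$pos2 - calls$pos2[i]) <= max_gap)
    eid <- eid + 1L
    if (length(cand) == 0L) {
      rows[[eid]] <- tibble::tibble(
        event_id = sprintf("EVT%03d", eid),
        call_id_1 = calls$call_id[i], call_id_2 = NA_character_,
        paired = FALSE, svclass = calls$svclass[i],
        chromA = calls$chrom1[i], stopA = NA_real_, resumeA = NA_real_,
        gapA = NA_real_, chromB = calls$chrom2[i], stopB = NA_real_,
        resumeB = NA_real_, gapB = NA_real_,
        support_total = as.numeric(calls$support[i]))
      used[i] <- TRUE
      next
    }
    d <- abs(calls$pos1[cand] - calls$pos1[i]) +
      abs(calls$pos2[cand] - calls$pos2[i])
    j <- cand[which.min(d)]
    used[i] <- used[j] <- TRUE
    gap_on <- function(side_i, pos_i, pos_j) {
      # side_i is call i's side on this chromosome; the partner has the
      # opposite side by complementarity
      if (side_i == "end") (pos_j - 1) - pos_i else (pos_i - 1) - pos_j
    }
    gA <- gap_on(calls$side1[i], calls$pos1[i], calls$pos1[j])
    gB <- gap_on(calls$side2[i], calls$pos2[i], calls$pos2[j])
    stopA <- if (calls$side1[i] == "end") calls$pos1[i] else calls$pos1[j]
    resumeA <- if (calls$side1[i] == "end") calls$pos1[j] else calls$pos1[i]
    stopB <- if (calls$side2[i] == "end") calls$pos2[i] else calls$pos2[j]
    resumeB <- if (calls$side2[i] == "end") calls$pos2[j] else calls$pos2[i]
    rows[[eid]] <- tibble::tibble(
      event_id = sprintf("EVT%03d", eid),
      call_id_1 = calls$call_id[i], call_id_2 = calls$call_id[j],
      paired = TRUE, svclass = calls$svclass[i],
      chromA = calls$chrom1[i], stopA = stopA, resumeA = resumeA, gapA = gA,
      chromB = calls$chrom2[i], stopB = stopB, resumeB = resumeB, gapB = gB,
      support_total = as.numeric(calls$support[i] + calls$support[j]))
  }
  do.call(rbind, rows)
}

#' Merge two breakend call sets
#'
#' Calls match when chromosome pair and orientation agree and both breakends
#' lie within `merge_tol`. Matched calls merge into one with the union of
#' supporting reads and a support-weighted (lower-middle) median position;
#' unmatched calls are retained tagged with their source. The operation is
#' commutative and idempotent at the level of (locus, mate, orientation,
#' read-id union).
#'
#' @param set1,set2 Calls tibbles.
#' @param merge_tol Maximum breakend distance (bases); defaults to the
#'   `merge_tol` of `cfg`.
#' @param cfg A [bnd_config()].
#' @param labels Length-2 character: source tags for unmatched calls.
#' @return Merged calls tibble.
#' @export
merge_callsets <- function(set1, set2, merge_tol = NULL, cfg = bnd_config(),
                           labels = c("set1", "set2")) {
  cfg <- as_bnd_config(cfg)
  if (is.null(merge_tol)) merge_tol <- cfg$merge_tol
  if (nrow(set1) == 0L && nrow(set2) == 0L) return(empty_calls())
  used2 <- rep(FALSE, nrow(set2))
  rows <- list()
  for (i in seq_len(nrow(set1))) {
    cand <- which(!used2 &
                    set2$chrom1 == set1$chrom1[i] &
                    set2$chrom2 == set1$chrom2[i] &
                    set2$orientation == set1$orientation[i] &
                    abs(set2$pos1 - set1$pos1[i]) <= merge_tol &
                    abs(set2$pos2 - set1$pos2[i]) <= merge_tol)
    if (length(cand) == 0L) {
      r <- set1[i, ]
      r$source <- labels[1]
      rows[[length(rows) + 1L]] <- r
      next
    }
    d <- abs(set2$pos1[cand] - set1$pos1[i]) +
      abs(set2$pos2[cand] - set1$pos2[i])
    j <- cand[which.min(d)]
    used2[j] <- TRUE
    reads <- union(strsplit(set1$read_ids[i], ",")[[1]],
                   strsplit(set2$read_ids[j], ",")[[1]])
    reads <- reads[nzchar(reads)]
    w <- pmax(1L, c(set1$support[i], set2$support[j]))
    p1 <- lomedian(c(set1$pos1[i], set2$pos1[j]), w)
    p2 <- lomedian(c(set1$pos2[i], set2$pos2[j]), w)
    lo1 <- min(set1$pos1[i] + set1$ci1_lo, set2$pos1[j] + set2$ci1_lo)
    hi1 <- max(set1$pos1[i] + set1$ci1_hi, set2$pos1[j] + set2$ci1_hi)
    lo2 <- min(set1$pos2[i] + set1$ci2_lo, set2$pos2[j] + set2$ci2_lo)
    hi2 <- max(set1$pos2[i] + set1$ci2_hi, set2$pos2[j] + set2$ci2_hi)
    r <- set1[i, ]
    r$pos1 <- p1; r$ci1_lo <- lo1 - p1; r$ci1_hi <- hi1 - p1
    r$pos2 <- p2; r$ci2_lo <- lo2 - p2; r$ci2_hi <- hi2 - p2
    r$support <- length(reads)
    r$read_ids <- paste(sort(reads), collapse = ",")
    r$median_insertion <- lomedian(c(set1$median_insertion[i],
                                     set2$median_insertion[j]), w)
    r$low_support <- r$support < cfg$min_support
    r$imprecise <- r$low_support |
      (r$ci1_hi - r$ci1_lo) > cfg$cluster_tol |
      (r$ci2_hi - r$ci2_lo) > cfg$cluster_tol
    r$source <- "merged"
    rows[[length(rows) + 1L]] <- r
  }
  for (j in which(!used2)) {
    r <- set2[j, ]
    r$source <- labels[2]
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ]
  out$call_id <- sprintf("BND%04d", seq_len(nrow(out)))
  out
}

#' Annotate breakends against a repeat/feature BED
#'
#' Labels each breakend with the names of BED features containing it
#' (0-based half-open containment; a breakend whose 0-based coordinate equals
#' a feature end is outside it). Multiple containing features are joined with
#' commas in file order.
#'
#' @param calls Calls tibble.
#' @param bed BED file path or a tibble from [read_bed()].
#' @return Calls tibble with `label1` and `label2` columns.
#' @export
annotate_calls <- function(calls, bed) {
  if (is.character(bed)) bed <- read_bed(bed)
  label_for <- function(chrom, pos) {
    vapply(seq_along(pos), function(k) {
      hit <- bed$chrom == chrom[k] & bed$start <= pos[k] - 1 &
        pos[k] - 1 < bed$end
      paste(bed$name[hit], collapse = ",")
    }, character(1))
  }
  calls$label1 <- label_for(calls$chrom1, calls$pos1)
  calls$label2 <- label_for(calls$chrom2, calls$pos2)
  calls
}

#' Flag breakends adjacent to reference assembly gaps
#'
#' A breakend within `dist` bases of an N-run of at least `min_run` bases
#' (centromeres, unresolved gaps) is marked imprecise: split alignments into
#' such regions cannot pin the junction to a base.
#'
#' @param calls Calls tibble.
#' @param ref Reference `DNAStringSet`.
#' @param dist Distance threshold (bases). Default 5000.
#' @param min_run Minimum N-run length (bases). Default 100.
#' @return Calls tibble with updated `imprecise` flags.
#' @export
flag_near_gaps <- function(calls, ref, dist = 5000, min_run = 100) {
  if (nrow(calls) == 0L) return(calls)
  runs <- n_run_ranges(ref)
  near <- function(chrom, pos) {
    vapply(seq_along(pos), function(k) {
      r <- runs[[chrom[k]]]
      if (is.null(r) || length(r) == 0L) return(FALSE)
      r <- r[IRanges::width(r) >= min_run]
      if (length(r) == 0L) return(FALSE)
      any(pos[k] >= IRanges::start(r) - dist & pos[k] <= IRanges::end(r) + dist)
    }, logical(1))
  }
  calls$imprecise <- calls$imprecise | near(calls$chrom1, calls$pos1) |
    near(calls$chrom2, calls$pos2)
  calls
}

#' Reconstruct junction-spanning sequence from the reference
#'
#' Builds the derivative sequence across one called junction: `flank` bases
#' of retained sequence running into the breakpoint, concatenated with
#' `flank` bases resuming on the partner, reverse-complementing as the
#' orientation requires. Useful for primer design and junction validation.
#'
#' @param ref Reference `DNAStringSet`.
#' @param calls Calls tibble (precise calls only).
#' @param flank Bases on each side. Default 500.
#' @return A `DNAStringSet`, one record per junction; ids encode the two
#'   breakends. Flanks overrunning a contig end are truncated with a warning.
#' @export
junction_sequence <- function(ref, calls, flank = 500) {
  stopifnot(flank >= 1)
  if (any(calls$imprecise))
    stop("junction_sequence requires precise calls; got imprecise: ",
         paste(calls$call_id[calls$imprecise], collapse = ", "),
         call. = FALSE)
  piece <- function(chrom, pos, side, rc) {
    len <- length(ref[[chrom]])
    if (side == "end") { s <- pos - flank + 1; e <- pos }
    else { s <- pos; e <- pos + flank - 1 }
    if (s < 1 || e > len) {
      warning("flank truncated at contig end for ", chrom, ":", pos,
              call. = FALSE)
      s <- max(1, s); e <- min(len, e)
    }
    x <- Biostrings::subseq(ref[[chrom]], s, e)
    if (rc) Biostrings::reverseComplement(x) else x
  }
  seqs <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    halves <- switch(
      cl$orientation,
      "+-" = list(piece(cl$chrom1, cl$pos1, "end", FALSE),
                  piece(cl$chrom2, cl$pos2, "start", FALSE)),
      "-+" = list(piece(cl$chrom2, cl$pos2, "end", FALSE),
                  piece(cl$chrom1, cl$pos1, "start", FALSE)),
      "++" = list(piece(cl$chrom1, cl$pos1, "end", FALSE),
                  piece(cl$chrom2, cl$pos2, "end", TRUE)),
      "--" = list(piece(cl$chrom1, cl$pos1, "start", TRUE),
                  piece(cl$chrom2, cl$pos2, "start", FALSE)),
      stop("unknown orientation: ", cl$orientation, call. = FALSE)
    )
    Biostrings::xscat(halves[[1]], halves[[2]])
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0(calls$chrom1, ":", calls$pos1,
                       "(", substr(calls$orientation, 1, 1), ")-",
                       calls$chrom2, ":", calls$pos2,
                       "(", substr(calls$orientation, 2, 2), ")")
  out
}
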